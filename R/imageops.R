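# Low-level raster helpers shared by the preprocessing and nonperfusion
# stages. All operate on plain matrices; coordinates are (row, col).

# Separable 1D convolution along rows (dim = 1) or columns (dim = 2) with
# replicate padding at the borders.
conv1d <- function(x, kernel, dim = 1) {
  m <- (length(kernel) - 1L) %/% 2L
  n <- nrow(x)
  p <- ncol(x)
  out <- matrix(0, n, p)
  if (dim == 1) {
    idx <- c(rep(1L, m), seq_len(n), rep(n, m))
    xp <- x[idx, , drop = FALSE]
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * xp[j:(j + n - 1L), , drop = FALSE]
    }
  } else {
    idx <- c(rep(1L, m), seq_len(p), rep(p, m))
    xp <- x[, idx, drop = FALSE]
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * xp[, j:(j + p - 1L), drop = FALSE]
    }
  }
  out
}

# Sampled Gaussian kernel and its first/second derivatives, truncated at
# 4 sigma and with the 0th-order kernel normalized to unit sum.
gauss_kernels <- function(sigma) {
  m <- max(1L, ceiling(4 * sigma))
  t <- seq(-m, m)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- (-t / sigma^2) * g
  g2 <- ((t^2 - sigma^2) / sigma^4) * g
  # derivative kernels must annihilate constants exactly
  g1 <- g1 - mean(g1)
  g2 <- g2 - mean(g2)
  list(g = g, g1 = g1, g2 = g2)
}

# Shift a logical matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(x, dr, dc, fill = FALSE) {
  n <- nrow(x); p <- ncol(x)
  out <- matrix(fill, n, p)
  rs <- seq_len(n) - dr
  cs <- seq_len(p) - dc
  ok_r <- rs >= 1 & rs <= n
  ok_c <- cs >= 1 & cs <= p
  out[which(ok_r), which(ok_c)] <- x[rs[ok_r], cs[ok_c]]
  out
}

# Euler number (components minus holes) for 8-connected foreground, by
# Gray's bit-quad counts on the background-padded mask.
euler_number <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  a <- m[-nrow(m), -ncol(m)]
  b <- m[-nrow(m), -1]
  c_ <- m[-1, -ncol(m)]
  d <- m[-1, -1]
  s <- a + b + c_ + d
  q1 <- sum(s == 1)
  q3 <- sum(s == 3)
  qd <- sum(s == 2 & ((a & d & !b & !c_) | (b & c_ & !a & !d)))
  (q1 - q3 - 2L * qd) / 4L
}

# Remove 8-connected foreground components smaller than min_px pixels.
remove_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- .label8_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Corner-corrected chain-code boundary length (Vossepoel-Smeulders weights
# 0.980 per axial and 1.406 per diagonal step), accumulated per label of a
# component labelling. `perimeter` must be the thin boundary map; returns a
# numeric vector of lengths indexed by label.
chain_length_by_label <- function(perimeter, lab, n_labels) {
  out <- numeric(n_labels)
  if (!any(perimeter)) return(out)
  segs <- .trace_segments_cpp(perimeter)
  for (p in segs) {
    if (nrow(p) < 2) next
    st <- abs(diff(p))
    diag <- rowSums(st) == 2
    l <- lab[p[1, 1], p[1, 2]]
    out[l] <- out[l] + 0.980 * sum(!diag) + 1.406 * sum(diag)
  }
  out
}

# Exact Euclidean distance (pixels) from every pixel to the nearest TRUE
# pixel of `reference` (0 on the reference itself).
edt_to_reference <- function(reference) {
  if (!any(reference)) stop("reference mask is empty: distances undefined")
  d <- EBImage::distmap(EBImage::Image(!reference), metric = "euclidean")
  matrix(EBImage::imageData(d), nrow(reference), ncol(reference))
}

# Binary erosion by a Euclidean disk of radius r (pixels): keep foreground
# pixels strictly farther than r from the background.
erode_disk <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  if (all(mask)) return(mask)
  d <- edt_to_reference(!mask)
  mask & (d > r)
}

# Binary dilation by a Euclidean disk of radius r (pixels).
dilate_disk <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  d <- edt_to_reference(mask)
  d <= r
}
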