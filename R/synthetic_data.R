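# Generators for all test inputs: analytic shapes with closed-form metric
# values, stochastic capillary networks with exact ground truth, and a
# two-group clustered cohort. Every generator is a pure function of its
# parameters and seed.

disk_mask <- function(n, center, r) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - center[1])^2 + (cc - center[2])^2 <= r^2
}

# Round a dense point sequence to pixels, deduplicate consecutive repeats,
# and drop pixels made redundant by a diagonal shortcut so the result is a
# thin 8-connected chain.
rasterize_curve <- function(rows, cols, n) {
  pr <- round(rows); pc <- round(cols)
  keep <- c(TRUE, diff(pr) != 0 | diff(pc) != 0)
  pr <- pr[keep]; pc <- pc[keep]
  repeat {
    if (length(pr) < 3) break
    drop <- rep(FALSE, length(pr))
    i <- 2L
    while (i < length(pr)) {
      if (!drop[i - 1L] &&
          max(abs(pr[i + 1L] - pr[i - 1L]), abs(pc[i + 1L] - pc[i - 1L])) <= 1) {
        drop[i] <- TRUE
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    if (!any(drop)) break
    pr <- pr[!drop]; pc <- pc[!drop]
  }
  ok <- pr >= 1 & pr <= n & pc >= 1 & pc <= n
  cbind(pr[ok], pc[ok])
}

#' Generate an analytic test shape with exact ground truth
#'
#' Noise-free binary-valued images of simple shapes whose vascular indices
#' have closed forms, used as oracles for the metric implementations.
#'
#' @param kind one of `"disk"`, `"square"`, `"bar"`, `"line"`, `"arc"`,
#'   `"annulus"`, `"grid"`.
#' @param params named list of shape parameters (pixels): disk/annulus
#'   `r` (+ `r_inner`), square `side`, bar `width` and `length`, line none,
#'   arc `r` (semicircle), grid `spacing` and `width`.
#' @param image_size image edge length in pixels.
#' @param field_width_mm physical width (default 3).
#' @return A list with `image` (an [enface_image] with vessel pixels at
#'   intensity 1) and `truth` (a `synthetic_truth` with the exact
#'   `vessel_mask`, empty `faz_mask` and `dropout_mask`).
#' @export
make_shape <- function(kind = c("disk", "square", "bar", "line", "arc",
                                "annulus", "grid"),
                       params = list(), image_size = 200,
                       field_width_mm = 3) {
  kind <- match.arg(kind)
  n <- image_size
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  mask <- matrix(FALSE, n, n)
  if (kind == "disk") {
    r <- params$r %||% 50
    if (r >= n / 2) stop("disk of radius ", r, " does not fit in ", n, " px")
    mask <- disk_mask(n, ctr, r)
  } else if (kind == "annulus") {
    r <- params$r %||% 60
    ri <- params$r_inner %||% 40
    if (r >= n / 2 || ri >= r) stop("annulus geometry out of bounds")
    mask <- disk_mask(n, ctr, r) & !disk_mask(n, ctr, ri)
  } else if (kind == "square") {
    side <- params$side %||% 80
    if (side > n) stop("square side ", side, " exceeds image size")
    r0 <- floor(ctr[1] - side / 2) + 1L
    mask[r0:(r0 + side - 1L), r0:(r0 + side - 1L)] <- TRUE
  } else if (kind == "bar") {
    w <- params$width %||% 5
    len <- params$length %||% n
    if (w > n || len > n) stop("bar does not fit in image")
    r0 <- floor(ctr[1] - w / 2) + 1L
    c0 <- floor(ctr[2] - len / 2) + 1L
    mask[r0:(r0 + w - 1L), c0:(c0 + len - 1L)] <- TRUE
  } else if (kind == "line") {
    mask[round(ctr[1]), ] <- TRUE
  } else if (kind == "arc") {
    r <- params$r %||% 60
    if (r >= n / 2) stop("arc radius out of bounds")
    th <- seq(0, pi, length.out = max(2000, 40 * r))
    pts <- rasterize_curve(ctr[1] - r * sin(th), ctr[2] + r * cos(th), n)
    mask[pts] <- TRUE
  } else if (kind == "grid") {
    spacing <- params$spacing %||% 10
    w <- params$width %||% 1
    pos <- seq(ceiling(spacing / 2), n, by = spacing)
    for (p in pos) {
      idx <- p:min(n, p + w - 1L)
      mask[idx, ] <- TRUE
      mask[, idx] <- TRUE
    }
  }
  empty <- matrix(FALSE, n, n)
  list(
    image = enface_image(mask * 1, field_width_mm = field_width_mm),
    truth = structure(
      list(vessel_mask = mask, faz_mask = empty, dropout_mask = empty,
           params = c(list(kind = kind, image_size = n), params)),
      class = "synthetic_truth"
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic enface angiogram with exact ground truth
#'
#' Emulates the appearance a quantification pipeline sees on a macular
#' enface OCTA scan: a sine-perturbed capillary lattice plus a few coarser
#' superficial-style trunk vessels, a central avascular FAZ disk, circular
#' capillary-dropout lesions of known total area, and multiplicative
#' speckle noise. The vessel, FAZ and dropout masks are exact by
#' construction.
#'
#' @param density_target target vessel area fraction in percent; controls
#'   the lattice spacing.
#' @param tortuosity_amp amplitude (pixels) of the sinusoidal perturbation
#'   of each lattice curve.
#' @param faz_radius_um FAZ disk radius in micrometres (default 350, a
#'   normal-sized FAZ of ~0.38 mm^2).
#' @param dropout_fraction total dropout-lesion area as percent of the
#'   image.
#' @param noise_sd multiplicative speckle SD (0 = noise free).
#' @param seed integer seed.
#' @param image_size image edge length in pixels (default 304).
#' @param field_width_mm physical width (default 3).
#' @param n_trunks number of coarse trunk vessels (default 4).
#' @return A list with `image` (an [enface_image]) and `truth` (a
#'   `synthetic_truth` with `vessel_mask`, `faz_mask`, `dropout_mask` and
#'   the generator parameters).
#' @export
make_network <- function(density_target = 25, tortuosity_amp = 3,
                         faz_radius_um = 350, dropout_fraction = 0,
                         noise_sd = 0.2, seed = 1L, image_size = 304,
                         field_width_mm = 3, n_trunks = 4) {
  stopifnot(density_target > 0, density_target <= 60,
            tortuosity_amp >= 0, faz_radius_um >= 0,
            dropout_fraction >= 0, dropout_fraction < 80, noise_sd >= 0)
  n <- image_size
  px_um <- field_width_mm * 1000 / n
  set.seed(as.integer(seed))
  # lattice spacing: two orthogonal 1-px curve families give a vessel
  # fraction of roughly 2/spacing
  spacing <- max(3L, round(200 / density_target))
  vessel <- matrix(FALSE, n, n)
  t <- seq_len(n)
  draw_family <- function(vessel, vertical) {
    for (x0 in seq(1 + spacing %/% 2, n, by = spacing)) {
      ph <- runif(1, 0, 2 * pi)
      fr <- runif(1, 1.5, 3.5)  # oscillations across the field
      off <- tortuosity_amp * sin(2 * pi * fr * t / n + ph)
      pts <- if (vertical) {
        rasterize_curve(t, x0 + off, n)
      } else {
        rasterize_curve(x0 + off, t, n)
      }
      vessel[pts] <- TRUE
    }
    vessel
  }
  vessel <- draw_family(vessel, vertical = TRUE)
  vessel <- draw_family(vessel, vertical = FALSE)
  # coarser trunks, 3 px wide
  trunk <- matrix(FALSE, n, n)
  for (i in seq_len(n_trunks)) {
    x0 <- runif(1, 0.15 * n, 0.85 * n)
    ph <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.03, 0.08) * n
    off <- amp * sin(2 * pi * t / n + ph)
    pts <- if (i %% 2 == 0) {
      rasterize_curve(t, x0 + off, n)
    } else {
      rasterize_curve(x0 + off, t, n)
    }
    trunk[pts] <- TRUE
  }
  vessel <- vessel | dilate_disk(trunk, 1)

  # central FAZ
  faz_r_px <- faz_radius_um / px_um
  faz <- if (faz_r_px >= 1) {
    disk_mask(n, c((n + 1) / 2, (n + 1) / 2), faz_r_px)
  } else {
    matrix(FALSE, n, n)
  }
  vessel[faz] <- FALSE

  # dropout lesions outside the FAZ, totalling dropout_fraction percent
  # nonperfusion patches in DR are typically a few hundred micrometres
  # across; lesion radii are capped at 450 um
  dropout <- matrix(FALSE, n, n)
  target_px <- dropout_fraction / 100 * n^2
  r_cap <- 450 / px_um
  guard <- 0L
  while (sum(dropout) < target_px && guard < 200L) {
    guard <- guard + 1L
    need <- target_px - sum(dropout)
    r <- min(max(4, sqrt(need / pi)), r_cap)
    ctr_r <- runif(1, r + 1, n - r)
    ctr_c <- runif(1, r + 1, n - r)
    # keep lesions clear of the FAZ so truth areas stay unambiguous
    if (sqrt((ctr_r - (n + 1) / 2)^2 + (ctr_c - (n + 1) / 2)^2) <
        faz_r_px + r + 2) next
    dropout <- dropout | disk_mask(n, c(ctr_r, ctr_c), r)
  }
  dropout <- dropout & !faz
  if (dropout_fraction > 0 && sum(dropout) < 0.5 * target_px) {
    stop("infeasible dropout fraction for this FAZ/field geometry")
  }
  vessel[dropout] <- FALSE

  # render: dim noise floor everywhere, bright vessels, multiplicative speckle
  img <- matrix(0.12, n, n)
  img[vessel] <- 0.85
  if (noise_sd > 0) {
    img <- img * (1 + noise_sd * matrix(rnorm(n * n), n, n))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(
    image = enface_image(img, field_width_mm = field_width_mm),
    truth = structure(
      list(
        vessel_mask = vessel, faz_mask = faz, dropout_mask = dropout,
        params = list(density_target = density_target,
                      tortuosity_amp = tortuosity_amp,
                      faz_radius_um = faz_radius_um,
                      dropout_fraction = dropout_fraction,
                      noise_sd = noise_sd, seed = seed,
                      image_size = image_size,
                      field_width_mm = field_width_mm)
      ),
      class = "synthetic_truth"
    )
  )
}

#' Diabetic macular edema classification rule
#'
#' An eye has DME when central subfield thickness exceeds 350 micrometres
#' (strictly) or central retinal cystoid changes are present.
#'
#' @param cst_um central subfield thickness in micrometres (> 0).
#' @param central_cysts logical flag for central cystoid changes.
#' @return Logical DME flag (vectorized).
#' @export
classify_dme <- function(cst_um, central_cysts = FALSE) {
  stopifnot(all(cst_um > 0))
  cst_um > 350 | central_cysts
}

#' Cohort simulation specification
#'
#' Defaults mirror the shape of a typical retrospective fellow-eye DR
#' cohort: 92 patients, half contributing both eyes (138 eyes), 59 eyes
#' with DME, about a third PDR, with fellow-eye correlation 0.5. Group
#' effects are additive shifts on the nonperfusion and density metrics of
#' DME eyes.
#'
#' @param n_patients number of patients (>= 2).
#' @param bilateral_fraction fraction of patients contributing both eyes.
#' @param p_dme per-eye probability of DME.
#' @param dme_effect_gpd percentage points added to GPD and CNP of DME eyes.
#' @param dme_effect_vd percentage points subtracted from VD of DME eyes.
#' @param inter_eye_correlation correlation of fellow-eye metric values.
#' @param p_pdr per-eye probability of proliferative DR, independent of DME.
#' @param noise_sd_scale multiplier on the per-metric residual SDs.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 92, bilateral_fraction = 0.5,
                        p_dme = 59 / 138, dme_effect_gpd = 3,
                        dme_effect_vd = 2.5, inter_eye_correlation = 0.5,
                        p_pdr = 44 / 138, noise_sd_scale = 1,
                        seed = 20211203L) {
  stopifnot(n_patients >= 2,
            bilateral_fraction >= 0, bilateral_fraction <= 1,
            p_dme >= 0, p_dme <= 1, p_pdr >= 0, p_pdr <= 1,
            inter_eye_correlation >= 0, inter_eye_correlation <= 1,
            noise_sd_scale > 0)
  structure(
    list(n_patients = n_patients, bilateral_fraction = bilateral_fraction,
         p_dme = p_dme, dme_effect_gpd = dme_effect_gpd,
         dme_effect_vd = dme_effect_vd,
         inter_eye_correlation = inter_eye_correlation, p_pdr = p_pdr,
         noise_sd_scale = noise_sd_scale, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Baseline metric means and SDs (no-DME, NPDR eyes) used by the cohort
# generator; magnitudes follow what enface 3x3 mm OCTA quantification
# typically reports in diabetic eyes.
cohort_baseline <- function() {
  data.frame(
    metric = c("faz_area_mm2",
               "scp_vti", "scp_fd", "scp_cnp_pct", "scp_gpd_pct",
               "scp_vd", "scp_vdi", "scp_vci",
               "dcp_vti", "dcp_fd", "dcp_cnp_pct", "dcp_gpd_pct",
               "dcp_vd", "dcp_vdi", "dcp_vci"),
    mean = c(0.46,
             1.138, 1.944, 4.99, 7.01, 28.86, 2.31, 1.09,
             1.141, 1.965, 1.09, 2.17, 31.54, 2.24, 1.20),
    sd = c(0.16,
           0.013, 0.012, 4.17, 3.95, 3.77, 0.08, 0.08,
           0.013, 0.004, 1.27, 1.61, 3.63, 0.07, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-group clustered cohort of eye records
#'
#' Draws per-eye metric sets with a shared per-patient Gaussian effect
#' (inducing the requested fellow-eye correlation), additive DME shifts on
#' the nonperfusion and density metrics, an independent PDR label with its
#' own smaller shift, and clinical covariates consistent with the DME
#' classification rule (CST > 350 um or central cysts).
#'
#' @param spec a [cohort_spec].
#' @return A data frame, one row per eye: `patient_id`, `eye`, `dme`,
#'   `dr_stage`, `cst_um`, `central_cysts`, `bcva_logmar`, and one column
#'   per metric (prefixed `scp_` / `dcp_`, plus `faz_area_mm2`).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  base <- cohort_baseline()
  rho <- spec$inter_eye_correlation

  bilateral <- runif(spec$n_patients) < spec$bilateral_fraction
  n_eyes_pp <- ifelse(bilateral, 2L, 1L)
  patient_id <- rep(seq_len(spec$n_patients), n_eyes_pp)
  eye <- unlist(lapply(n_eyes_pp, function(k) c("OD", "OS")[seq_len(k)]),
                use.names = FALSE)
  n_eyes <- length(patient_id)

  dme <- runif(n_eyes) < spec$p_dme
  pdr <- runif(n_eyes) < spec$p_pdr

  # clinical covariates consistent with the classification rule
  cst <- numeric(n_eyes)
  cysts <- logical(n_eyes)
  cst[!dme] <- pmin(rnorm(sum(!dme), 254.1, 29.9), 349)
  cst[!dme] <- pmax(cst[!dme], 150)
  cst[dme] <- pmax(rnorm(sum(dme), 420.1, 115.4), 200)
  cysts[dme] <- cst[dme] <= 350 | runif(sum(dme)) < 0.6
  bcva <- pmax(rnorm(n_eyes, ifelse(dme, 0.46, 0.19),
                     ifelse(dme, 0.30, 0.19)), 0)
  stopifnot(all(classify_dme(cst, cysts) == dme))

  out <- data.frame(patient_id = patient_id, eye = eye, dme = dme,
                    dr_stage = ifelse(pdr, "PDR", "NPDR"),
                    cst_um = round(cst, 1), central_cysts = cysts,
                    bcva_logmar = round(bcva, 2),
                    stringsAsFactors = FALSE)

  # metric effects: DME raises nonperfusion, lowers density; PDR carries a
  # smaller shift in the same directions so stage adjustment has a target
  for (i in seq_len(nrow(base))) {
    m <- base$metric[i]
    mu <- base$mean[i]
    sdv <- base$sd[i] * spec$noise_sd_scale
    eff <- 0
    if (grepl("gpd|cnp", m)) {
      eff <- spec$dme_effect_gpd * ifelse(grepl("^dcp", m), 0.5, 1)
      stage_eff <- 0.4 * eff
    } else if (grepl("_vd$", m)) {
      eff <- -spec$dme_effect_vd
      stage_eff <- 0.4 * eff
    } else {
      stage_eff <- 0
    }
    u_pat <- rnorm(spec$n_patients)          # shared patient effect
    y <- mu + eff * dme + stage_eff * pdr +
      sdv * (sqrt(rho) * u_pat[patient_id] + sqrt(1 - rho) * rnorm(n_eyes))
    # physical bounds
    if (grepl("cnp|gpd", m)) y <- pmax(y, 0)
    if (grepl("_vd$", m)) y <- pmin(pmax(y, 0), 100)
    if (grepl("vti", m)) y <- pmax(y, 1)
    if (grepl("fd", m)) y <- pmin(pmax(y, 0), 2)
    if (grepl("faz", m)) y <- pmax(y, 0.05)
    out[[m]] <- y
  }
  out
}
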