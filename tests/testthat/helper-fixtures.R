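# Shared fixture builders; everything is generated in code at test time.

# random union of filled disks and bars, for topology property tests
random_blobs <- function(seed, n = 64, n_shapes = 6) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  for (i in seq_len(n_shapes)) {
    if (runif(1) < 0.6) {
      r <- runif(1, 3, 9)
      c0 <- runif(2, r + 1, n - r)
      m <- m | ((rr - c0[1])^2 + (cc - c0[2])^2 <= r^2)
    } else {
      w <- sample(2:4, 1)
      r0 <- sample(n - w, 1)
      c1 <- sort(sample(n, 2))
      m[r0:(r0 + w - 1), c1[1]:c1[2]] <- TRUE
    }
  }
  m
}

has_2x2_block <- function(m) {
  any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
        m[-nrow(m), -1] & m[-1, -1])
}

# dense noise-free capillary lattice with a dropout lesion, the standard
# input for deficit-recovery checks
lesion_network <- function(seed, dropout = 10, noise = 0) {
  make_network(density_target = 40, tortuosity_amp = 2,
               dropout_fraction = dropout, noise_sd = noise, seed = seed)
}
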