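test_that("distance map is the exact Euclidean transform in micrometres", {
  ref <- matrix(TRUE, 10, 10)
  dm <- distance_map(ref, 10)
  expect_equal(dm$um, matrix(0, 10, 10))

  one <- matrix(FALSE, 10, 10)
  one[1, 1] <- TRUE
  dm <- distance_map(one, 10)
  expect_equal(dm$um[4, 5], 50)      # 3-4-5 triangle
  expect_equal(dm$um[1, 1], 0)
  expect_equal(dm$um[1, 10], 90)

  # 1-Lipschitz in pixel steps
  set.seed(6)
  ref <- random_blobs(31)
  dm <- distance_map(ref, 1)$um
  dh <- abs(diff(dm))
  dv <- abs(t(diff(t(dm))))
  expect_lte(max(dh, dv), sqrt(2) + 1e-9)

  expect_error(distance_map(matrix(FALSE, 5, 5), 10), "empty")
})

test_that("CNP is zero on a dense grid and recovers a known lesion", {
  cfg <- analysis_config()
  # dense regular grid: every pixel within the normal inter-capillary bound
  g <- make_shape("grid", list(spacing = 5, width = 1), 200)
  px_um <- g$image$pixel_size_um  # 15 um/px: cell centers ~ 2.5 px = 37 um
  cfg40 <- analysis_config(cnp_distance_threshold_um = 40,
                           gpd_distance_threshold_um = 40)
  faz0 <- matrix(FALSE, 200, 200)
  expect_equal(cnp_quantify(g$truth$vessel_mask, faz0, cfg40, px_um)$percent,
               0)

  # lesion of ~10% truth fraction on a noise-free network
  net <- lesion_network(seed = 21)
  maps <- make_vessel_maps(net$image, net$truth$faz_mask, cfg)
  truth <- 100 * mean(net$truth$dropout_mask)
  cnp <- cnp_quantify(maps$binary, net$truth$faz_mask, cfg,
                      net$image$pixel_size_um)
  expect_lt(abs(cnp$percent - truth), 2)
  expect_false(any(cnp$mask & net$truth$faz_mask))
  expect_false(any(cnp$mask & maps$binary))

  # avascular center covered exactly by the FAZ mask: excluded entirely
  net2 <- make_network(40, tortuosity_amp = 2, faz_radius_um = 500,
                       dropout_fraction = 0, noise_sd = 0, seed = 3)
  maps2 <- make_vessel_maps(net2$image, net2$truth$faz_mask, cfg)
  cnp2 <- cnp_quantify(maps2$binary, net2$truth$faz_mask, cfg,
                       net2$image$pixel_size_um)
  expect_lt(cnp2$percent, 0.1)
})

test_that("GPD dominates CNP at equal thresholds without morphology", {
  cfg_raw <- analysis_config(cnp_morphology = FALSE)
  for (seed in c(2, 13, 40)) {
    net <- lesion_network(seed, dropout = 8)
    maps <- make_vessel_maps(net$image, net$truth$faz_mask, cfg_raw)
    cnp <- cnp_quantify(maps$binary, net$truth$faz_mask, cfg_raw,
                        net$image$pixel_size_um)
    gpd <- gpd_quantify(maps$skeleton, net$truth$faz_mask, cfg_raw,
                        net$image$pixel_size_um)
    expect_gte(gpd$percent, cnp$percent)
    # pointwise: every CNP deficit pixel is also a GPD deficit pixel
    expect_true(all(gpd$mask[cnp$mask]))
  }
})

test_that("deficits are monotone in threshold and in vessel addition", {
  net <- lesion_network(seed = 17, dropout = 8)
  cfg <- analysis_config(cnp_morphology = FALSE)
  maps <- make_vessel_maps(net$image, net$truth$faz_mask, cfg)
  px <- net$image$pixel_size_um
  faz <- net$truth$faz_mask

  pct <- sapply(c(20, 30, 45, 60), function(thr) {
    c(cnp_quantify(maps$binary, faz,
                   analysis_config(cnp_distance_threshold_um = thr,
                                   cnp_morphology = FALSE), px)$percent,
      gpd_quantify(maps$skeleton, faz,
                   analysis_config(gpd_distance_threshold_um = thr), px)$percent)
  })
  expect_true(all(diff(pct[1, ]) <= 0))
  expect_true(all(diff(pct[2, ]) <= 0))

  # adding vessels never increases a deficit
  added <- maps$binary
  added[150:154, 10:300] <- TRUE
  cnp0 <- cnp_quantify(maps$binary, faz, cfg, px)$percent
  cnp1 <- cnp_quantify(added, faz, cfg, px)$percent
  expect_lte(cnp1, cnp0)

  # empty FAZ mask: percent equals the raw thresholded fraction
  gpd <- gpd_quantify(maps$skeleton, matrix(FALSE, 304, 304), cfg, px)
  raw <- distance_map(maps$skeleton, px, "SKELETON")$um > 30
  raw[maps$skeleton] <- FALSE
  expect_equal(gpd$percent, 100 * mean(raw))
})

test_that("deficit error shrinks as noise goes to zero", {
  errs <- sapply(c(0.3, 0.15, 0), function(ns) {
    e <- sapply(c(51, 52), function(seed) {
      net <- lesion_network(seed, dropout = 10, noise = ns)
      cfg <- analysis_config()
      maps <- make_vessel_maps(net$image, net$truth$faz_mask, cfg)
      gpd <- gpd_quantify(maps$skeleton, net$truth$faz_mask, cfg,
                          net$image$pixel_size_um)
      abs(gpd$percent - 100 * mean(net$truth$dropout_mask))
    })
    mean(e)
  })
  expect_true(all(diff(errs) <= 0.5))  # non-increasing up to MC wiggle
  expect_lt(errs[3], 2)
})

test_that("fallback FAZ detector finds the central avascular region", {
  g <- make_shape("grid", list(spacing = 4, width = 1), 200)$truth$vessel_mask
  n <- 200
  faz_true <- octaquant:::disk_mask(n, c(100.5, 100.5), 30)
  corner <- octaquant:::disk_mask(n, c(30, 30), 15)
  vessels <- g & !faz_true & !corner
  faz <- faz_fallback(vessels, 15)
  inter <- sum(faz & faz_true)
  expect_gt(inter / sum(faz_true), 0.85)
  expect_lt(abs(sum(faz) - pi * 30^2) / (pi * 30^2), 0.10)
  # only the central region, not the corner one
  expect_equal(sum(faz & corner), 0)

  solid <- matrix(TRUE, 50, 50)
  expect_error(faz_fallback(solid), "center is a vessel")
})
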