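test_that("vessel density and length density are occupancy percentages", {
  expect_equal(vessel_density(matrix(TRUE, 10, 10)), 100)
  half <- matrix(c(TRUE, FALSE), 10, 10)
  expect_equal(vessel_density(half), 50)

  set.seed(4)
  m <- matrix(FALSE, 100, 100)
  m[sample(10000, 1234)] <- TRUE
  expect_equal(vessel_density(m), 12.34)

  expect_equal(vessel_length_density(matrix(FALSE, 10, 10)), 0)
  line <- matrix(FALSE, 100, 100)
  line[50, ] <- TRUE
  expect_equal(vessel_length_density(line), 1.0)
  # when every vessel is already 1 px wide, VLD == VD
  expect_equal(vessel_length_density(line), vessel_density(line))
})

test_that("vessel diameter index measures mean caliber", {
  bar <- make_shape("bar", list(width = 5, length = 180), 200)
  sk <- skeletonize_map(bar$truth$vessel_mask)
  vd <- vessel_density(bar$truth$vessel_mask)
  vld <- vessel_length_density(sk)
  expect_equal(vessel_diameter_index(vd, vld), 5, tolerance = 0.1)
  expect_equal(vessel_diameter_index(3, 3), 1.0)
  expect_true(is.na(vessel_diameter_index(3, 0)))
  expect_equal(vessel_diameter_index(10, 4, inverted = TRUE), 0.4)

  # widening at fixed centerline increases VDI strictly
  vdis <- sapply(c(3, 5, 7), function(w) {
    b <- make_shape("bar", list(width = w, length = 180), 200)$truth$vessel_mask
    vessel_diameter_index(vessel_density(b), vessel_length_density(sk))
  })
  expect_true(all(diff(vdis) > 0))
})

test_that("box-counting fractal dimension matches analytic dimensions", {
  line <- make_shape("line", image_size = 304)$truth$vessel_mask
  fd_line <- fractal_dimension(line, c(2, 4, 8, 16, 32))
  expect_equal(fd_line, 1, tolerance = 0.05)
  # independent oracle: N(s) = ceil(W / s) for a full-width straight line
  expect_equal(octaquant:::box_counts(line, c(2, 4, 8, 16, 32)),
               as.integer(ceiling(304 / c(2, 4, 8, 16, 32))))

  full <- matrix(TRUE, 304, 304)
  expect_equal(fractal_dimension(full), 2, tolerance = 0.05)

  px <- matrix(FALSE, 64, 64)
  px[10, 20] <- TRUE
  expect_equal(fractal_dimension(px), 0)
  expect_true(is.na(fractal_dimension(matrix(FALSE, 8, 8))))

  # monotone box counts on nested skeletons
  s1 <- matrix(FALSE, 128, 128)
  s1[64, 10:100] <- TRUE
  s2 <- s1
  s2[10:100, 64] <- TRUE
  n1 <- octaquant:::box_counts(s1, c(2, 4, 8, 16))
  n2 <- octaquant:::box_counts(s2, c(2, 4, 8, 16))
  expect_true(all(n1 <= n2))
})

test_that("segment decomposition partitions the skeleton at nodes", {
  # one open curve: a single segment
  arc <- make_shape("arc", list(r = 40), 120)$truth$vessel_mask
  expect_length(decompose_segments(arc), 1)

  # two crossing lines: 4 segments sharing the center node (drawn
  # diagonally so the arms stay 1 px wide under 8-connectivity)
  m <- matrix(FALSE, 101, 101)
  m[cbind(21:81, 21:81)] <- TRUE
  m[cbind(21:81, 81:21)] <- TRUE
  segs <- decompose_segments(m)
  expect_length(segs, 4)
  npix <- sum(sapply(segs, function(s) nrow(s$path)))
  expect_equal(npix, sum(m) + 3)  # center pixel shared by all 4 segments

  # every skeleton pixel belongs to at least one segment, also for an
  # orthogonal crossing whose center region carries several nodes
  plus <- matrix(FALSE, 101, 101)
  plus[51, 21:81] <- TRUE
  plus[21:81, 51] <- TRUE
  for (mm in list(m, plus)) {
    covered <- matrix(FALSE, 101, 101)
    for (s in decompose_segments(mm)) covered[s$path] <- TRUE
    expect_identical(covered, mm)
  }

  # arc >= chord for every segment
  for (s in segs) expect_gte(s$arc_length_px, s$chord_length_px)
})

test_that("tortuosity index is 1 for straight vessels and pi/2 for a
           semicircle", {
  m <- matrix(FALSE, 64, 64)
  m[10, 5:60] <- TRUE       # horizontal
  m[cbind(20:50, 20:50)] <- TRUE  # diagonal
  expect_equal(vascular_tortuosity_index(decompose_segments(m)), 1.0)

  arc <- make_shape("arc", list(r = 60), 160)$truth$vessel_mask
  vti <- vascular_tortuosity_index(decompose_segments(arc))
  expect_equal(vti, pi / 2, tolerance = 0.05 * pi / 2)

  # a mixed set lies strictly between the per-segment extremes
  both <- arc
  both[155, 10:150] <- TRUE
  v_mix <- vascular_tortuosity_index(decompose_segments(both))
  expect_gt(v_mix, 1)
  expect_lt(v_mix, vti)

  expect_true(is.na(vascular_tortuosity_index(list())))
})

test_that("VTI and VCI are invariant under translation and 90-degree
           rotation", {
  net <- make_network(25, dropout_fraction = 0, noise_sd = 0, seed = 9,
                      image_size = 160)
  cfg <- analysis_config()
  maps <- make_vessel_maps(net$image, net$truth$faz_mask, cfg)
  vti0 <- vascular_tortuosity_index(decompose_segments(maps$skeleton))
  vci0 <- vascular_complexity_index(maps$binary)

  rot <- function(m) t(m)[, nrow(m):1]
  sk_r <- rot(maps$skeleton)
  bin_r <- rot(maps$binary)
  expect_equal(vascular_tortuosity_index(decompose_segments(sk_r)), vti0,
               tolerance = 1e-12)
  expect_equal(vascular_complexity_index(bin_r), vci0, tolerance = 1e-12)

  # translation by whole pixels (content away from borders)
  sh <- function(m) octaquant:::shift_mat(m, 2, 3)
  inner <- matrix(FALSE, 160, 160)
  inner[30:130, 30:130] <- TRUE
  sk_t <- sh(maps$skeleton & inner)
  expect_equal(
    vascular_tortuosity_index(decompose_segments(sk_t)),
    vascular_tortuosity_index(decompose_segments(maps$skeleton & inner)),
    tolerance = 1e-12)
})

test_that("complexity index matches isoperimetric oracles", {
  d <- make_shape("disk", list(r = 50), 150)$truth$vessel_mask
  expect_equal(vascular_complexity_index(d), 1.00, tolerance = 0.10)

  s <- make_shape("square", list(side = 80), 150)$truth$vessel_mask
  expect_equal(vascular_complexity_index(s), 4 / pi, tolerance = 0.10)

  # scale invariance within 5%
  s2 <- make_shape("square", list(side = 160), 300)$truth$vessel_mask
  expect_equal(vascular_complexity_index(s2), vascular_complexity_index(s),
               tolerance = 0.05)
  d2 <- make_shape("disk", list(r = 100), 300)$truth$vessel_mask
  expect_equal(vascular_complexity_index(d2), vascular_complexity_index(d),
               tolerance = 0.05)

  expect_true(is.na(vascular_complexity_index(matrix(FALSE, 5, 5))))
  # pooled variant reproduces the literal pooled pixel-count formula
  per <- perimeter_of(d)
  expect_equal(
    vascular_complexity_index(d, per, pooled = TRUE,
                              perimeter_measure = "pixel_count"),
    sum(per)^2 / (4 * pi * sum(d)))
})

test_that("compute_metric_set populates every field consistently", {
  cfg <- analysis_config()
  net <- make_network(25, dropout_fraction = 0, noise_sd = 0, seed = 12,
                      image_size = 200)
  maps <- make_vessel_maps(net$image, net$truth$faz_mask, cfg)
  ms <- compute_metric_set(maps, net$truth$faz_mask, cfg,
                           net$image$pixel_size_um)
  expect_s3_class(ms, "metric_set")
  expect_lte(ms$vld, ms$vd)
  expect_gte(ms$vti, 1)
  expect_gte(ms$fd, 0)
  expect_lte(ms$fd, 2)
  expect_lt(abs(ms$vd - 100 * mean(net$truth$vessel_mask)), 3)
  expect_equal(ms$faz_area_mm2,
               sum(net$truth$faz_mask) * (net$image$pixel_size_um / 1000)^2)

  # deterministic on fixed input
  ms2 <- compute_metric_set(maps, net$truth$faz_mask, cfg,
                            net$image$pixel_size_um)
  expect_identical(ms, ms2)

  # all-vessel reference: full density, no deficit anywhere
  all_on <- matrix(TRUE, 50, 50)
  faz0 <- matrix(FALSE, 50, 50)
  expect_equal(vessel_density(all_on), 100)
  expect_equal(cnp_quantify(all_on, faz0, cfg, 10)$percent, 0)
  expect_equal(gpd_quantify(all_on, faz0, cfg, 10)$percent, 0)
})
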