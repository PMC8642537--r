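test_that("frangi vesselness is zero on flat regions and peaks on ridges", {
  flat <- enface_image(matrix(0.7, 64, 64))
  expect_equal(frangi_enhance(flat)$pixels, matrix(0, 64, 64))

  # interior of a large uniform disk: no curvature, no response
  d <- make_shape("disk", list(r = 60), image_size = 160)
  v <- frangi_enhance(d$image, scales = c(1, 1.5, 2))$pixels
  interior <- octaquant:::disk_mask(160, c(80.5, 80.5), 40)
  expect_lt(max(v[interior]), 1e-4)

  # single bright 1-px line: response on the line beats any pixel >= 3 away
  m <- matrix(0, 64, 64)
  m[32, ] <- 1
  v <- frangi_enhance(enface_image(m), scales = 1)$pixels
  on_line <- v[32, 5:60]
  far <- v[c(1:29, 35:64), ]
  expect_gt(min(on_line), max(far))

  expect_error(frangi_enhance(flat, scales = numeric(0)))
})

test_that("faz_threshold implements mean + k * population SD", {
  m <- matrix(0, 4, 4)
  m[1, 1:4] <- c(0, 0, 0.20, 0.20)
  faz <- matrix(FALSE, 4, 4)
  faz[1, 1:4] <- TRUE
  # mean 0.10, population SD 0.10
  expect_equal(faz_threshold(m, faz, k = 1.2), 0.22)
  expect_equal(faz_threshold(m, faz, k = 0), 0.10)

  # SD = 0 when all FAZ pixels equal
  u <- matrix(0.10, 4, 4)
  expect_equal(faz_threshold(u, faz, k = 5), 0.10)

  # affine in k
  t1 <- faz_threshold(m, faz, k = 0.4)
  t2 <- faz_threshold(m, faz, k = 2.0)
  tm <- faz_threshold(m, faz, k = 1.2)
  expect_equal(t1 + t2, 2 * tm, tolerance = 1e-12)

  # sample SD option
  expect_equal(faz_threshold(m, faz, k = 1, sd_type = "sample"),
               0.10 + sd(c(0, 0, 0.2, 0.2)))

  one <- matrix(FALSE, 4, 4)
  one[1, 1] <- TRUE
  expect_error(faz_threshold(m, one), "at least 2")
})

test_that("binarize thresholds strictly and monotonically", {
  set.seed(2)
  m <- matrix(runif(100, 0.01, 1), 10, 10)
  expect_true(all(binarize(m, 0)))
  expect_false(any(binarize(m, 1)))

  chk <- matrix(c(0.2, 0.8), 10, 10)
  expect_equal(sum(binarize(chk, 0.5)), 50)

  lo <- binarize(m, 0.3)
  hi <- binarize(m, 0.6)
  expect_true(all(lo | !hi))  # raising the threshold never adds pixels
})

test_that("skeletonization thins to 1 px and preserves topology", {
  one <- matrix(FALSE, 9, 9)
  one[5, 5] <- TRUE
  expect_identical(skeletonize_map(one), one)

  bar <- matrix(FALSE, 40, 110)
  bar[18:22, 6:105] <- TRUE
  sk <- skeletonize_map(bar)
  expect_true(all(bar[sk]))
  expect_false(has_2x2_block(sk))
  expect_gte(sum(sk), 96)
  expect_lte(sum(sk), 100)

  ann <- make_shape("annulus", list(r = 60, r_inner = 40), 160)
  sk <- skeletonize_map(ann$truth$vessel_mask)
  expect_equal(octaquant:::euler_number(sk), 0)  # one loop: 1 comp - 1 hole
  segs <- decompose_segments(sk)
  expect_length(segs, 2)  # an isolated loop is split in two

  empty <- matrix(FALSE, 5, 5)
  expect_identical(skeletonize_map(empty), empty)
})

test_that("thinning preserves the Euler number on random blobs", {
  for (seed in 1:10) {
    m <- random_blobs(seed)
    sk <- skeletonize_map(m)
    expect_true(all(m[sk]))
    expect_false(has_2x2_block(sk))
    expect_equal(octaquant:::euler_number(sk), octaquant:::euler_number(m),
                 label = paste("euler, seed", seed))
  }
})

test_that("perimeter marks foreground 4-adjacent to background", {
  one <- matrix(FALSE, 5, 5)
  one[3, 3] <- TRUE
  expect_identical(perimeter_of(one), one)

  full <- matrix(TRUE, 10, 10)
  per <- perimeter_of(full)
  frame <- matrix(FALSE, 10, 10)
  frame[c(1, 10), ] <- TRUE
  frame[, c(1, 10)] <- TRUE
  expect_identical(per, frame)

  d <- make_shape("disk", list(r = 50), 150)$truth$vessel_mask
  cnt <- sum(perimeter_of(d))
  expect_lt(abs(cnt - 2 * pi * 50) / (2 * pi * 50), 0.15)
  # explicit boundary scan oracle: same set by construction
  man <- d & (!octaquant:::shift_mat(d, 1, 0) | !octaquant:::shift_mat(d, -1, 0) |
              !octaquant:::shift_mat(d, 0, 1) | !octaquant:::shift_mat(d, 0, -1))
  expect_identical(perimeter_of(d), man)
})

test_that("make_vessel_maps recovers truth on clean networks and stays
           empty on pure noise", {
  cfg <- analysis_config()
  net <- make_network(25, dropout_fraction = 0, noise_sd = 0, seed = 5,
                      image_size = 200)
  maps <- make_vessel_maps(net$image, net$truth$faz_mask, cfg)
  recall <- sum(maps$binary & net$truth$vessel_mask) /
    sum(net$truth$vessel_mask)
  expect_gte(recall, 0.95)
  expect_true(all(maps$binary[maps$skeleton]))
  expect_true(all(maps$binary[maps$perimeter]))

  # identical input twice: identical maps
  maps2 <- make_vessel_maps(net$image, net$truth$faz_mask, cfg)
  expect_identical(maps, maps2)

  # vessel-free image with FAZ noise: nothing survives cleanup
  set.seed(8)
  n <- 200
  noise <- matrix(pmin(pmax(0.12 * (1 + 0.2 * rnorm(n * n)), 0), 1), n, n)
  img <- enface_image(noise)
  faz <- octaquant:::disk_mask(n, c(100.5, 100.5), 30)
  maps <- make_vessel_maps(img, faz, cfg)
  expect_equal(sum(maps$binary), 0)
})
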