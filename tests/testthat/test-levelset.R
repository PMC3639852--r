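test_that("nonlinear data term reproduces its closed-form spot values", {
  t <- 6
  # right limit at the belt mean: 1 - exp(-2/t)
  expect_equal(data_term_nonlinear(0.5 + 1e-12, mu = 0.5, i_m = 0.9, t = t),
               1 - exp(-2 / t), tolerance = 1e-6)
  expect_equal(1 - exp(-2 / 6), 0.2834687, tolerance = 1e-6)
  # worked value below the mean
  expect_equal(data_term_nonlinear(0.3, mu = 0.5, i_m = 0.9, t = 6),
               -exp(-0.2 / 2.4), tolerance = 1e-12)
  expect_equal(-exp(-0.2 / 2.4), -0.9200444, tolerance = 1e-6)
  # forced zero at the belt maximum
  expect_lt(abs(data_term_nonlinear(0.9, mu = 0.5, i_m = 0.9)), 1e-12)
  # the jump at i = mu is part of the law: left branch -> -1
  expect_equal(data_term_nonlinear(0.5 - 1e-12, mu = 0.5, i_m = 0.9, t = 6),
               -1, tolerance = 1e-6)
  expect_error(data_term_nonlinear(0.5, mu = 0.7, i_m = 0.7),
               class = "acnm_degenerate_acn")
})

test_that("nonlinear data term has the sign structure of the exclusion law", {
  set.seed(1)
  grid <- seq(0, 1, length.out = 501)
  for (rep in 1:50) {
    mu <- runif(1, 0.1, 0.6)
    i_m <- runif(1, mu + 0.1, 1)
    t <- runif(1, 1, 10)
    D <- data_term_nonlinear(grid, mu, i_m, t)
    expect_true(all(D[grid < mu] < 0))
    expect_true(all(D[grid > mu & grid < i_m - 1e-9] > 0))
    expect_true(all(D[grid > i_m + 1e-9] < 0))
  }
})

test_that("t trades contraction speed against expansion speed", {
  mu <- 0.4; i_m <- 0.85
  ts <- c(2, 4, 6)
  below <- seq(0.05, 0.35, length.out = 25)
  inside <- seq(0.45, 0.8, length.out = 25)
  D <- sapply(ts, function(t) data_term_nonlinear(c(below, inside), mu, i_m, t))
  nb <- length(below)
  # |D| increasing in t below the mean (faster contraction)
  expect_true(all(abs(D[1:nb, 2]) > abs(D[1:nb, 1])))
  expect_true(all(abs(D[1:nb, 3]) > abs(D[1:nb, 2])))
  # D decreasing in t inside (mu, i_m) (slower expansion)
  expect_true(all(D[(nb + 1):(2 * nb), 2] < D[(nb + 1):(2 * nb), 1]))
  expect_true(all(D[(nb + 1):(2 * nb), 3] < D[(nb + 1):(2 * nb), 2]))
})

test_that("linear data term peaks at the target and crosses zero at its range", {
  expect_equal(data_term_linear(0.6, T0 = 0.6, epsilon = 0.2), 0.2)
  expect_equal(data_term_linear(0.8, T0 = 0.6, epsilon = 0.2), 0)
  expect_lt(data_term_linear(0.05, T0 = 0.6, epsilon = 0.2), 0)
  expect_error(data_term_linear(0.5, 0.5, 0), class = "acnm_validation_error")
})

test_that("signed distance fields have the SDF structure", {
  disk <- disk_region(48, 48, 24, 24, 10)
  f <- signed_distance(disk)
  expect_equal(f$phi[24, 24], 10, tolerance = 1)
  expect_true(all(f$phi[disk] >= 0))
  expect_true(all(f$phi[!disk] < 0))
  # |grad phi| near 1 in the band around the zero set
  band <- abs(f$phi) < 3
  gnorm <- slope8(f$phi)[band]
  expect_true(all(gnorm > 0.9 & gnorm < 1.1))
  expect_error(signed_distance(matrix(FALSE, 8, 8)), class = "acnm_validation_error")
  expect_error(signed_distance(matrix(TRUE, 8, 8)), class = "acnm_validation_error")
})

test_that("evolution is confined to the belt and moves disks as advection dictates", {
  disk <- disk_region(64, 64, 32, 32, 12)
  belt <- disk_region(64, 64, 32, 32, 18) & !disk_region(64, 64, 32, 32, 6)
  f <- signed_distance(disk)
  ones <- matrix(1, 64, 64)

  # off-belt pixels never change
  p <- speed_params(beta = 1.2)
  f2 <- evolve_step(f, 0.5 * ones, 0.7 * ones, p, belt)
  expect_identical(f2$phi[!belt], f$phi[!belt])

  # uniform D > 0, beta = 0: the disk grows
  p0 <- speed_params(beta = 0)
  g <- f
  for (i in 1:10) g <- evolve_step(g, 0.5 * ones, ones, p0, belt)
  expect_gt(sum(g$phi >= 0), sum(disk))

  # D = 0, beta > 0, g = 1: curvature flow shrinks the disk
  pc <- speed_params(beta = 1)
  h <- f
  for (i in 1:60) h <- evolve_step(h, 0 * ones, ones, pc, belt)
  expect_lt(sum(h$phi >= 0), sum(disk))
})

test_that("reinitialization restores the SDF band without moving the front", {
  disk <- disk_region(64, 64, 30, 34, 13)
  f0 <- signed_distance(disk_region(64, 64, 30, 34, 13))
  # near-fixed point on an exact SDF: no sign flips, zero set still in place
  f1 <- reinitialize(f0)
  expect_equal(sum(xor(f1$phi >= 0, f0$phi >= 0)), 0)
  expect_lt(max(abs(f1$phi - f0$phi)[abs(f0$phi) < 2]), 0.5)

  # after 50 evolution steps the band gradient is restored (band measured
  # inside the update region: values across the frozen-belt cliff are stale
  # by construction)
  belt <- disk_region(64, 64, 30, 34, 20) & !disk_region(64, 64, 30, 34, 6)
  ones <- matrix(1, 64, 64)
  p <- speed_params(beta = 0.5)
  g <- f0
  for (i in 1:50) g <- evolve_step(g, 0.1 * ones, ones, p, belt)
  r <- reinitialize(g, iters = 20)
  inner_belt <- as.matrix(EBImage::erode(belt * 1,
                                         EBImage::makeBrush(3, "box"))) > 0
  gnorm <- slope8(r$phi)[abs(r$phi) < 3 & inner_belt]
  expect_true(all(abs(gnorm - 1) <= 0.1))
  # region recovered from phi >= 0 shifts by at most a 1-pixel ring
  flips <- xor(r$phi >= 0, g$phi >= 0)
  border <- g$phi >= 0 &
    !(as.matrix(EBImage::erode((g$phi >= 0) * 1, EBImage::makeBrush(5, "disc"))) > 0)
  expect_true(all(!flips | border |
                  as.matrix(EBImage::dilate((g$phi >= 0) * 1,
                                            EBImage::makeBrush(5, "disc"))) > 0))
})

test_that("extract_contour keeps large components and fills holes", {
  m <- matrix(FALSE, 64, 64)
  m[10:40, 10:40] <- TRUE           # area ~ 961
  m[20:24, 20:24] <- FALSE          # a hole, to be filled
  m[55:57, 55:59] <- TRUE           # 15-pixel speck, to be dropped
  f <- signed_distance(m)
  ctr <- extract_contour(f, min_area = 50)
  expect_length(ctr$chains, 1)
  expect_true(all(ctr$region[20:24, 20:24]))   # hole filled
  expect_false(any(ctr$region[55:57, 55:59]))  # speck dropped
  all_neg <- structure(list(phi = matrix(-1, 8, 8)), class = "acnm_field")
  expect_error(extract_contour(all_neg, 10), class = "acnm_empty_contour")
  big_min <- signed_distance(disk_region(32, 32, 16, 16, 3))
  expect_error(extract_contour(big_min, min_area = 1000),
               class = "acnm_empty_contour")
})

test_that("the slice loop recovers the clean middle slice and is a near fixed point", {
  ph <- clean_phantom()
  mid <- dim(ph$volume$data)[1] %/% 2
  slice <- ph$volume$data[mid, , ]
  truth <- ph$truth$data[mid, , ] > 0
  init <- initial_contour_middle_slice(slice)
  ctr <- run_acnm_slice(slice, init)
  expect_gte(region_dice2(ctr$region, truth), 0.95)
  # re-running from its own output stays where it is
  again <- run_acnm_slice(slice, ctr)
  expect_gte(region_dice2(again$region, ctr$region),
             speed_params()$converge_tol)
})

test_that("the nonlinear law excludes the eye; the linear baseline leaks", {
  fx <- eye_slice_fixture()
  p <- speed_params(inner_tol = 0, converge_tol = 1, outer_max = 20)
  nl <- run_acnm_slice(fx$slice, fx$init, p)
  li <- run_acnm_slice(fx$slice, fx$init, p, speed = "linear")
  expect_lte(sum(nl$region & fx$eye), 5)
  fp_nl <- sum(nl$region & !fx$truth) / sum(fx$truth)
  fp_li <- sum(li$region & !fx$truth) / sum(fx$truth)
  expect_lt(fp_nl, fp_li)
})
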