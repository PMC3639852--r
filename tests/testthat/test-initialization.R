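test_that("surrogate initializer recovers a disk and the phantom middle slice", {
  # perfect disk on dark background
  disk <- disk_region(64, 64, 32, 32, 18)
  slice <- matrix(0.05, 64, 64)
  slice[disk] <- 0.8
  ctr <- initial_contour_middle_slice(slice, safety_margin = 0)
  expect_lt(abs(ctr$area - sum(disk)) / sum(disk), 0.10)

  # noiseless phantom middle slice: frozen regression bound
  ph <- clean_phantom()
  mid <- dim(ph$volume$data)[1] %/% 2
  truth <- ph$truth$data[mid, , ] > 0
  ctr2 <- initial_contour_middle_slice(ph$volume$data[mid, , ])
  expect_gte(region_dice2(ctr2$region, truth), 0.80)

  expect_error(initial_contour_middle_slice(matrix(0.05, 64, 64)),
               class = "acnm_init_error")
})

test_that("contour boundaries are closed chains on the region border", {
  disk <- disk_region(40, 40, 20, 20, 12)
  ctr <- contour_from_region(disk)
  expect_length(ctr$chains, 1)
  ch <- ctr$chains[[1]]
  # every chain pixel is a boundary pixel; chain is closed (steps of <= 1 px,
  # ends adjacent)
  expect_true(all(ctr$boundary_mask[ch]))
  steps <- sqrt(rowSums(diff(rbind(ch, ch[1, ]))^2))
  expect_lte(max(steps), sqrt(2) + 1e-9)
  # boundary pixels are exactly those with a background 8-neighbour
  expect_true(all(ctr$boundary_mask == (disk & !(
    as.matrix(EBImage::erode(disk * 1, EBImage::makeBrush(3, "box"))) > 0))))
})

test_that("circle initializer hits 0.83 x area at the same centroid", {
  ref <- contour_from_region(disk_region(128, 128, 60, 70, 40))
  out <- circle_initial_contour(ref)
  expect_lt(abs(out$area - 0.83 * ref$area) / (0.83 * ref$area), 0.02)
  cref <- colMeans(which(ref$region, arr.ind = TRUE))
  cout <- colMeans(which(out$region, arr.ind = TRUE))
  expect_lt(max(abs(cref - cout)), 0.5)
  tiny <- contour_from_region(disk_region(16, 16, 8, 8, 0.9))
  expect_error(circle_initial_contour(tiny), class = "acnm_init_error")
})

test_that("propagation decision matches exhaustive pixel enumeration", {
  # 8x8: next darker inside the mask, identical elsewhere -> contract
  cur <- matrix(0.5, 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  nxt <- cur; nxt[mask] <- 0.3
  dec <- propagation_decision(cur, nxt, mask)
  expect_equal(dec$direction, "contract")
  expect_equal(dec$r1_cover, sum(mask))
  expect_equal(dec$r2_cover, 0)

  # mirrored: next brighter inside -> expand
  nxt2 <- cur; nxt2[mask] <- 0.7
  expect_equal(propagation_decision(cur, nxt2, mask)$direction, "expand")

  # identical slices: R1 empty -> expand for a non-empty mask
  expect_equal(propagation_decision(cur, cur, mask)$direction, "expand")
  # and the 0-0 tie (empty mask) contracts by the tie-break
  dec0 <- propagation_decision(cur, cur, matrix(FALSE, 8, 8))
  expect_equal(dec0$direction, "contract")
  expect_equal(dec0$r1_cover + dec0$r2_cover, 0)

  expect_error(propagation_decision(cur, matrix(0, 4, 4), mask),
               class = "acnm_validation_error")
})

test_that("the decision is invariant to adding a constant to both slices", {
  set.seed(21)
  for (i in 1:20) {
    cur <- matrix(runif(100), 10, 10)
    nxt <- matrix(runif(100), 10, 10)
    mask <- matrix(runif(100) > 0.5, 10, 10)
    a <- propagation_decision(cur, nxt, mask)
    b <- propagation_decision(cur + 3.7, nxt + 3.7, mask)
    expect_identical(a$direction, b$direction)
    expect_identical(a$r1_cover, b$r1_cover)
  }
})

test_that("decisions on the phantom slice pairs follow the area trend", {
  shr <- slice_pair_fixture("shrinking")
  expect_equal(propagation_decision(shr$current, shr$nxt,
                                    shr$current_truth)$direction, "contract")
  gro <- slice_pair_fixture("growing")
  expect_equal(propagation_decision(gro$current, gro$nxt,
                                    gro$current_truth)$direction, "expand")
})

test_that("propagation erodes/dilates by a disc and is set-monotone", {
  ctr <- contour_from_region(disk_region(48, 48, 24, 24, 10))
  shr <- propagate_initial_contour(ctr, "contract", 2)
  target <- sum(disk_region(48, 48, 24, 24, 8))
  expect_lt(abs(shr$area - target) / target, 0.10)
  expect_true(all(shr$region <= ctr$region))

  gro <- propagate_initial_contour(ctr, "expand", 2)
  expect_true(all(gro$region >= ctr$region))

  # expand then contract on a convex region roughly recovers the original
  back <- propagate_initial_contour(gro, "contract", 2)
  expect_lt(abs(back$area - ctr$area) / ctr$area, 0.05)

  tiny <- contour_from_region(local({
    m <- matrix(FALSE, 16, 16); m[8, 8:9] <- TRUE; m
  }))
  expect_error(propagate_initial_contour(tiny, "contract", 2),
               class = "acnm_empty_contour")
})
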