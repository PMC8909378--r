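test_that("lung masking blanks exactly the non-lung voxels", {
  dims <- c(2L, 6L, 8L)
  hu <- array(stats::rnorm(prod(dims), -300, 100), dim = dims)
  vol <- ct_volume(hu, c(1, 1, 1))
  all1 <- lung_mask(array(1L, dim = dims), c(1, 1, 1))
  expect_equal(mask_lungs(vol, all1)$voxels, hu)

  checker <- lung_mask(array((seq_len(prod(dims)) %% 2L), dim = dims),
                       c(1, 1, 1))
  out <- mask_lungs(vol, checker, fill = -1000)
  expect_true(all(out$voxels[checker$voxels == 0L] == -1000))
  expect_equal(out$voxels[checker$voxels == 1L], hu[checker$voxels == 1L])
  expect_equal(sum(out$voxels == -1000), sum(checker$voxels == 0L))

  empty <- lung_mask(array(0L, dim = dims), c(1, 1, 1))
  expect_error(mask_lungs(vol, empty), "empty")
})

test_that("crop geometry pads small boxes and minimally downscales large ones", {
  box_mask <- function(ny, nx, bh, bw) {
    m <- array(0L, dim = c(1L, ny, nx))
    m[1, 10:(9 + bh), 20:(19 + bw)] <- 1L
    lung_mask(m, c(1, 1, 1))
  }
  # 200 x 300 box in a 512 x 512 slice: fits, original resolution
  cg <- compute_crop(box_mask(512, 512, 200, 300))
  expect_equal(cg$scale, 1)
  expect_equal(unname(cg$scaled), c(200, 300))
  expect_equal(unname(cg$pad), c((288 - 200) %/% 2, (384 - 300) %/% 2))
  # 576 x 768 box: exactly double the target, s = 0.5
  cg2 <- compute_crop(box_mask(600, 800, 576, 768))
  expect_equal(cg2$scale, 0.5)
  expect_equal(unname(cg2$scaled), c(288, 384))
  expect_equal(unname(cg2$pad), c(0, 0))
  # boundary: box equal to target, s = 1, zero padding
  cg3 <- compute_crop(box_mask(400, 500, 288, 384))
  expect_equal(cg3$scale, 1)
  expect_equal(unname(cg3$pad), c(0, 0))
  # a single isotropic factor even for anisotropic overflow
  cg4 <- compute_crop(box_mask(600, 800, 576, 400))
  expect_equal(cg4$scale, 0.5)
  expect_equal(unname(cg4$scaled), c(288, 200))

  expect_error(compute_crop(lung_mask(array(0L, dim = c(1, 4, 4)),
                                      c(1, 1, 1))), "empty")
})

test_that("slice filter retains exactly the >= 1% pathology slices", {
  # 3 slices x 100 lung voxels with 0 / 1 / 5 pathology voxels
  dims <- c(3L, 10L, 10L)
  mask <- array(1L, dim = dims)
  lab <- array(1L, dim = dims)
  lab[2, 1, 1] <- 2L
  lab[3, 1, 1:5] <- 3L
  filt <- filter_slices(label_map(lab, c(1, 1, 1)),
                        lung_mask(mask, c(1, 1, 1)), tau = 0.01)
  expect_equal(filt$retained, c(2L, 3L))  # the 1% tie is retained
  expect_equal(filt$fraction, c(0, 0.01, 0.05))

  # all-normal volume: nothing retained
  filt0 <- filter_slices(label_map(array(1L, dim = dims), c(1, 1, 1)),
                         lung_mask(mask, c(1, 1, 1)))
  expect_length(filt0$retained, 0L)

  # tau = 0 retains every lung-containing slice
  mask2 <- mask; mask2[1, , ] <- 0L
  lab2 <- lab; lab2[1, , ] <- 0L
  filt2 <- filter_slices(label_map(lab2, c(1, 1, 1)),
                         lung_mask(mask2, c(1, 1, 1)), tau = 0)
  expect_equal(filt2$retained, c(2L, 3L))

  expect_error(filter_slices(label_map(lab, c(1, 1, 1)),
                             lung_mask(mask, c(1, 1, 1)), tau = 1.5),
               "tau")
})

test_that("slice filter matches the brute-force counter on random volumes", {
  for (s in 1:30) {
    pair <- random_map_pair(dims = c(4L, 7L, 9L), seed = s)
    got <- filter_slices(pair$a, pair$mask)$retained
    expect_identical(got, bf_retained_slices(pair$a, pair$mask))
  }
})

test_that("samples land on the target grid with conserved labels at s = 1", {
  cs <- generate_case(tiny_spec(seed = 8L), 1, 2)
  plan <- slice_plan(cs, target = c(32L, 48L))
  expect_equal(plan$crop$scale, 1)
  samples <- make_samples(cs, plan)
  expect_gt(length(samples), 0L)
  sm <- samples[[1]]
  expect_equal(dim(sm$image), c(32L, 48L))
  expect_true(all(sm$image >= 0 & sm$image <= 1))
  expect_equal(sm$case_id, "P001_T2")

  # class histogram equals the source in-bbox histogram (padding adds only
  # OUTSIDE background)
  bb <- plan$crop$bbox
  src <- cs$labels$voxels[sm$slice, bb["y0"]:bb["y1"], bb["x0"]:bb["x1"]]
  expect_equal(tabulate(sm$labels, 5L), tabulate(src, 5L))
  # lung voxel count conserved too
  expect_equal(sum(sm$lung), sum(cs$mask$voxels[sm$slice, , ]))
})

test_that("adjacent-slice channels stack clamped neighbours", {
  cs <- generate_case(tiny_spec(seed = 8L), 1, 2)
  plan <- slice_plan(cs, target = c(32L, 48L))
  z <- plan$retained[1]
  sm3 <- make_samples(cs, plan, slices = z, channels = 3L)[[1]]
  expect_equal(dim(sm3$image), c(32L, 48L, 3L))
  sm1 <- make_samples(cs, plan, slices = z)[[1]]
  expect_equal(sm3$image[, , 2], sm1$image)
  expect_error(make_samples(cs, plan, channels = 2L), "odd")
})

test_that("map-back inverts the crop exactly at scale 1", {
  cs <- generate_case(tiny_spec(seed = 8L), 1, 2)
  plan <- slice_plan(cs, target = c(32L, 48L))
  sm <- make_samples(cs, plan)[[2]]
  back <- map_back(sm$labels, plan$crop)
  expect_identical(back[cs$mask$voxels[sm$slice, , ] == 1L],
                   cs$labels$voxels[sm$slice, , ][
                     cs$mask$voxels[sm$slice, , ] == 1L])
})

test_that("map-back assigns exactly one label per box voxel at s < 1", {
  m <- array(0L, dim = c(1L, 80L, 100L))
  m[1, 5:76, 3:98] <- 1L   # 72 x 96 box onto a 32 x 48 target: s = 4/9
  mask <- lung_mask(m, c(1, 1, 1))
  cg <- compute_crop(mask, target = c(32L, 48L))
  expect_lt(cg$scale, 1)
  pred <- matrix(sample(1:5, 32 * 48, TRUE), 32, 48)
  back <- map_back(pred, cg)
  expect_true(all(back[m[1, , ] == 1L] %in% 1:5))
  expect_true(all(back[cg$bbox["y0"]:cg$bbox["y1"],
                       cg$bbox["x0"]:cg$bbox["x1"]] %in% 1:5))
  expect_true(all(back[-(cg$bbox["y0"]:cg$bbox["y1"]), ] == OUTSIDE))
})

test_that("pooled class frequencies conserve counts and respond to filtering", {
  cases <- generate_cohort(tiny_spec(seed = 12L))$cases
  fa <- class_frequencies(cases, "all")
  ff <- class_frequencies(cases, "filtered")
  expect_equal(sum(fa$fraction), 1)
  expect_equal(sum(ff$fraction), 1)
  # filtering concentrates pathology
  expect_gt(sum(ff$fraction[2:5]), sum(fa$fraction[2:5]))
  # conservation against a direct count
  total_lung <- sum(vapply(cases, function(cs) sum(cs$mask$voxels),
                           numeric(1)))
  expect_equal(sum(fa$voxels), total_lung)

  all1 <- toy_case(array(rep(c(0L, 1L), each = 8L), dim = c(2L, 4L, 2L)))
  expect_equal(class_frequencies(list(all1), "all")$fraction,
               c(1, 0, 0, 0, 0))
  expect_error(class_frequencies(list(all1), "filtered"), "empty")
})

test_that("patient splits partition patients without timepoint leakage", {
  pats <- sprintf("P%02d", 1:10)
  split <- split_patients(pats, k = 5, seed = 2)
  expect_setequal(names(split), pats)
  expect_true(all(table(split) == 2L))
  expect_identical(split, split_patients(pats, k = 5, seed = 2))
  expect_false(identical(split, split_patients(pats, k = 5, seed = 3)))
  expect_error(split_patients(pats[1:3], k = 5), "more folds")

  # uneven case: sizes differ by at most one
  split7 <- split_patients(sprintf("Q%d", 1:7), k = 3, seed = 1)
  expect_lte(diff(range(table(split7))), 1L)

  fs <- fixed_split(pats, n_test = 3, seed = 1)
  expect_length(fs$test, 3L)
  expect_setequal(c(fs$dev, fs$test), pats)
})
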