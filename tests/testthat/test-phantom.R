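small_spec <- function(...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), breast_radius = 10,
               chest_wall_depth = 10, ...)
}

test_that("phantom generation is deterministic given the seed", {
  a <- make_phantom(small_spec(seed = 11))
  b <- make_phantom(small_spec(seed = 11))
  expect_identical(a$series$pre, b$series$pre)
  expect_identical(a$series$post, b$series$post)
  expect_identical(a$gt$fgt_mask, b$gt$fgt_mask)
  c <- make_phantom(small_spec(seed = 12))
  expect_false(identical(a$series$pre, c$series$pre))
})

test_that("degenerate and invalid specs are handled", {
  ph <- make_phantom(small_spec(fgt_fraction_true = 0,
                                enhanced_fraction_true = c(0, 0, 0)))
  expect_equal(sum(ph$gt$fgt_mask), 0)
  expect_equal(ph$gt$true_fgt, 0)
  expect_error(phantom_spec(grid_shape = c(0, 10, 10)), "positive")
  expect_error(phantom_spec(fgt_fraction_true = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(enhanced_fraction_true = c(0.5, 0.4, 0.3)),
               "non-decreasing")
})

test_that("ground-truth masks realize the requested fractions", {
  ph <- make_phantom(phantom_spec(grid_shape = c(64L, 64L, 64L),
                                  breast_radius = 14, chest_wall_depth = 12,
                                  fgt_fraction_true = 0.164,
                                  enhanced_fraction_true = c(0.2, 0.4, 0.5),
                                  noise_sigma = 0))
  gt <- ph$gt
  # direct voxel counting, independent of true_metrics
  expect_lt(abs(sum(gt$fgt_mask) / sum(gt$breast_mask) - 0.164), 0.01)
  for (p in 1:3) {
    expect_lt(abs(sum(gt$enhanced_masks[[p]]) / sum(gt$fgt_mask) -
                    c(0.2, 0.4, 0.5)[p]), 0.01)
  }
  # noiseless volumes are piecewise constant by tissue class
  expect_lte(length(unique(as.vector(ph$series$pre))), 5)
})

test_that("mask nesting and kinetic monotonicity hold across random specs", {
  for (s in 1:4) {
    ef <- sort(runif(3, 0.1, 0.9))
    ph <- make_phantom(small_spec(fgt_fraction_true = runif(1, 0.05, 0.4),
                                  enhanced_fraction_true = ef, seed = s))
    gt <- ph$gt
    expect_true(all(gt$fgt_mask[gt$enhanced_masks[[3]]]))
    expect_true(all(gt$breast_mask[gt$fgt_mask]))
    for (p in 1:2)
      expect_true(all(gt$enhanced_masks[[p + 1]][gt$enhanced_masks[[p]]]))
    expect_true(!is.unsorted(gt$true_bpe_v))
  }
})

test_that("true_metrics applies the three formulas to the masks", {
  d <- c(4L, 4L, 4L)
  all_true <- array(TRUE, d)
  gt <- structure(list(breast_mask = all_true, fgt_mask = all_true,
                       enhanced_masks = list(all_true, all_true, all_true),
                       pre_clean = array(100, d),
                       post_clean = list(array(150, d), array(180, d),
                                         array(200, d))),
                  class = "ground_truth")
  tm <- true_metrics(gt)
  expect_equal(tm$fgt, 1)
  expect_equal(tm$bpe_v, rep(1, 3))
  expect_equal(tm$bpe_i, c(0.5, 0.8, 1.0))

  gt$breast_mask <- array(FALSE, d)
  expect_error(true_metrics(gt), "empty breast")

  ph <- make_phantom(small_spec(seed = 3))
  tm2 <- true_metrics(ph$gt)
  expect_equal(tm2$fgt, ph$gt$true_fgt)
  expect_equal(tm2$bpe_v, ph$gt$true_bpe_v)
  expect_equal(tm2$bpe_i, ph$gt$true_bpe_i, tolerance = 1e-12)
})

test_that("enhancement construction makes BPE_I truth analytic", {
  ph <- make_phantom(small_spec(enhancement_ratio_true = c(0.25, 0.3, 0.35),
                                noise_sigma = 0, seed = 2))
  tm <- true_metrics(ph$gt)
  expect_equal(tm$bpe_i, c(0.25, 0.3, 0.35), tolerance = 1e-12)
})

test_that("the study-shaped cohort reproduces the stratum counts exactly", {
  cohort <- make_cohort(table1_cohort_spec(seed = 5))
  expect_equal(nrow(cohort), 396)
  expect_equal(as.vector(table(cohort$group)), rep(132, 3))
  for (g in c("control", "cancer", "benign")) {
    sub <- cohort[cohort$group == g, ]
    expect_equal(sum(sub$menopause == "pre"), 62)
    expect_equal(as.vector(table(sub$week)), c(13, 16, 15, 18))
  }
  # invariants: week iff premenopausal, lesion side iff lesion group
  expect_true(all(is.na(cohort$week) == (cohort$menopause == "post")))
  expect_true(all(is.na(cohort$lesion_side) == (cohort$group == "control")))
})

test_that("cohort generation is reproducible and empty specs yield no rows", {
  a <- make_cohort(table1_cohort_spec(seed = 9))
  b <- make_cohort(table1_cohort_spec(seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))
  empty <- make_cohort(table1_cohort_spec(n_pre = 0L, weeks = rep(0L, 4),
                                          n_post = 0L))
  expect_equal(nrow(empty), 0)
  expect_error(table1_cohort_spec(n_pre = 5L, weeks = c(1L, 1L, 1L, 1L)),
               "sum")
})

test_that("per-subject BPE_V values inherit the medians' phase monotonicity", {
  cohort <- make_cohort(table1_cohort_spec(seed = 4, n_pre = 4L,
                                           weeks = c(1L, 1L, 1L, 1L),
                                           n_post = 4L))
  v <- as.matrix(cohort[, paste0("true_bpe_v_", 1:3)])
  expect_true(all(apply(v, 1, function(r) !is.unsorted(r))))
})
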