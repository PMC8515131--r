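mk <- function(d = c(4, 4, 4), val = FALSE) array(val, d)

test_that("metric formulas handle the identity and degenerate cases", {
  b <- mk(val = TRUE)
  expect_equal(compute_fgt_fraction(b, b), 1)
  expect_equal(compute_fgt_fraction(mk(), b), 0)
  expect_error(compute_fgt_fraction(b, mk()), "empty breast")
  expect_error(compute_fgt_fraction(b, {x <- b; x[1] <- FALSE; x}), "nested")

  expect_equal(compute_bpe_v(b, b), 1)
  expect_equal(compute_bpe_v(mk(), b), 0)
  und <- compute_bpe_v(mk(), mk())
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
})

test_that("BPE_I is the mean subtraction-to-original ratio", {
  d <- c(1, 1, 3)
  pre <- array(c(10, 10, 10), d)
  sub <- array(c(2, 3, 4), d)
  m <- array(TRUE, d)
  expect_equal(as.numeric(compute_bpe_i(sub, pre, m)), 0.3)
  # subtraction equal to pre -> all ratios 1
  expect_equal(as.numeric(compute_bpe_i(pre, pre, m)), 1)
  und <- compute_bpe_i(sub, pre, array(FALSE, d))
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
})

test_that("near-zero original intensities are excluded from the BPE_I mean", {
  d <- c(1, 1, 4)
  pre <- array(c(100, 100, 1e-9, 100), d)
  sub <- array(c(20, 30, 500, 40), d)
  m <- array(TRUE, d)
  got <- compute_bpe_i(sub, pre, m)
  expect_equal(as.numeric(got), mean(c(0.2, 0.3, 0.4)))
  expect_equal(attr(got, "n_excluded"), 1L)
})

test_that("BPE_I recovers the constructed enhancement ratio", {
  ph <- make_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L),
                                  breast_radius = 10, chest_wall_depth = 10,
                                  enhancement_ratio_true = c(0.25, 0.3, 0.35),
                                  noise_sigma = 0))
  sub <- subtract_volumes(ph$series$post[[1]], ph$series$pre)
  got <- compute_bpe_i(sub, ph$series$pre, ph$gt$enhanced_masks[[1]])
  expect_lt(abs(as.numeric(got) - 0.25), 0.01)
})

test_that("laterality selection averages controls and picks the contralateral side", {
  L <- quant_result(0.10, c(0.2, 0.3, 0.4), c(0.1, 0.2, 0.3), side = "left")
  R <- quant_result(0.20, c(0.4, 0.5, 0.6), c(0.3, 0.4, 0.5), side = "right")
  ctrl <- select_measurement("control", L, R)
  expect_equal(ctrl$fgt, 0.15)
  expect_equal(ctrl$bpe_v, c(0.3, 0.4, 0.5))
  expect_equal(ctrl$side, "combined")

  got <- select_measurement("cancer", L, R, lesion_side = "left")
  expect_identical(got, R)
  expect_identical(select_measurement("benign", L, R, lesion_side = "right"), L)
  expect_error(select_measurement("cancer", L, R), "lesion_side")
  # identical sides: selection is the identity for every group
  for (g in c("control", "benign", "cancer")) {
    same <- select_measurement(g, L, L, lesion_side = "left")
    expect_equal(same$fgt, L$fgt)
    expect_equal(same$bpe_v, L$bpe_v)
  }
})

test_that("end-to-end measurement recovers truth across a phantom cohort", {
  n <- 60
  set.seed(31)
  err_fgt <- err_bpev <- err_bpei <- numeric(n)
  for (i in seq_len(n)) {
    f <- runif(1, 0.08, 0.3)
    e2 <- runif(1, 0.2, 0.6)
    ef <- sort(c(0.7 * e2, e2, min(1, 1.2 * e2)))
    sp <- phantom_spec(grid_shape = c(48L, 48L, 48L), breast_radius = 10,
                       chest_wall_depth = 10, fgt_fraction_true = f,
                       enhanced_fraction_true = ef,
                       seed = sample.int(2^30, 1))
    ph <- make_phantom(sp)
    q <- quantify_series(ph$series)
    sel <- select_measurement("control", q$left, q$right)
    err_fgt[i] <- abs(sel$fgt - ph$gt$true_fgt)
    err_bpev[i] <- abs(sel$bpe_v[2] - ph$gt$true_bpe_v[2])
    err_bpei[i] <- abs(sel$bpe_i[2] - ph$gt$true_bpe_i[2])
  }
  expect_lte(median(err_fgt), 0.03)
  expect_lte(median(err_bpev), 0.03)
  expect_lte(median(err_bpei), 0.05)
})

test_that("measured BPE_V is phase-monotone through the full pipeline", {
  ph <- make_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L),
                                  breast_radius = 10, chest_wall_depth = 10,
                                  seed = 13))
  q <- quantify_series(ph$series)
  expect_true(!is.unsorted(q$left$bpe_v))
  expect_true(!is.unsorted(q$right$bpe_v))
})
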