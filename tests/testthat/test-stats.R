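rec <- function(id, age, meno = "pre", week = 2L) {
  data.frame(subject_id = id, age = age, menopause = meno,
             week = if (meno == "pre") week else NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("matching picks the nearest age within constraints", {
  cases <- rec("case1", 41)
  cands <- rbind(rec("c43", 43), rec("c48", 48))
  m <- match_cohorts(cases, cands)
  expect_equal(m$pairs$match_id, "c43")
  expect_equal(m$pairs$age_gap, 2)
  expect_length(m$unmatched, 0)
})

test_that("matching enforces the 5-year gap and menopause/week consistency", {
  m1 <- match_cohorts(rec("case1", 41), rec("c49", 49))
  expect_equal(m1$unmatched, "case1")

  m2 <- match_cohorts(rec("post1", 55, meno = "post"), rec("pre1", 55))
  expect_equal(m2$unmatched, "post1")

  m3 <- match_cohorts(rec("case1", 41, week = 2L), rec("c41", 41, week = 3L))
  expect_equal(m3$unmatched, "case1")
})

test_that("matching is deterministic with lowest-id tie-break and single-use candidates", {
  cases <- rbind(rec("a", 40), rec("b", 40))
  cands <- rbind(rec("z", 41), rec("y", 41))
  m <- match_cohorts(cases, cands)
  expect_equal(m$pairs$match_id[m$pairs$case_id == "a"], "y")
  expect_equal(m$pairs$match_id[m$pairs$case_id == "b"], "z")
  expect_equal(anyDuplicated(m$pairs$match_id), 0L)
})

test_that("Mann-Whitney U matches exact enumeration on tiny samples", {
  got <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(got$U, 0)
  expect_equal(got$p, 2 / choose(4, 2))
  expect_equal(got$method, "exact")

  tie <- mann_whitney_u(5, 5)
  expect_equal(tie$p, 1)

  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- round(rnorm(n1), 6); y <- round(rnorm(n2), 6)
    expect_equal(mann_whitney_u(x, y)$p, exact_mw_p(x, y), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(22)
  for (i in 1:15) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.3)
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    if (ours$method == "normal") expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # with heavy ties the tie-corrected normal path must match too
  x <- sample(1:4, 30, replace = TRUE); y <- sample(2:5, 25, replace = TRUE)
  expect_equal(mann_whitney_u(x, y)$p,
               suppressWarnings(wilcox.test(x, y, exact = FALSE))$p.value,
               tolerance = 1e-9)
})

test_that("exact and normal p-values agree closely at n1=n2=6", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    exact <- mann_whitney_u(x, y)$p
    normal <- {
      r <- rank(c(x, y)); U <- sum(r[1:6]) - 21
      z <- (U - 18 - sign(U - 18) * 0.5) / sqrt(6 * 6 * 13 / 12)
      min(1, 2 * pnorm(-abs(z)))
    }
    expect_lt(abs(exact - normal), 0.02)
  }
})

test_that("empirical AUC equals brute-force pair counting", {
  expect_equal(empirical_auc(c(2, 4), c(1, 3)), 0.75)
  expect_equal(empirical_auc(6:10, 1:5), 1)
  expect_equal(empirical_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)

  set.seed(24)
  for (i in 1:30) {
    x <- sample(1:10, sample(2:8, 1), replace = TRUE)
    y <- sample(1:10, sample(2:8, 1), replace = TRUE)
    expect_equal(empirical_auc(x, y), brute_force_auc(x, y))
  }
})

test_that("AUC identities: U/(n1 n2) and complement symmetry", {
  set.seed(25)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1))
    expect_equal(empirical_auc(x, y),
                 mann_whitney_u(x, y)$U / (length(x) * length(y)))
    expect_equal(empirical_auc(x, y) + empirical_auc(y, x), 1)
  }
})

test_that("compare_groups produces table-shaped rows with consistent fields", {
  set.seed(26)
  n <- 30
  records <- data.frame(
    group = rep(c("cancer", "control", "benign"), each = n),
    menopause = "pre",
    bpe_v_2 = c(rnorm(n, 0.48, 0.1), rnorm(n, 0.32, 0.1), rnorm(n, 0.39, 0.1)))
  out <- compare_groups(records, "bpe_v", "pre", phase = 2)
  expect_equal(nrow(out), 2)
  expect_setequal(out$contrast, c("cancer_vs_control", "cancer_vs_benign"))
  # AUC field equals the estimator applied to the same values, exactly
  cc <- out[out$contrast == "cancer_vs_control", ]
  expect_identical(cc$auc,
                   empirical_auc(records$bpe_v_2[records$group == "cancer"],
                                 records$bpe_v_2[records$group == "control"]))
  expect_equal(cc$cancer_pct,
               100 * median(records$bpe_v_2[records$group == "cancer"]))

  # identical groups: no discrimination
  same <- data.frame(group = rep(c("cancer", "control", "benign"), each = 50),
                     menopause = "post", fgt = rep(rnorm(50, 0.1, 0.02), 3))
  res <- compare_groups(same, "fgt", "post")
  expect_equal(res$auc, c(0.5, 0.5))
  expect_true(all(res$p > 0.9))

  expect_error(compare_groups(records, "bpe_v", "post", 2), "empty stratum")
  short <- records[-(1:29), ]
  expect_error(compare_groups(short, "bpe_v", "pre", 2), "at least 2")
})
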