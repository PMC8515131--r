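#' Greedy 1:1 matched cohort construction
#'
#' Matches each case to the candidate nearest in age, subject to consistent
#' menopausal status, consistent menstrual week (premenopausal subjects
#' only) and an age gap of at most `max_age_gap` years.  Cases are processed
#' in ascending age order (ties by subject id); each candidate is used at
#' most once; cases with no admissible candidate are reported unmatched,
#' which is an outcome, not an error.
#'
#' @param cases,candidates data frames with columns `subject_id`, `age`,
#'   `menopause` (`"pre"`/`"post"`) and `week` (`NA` for postmenopausal).
#' @param max_age_gap maximum allowed age difference in years.
#' @return List with `pairs` (data frame `case_id`, `match_id`, `age_gap`)
#'   and `unmatched` (character vector of case ids).
#' @export
match_cohorts <- function(cases, candidates, max_age_gap = 5) {
  need <- c("subject_id", "age", "menopause", "week")
  stopifnot(all(need %in% names(cases)), all(need %in% names(candidates)))
  cases <- cases[order(cases$age, cases$subject_id), , drop = FALSE]
  avail <- candidates
  pairs <- list(); unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ok <- avail$menopause == cs$menopause &
      abs(avail$age - cs$age) <= max_age_gap
    if (cs$menopause == "pre") ok <- ok & !is.na(avail$week) & avail$week == cs$week
    ok[is.na(ok)] <- FALSE
    if (!any(ok)) { unmatched <- c(unmatched, cs$subject_id); next }
    cand <- avail[ok, , drop = FALSE]
    cand <- cand[order(abs(cand$age - cs$age), cand$subject_id), , drop = FALSE]
    chosen <- cand[1, ]
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_id = cs$subject_id, match_id = chosen$subject_id,
      age_gap = abs(chosen$age - cs$age), stringsAsFactors = FALSE)
    avail <- avail[avail$subject_id != chosen$subject_id, , drop = FALSE]
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(case_id = character(0), match_id = character(0),
                    age_gap = numeric(0)),
       unmatched = unmatched)
}

#' Mann-Whitney U test
#'
#' Returns the U statistic of `x` (number of pairs with `x_i > y_j`, ties
#' counted one half) and a two-sided p-value: by exact enumeration of all
#' group assignments when `n1 + n2 <= 12` and there are no ties, otherwise
#' by the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @return List with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && n <= 12) {
    combos <- utils::combn(n, n1)
    rs <- rank(pooled)
    us <- apply(combos, 2, function(ix) sum(rs[ix])) - n1 * (n1 + 1) / 2
    centred <- abs(us - n1 * n2 / 2)
    p <- mean(centred >= abs(U - n1 * n2 / 2) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }

  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Empirical (nonparametric) AUC
#'
#' Pair-counting estimator of `P(X > Y) + 0.5 P(X = Y)` where `X` is a
#' positive-class (cancer) value and `Y` a comparator value — the area
#' under the empirical ROC curve, identical to the Mann-Whitney U statistic
#' divided by `n1 * n2`.
#'
#' @param cancer_values,other_values numeric samples.
#' @return AUC in \[0, 1\].
#' @export
empirical_auc <- function(cancer_values, other_values) {
  n1 <- length(cancer_values); n2 <- length(other_values)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(cancer_values, other_values))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Group comparison in the shape of the reported tables
#'
#' For one metric, menopausal stratum and (for the BPE metrics) phase,
#' compares the cancer group against the control and benign groups: group
#' medians (reported as percentages), Mann-Whitney U, two-sided p, and the
#' empirical AUC with cancer as the positive class.
#'
#' @param records data frame with columns `group`, `menopause` and the
#'   metric columns produced by [run_pipeline()] (`fgt`, `bpe_v_1..3`,
#'   `bpe_i_1..3`); rows with missing metric values are dropped listwise.
#' @param metric `"fgt"`, `"bpe_v"` or `"bpe_i"`.
#' @param stratum `"pre"` or `"post"`.
#' @param phase 1-3 for the BPE metrics; ignored for `"fgt"`.
#' @return Data frame of class `bpe_comparison`, one row per contrast.
#' @export
compare_groups <- function(records, metric = c("fgt", "bpe_v", "bpe_i"),
                           stratum = c("pre", "post"), phase = NULL) {
  metric <- match.arg(metric)
  stratum <- match.arg(stratum)
  col <- if (metric == "fgt") "fgt" else {
    if (is.null(phase)) stop("phase required for BPE metrics")
    paste0(metric, "_", phase)
  }
  sub <- records[records$menopause == stratum & !is.na(records[[col]]), ,
                 drop = FALSE]
  if (nrow(sub) == 0) stop("empty stratum")
  vals <- split(sub[[col]], sub$group)
  for (g in c("cancer", "control", "benign")) {
    if (length(vals[[g]] %||% numeric(0)) < 2)
      stop(sprintf("need at least 2 records per group ('%s' short)", g))
  }
  one <- function(comparator) {
    mw <- mann_whitney_u(vals$cancer, vals[[comparator]])
    data.frame(metric = metric, stratum = stratum,
               phase = if (metric == "fgt") NA_integer_ else as.integer(phase),
               contrast = paste0("cancer_vs_", comparator),
               cancer_pct = 100 * stats::median(vals$cancer),
               comparator_pct = 100 * stats::median(vals[[comparator]]),
               n_cancer = length(vals$cancer),
               n_comparator = length(vals[[comparator]]),
               U = mw$U, p = mw$p,
               auc = empirical_auc(vals$cancer, vals[[comparator]]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("control"), one("benign"))
  class(out) <- c("bpe_comparison", "data.frame")
  out
}
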