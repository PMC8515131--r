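# Independent oracles used across the suite.  These deliberately use naive
# exhaustive computation so they share no code path with the package.

# all admissible boundary paths of a cost map, scored by brute force
enumerate_best_path <- function(cost_map, smoothness_limit = 1L,
                                prior_path = NULL,
                                lambda_smooth = 0.15, lambda_prior = 0.02) {
  nr <- nrow(cost_map); nc <- ncol(cost_map)
  paths <- matrix(seq_len(nr), ncol = 1)
  for (j in seq_len(nc - 1)) {
    grown <- list()
    for (d in seq(-smoothness_limit, smoothness_limit)) {
      nxt <- paths[, ncol(paths)] + d
      ok <- nxt >= 1 & nxt <= nr
      if (any(ok)) grown[[length(grown) + 1]] <- cbind(paths[ok, , drop = FALSE],
                                                       nxt[ok])
    }
    paths <- do.call(rbind, grown)
  }
  score <- function(p) {
    s <- sum(cost_map[cbind(p, seq_len(nc))]) +
      lambda_smooth * sum(abs(diff(p)))
    if (!is.null(prior_path)) s <- s + lambda_prior * sum(abs(p - prior_path))
    s
  }
  costs <- apply(paths, 1, score)
  list(cost = min(costs), path = paths[which.min(costs), ],
       n_optima = sum(abs(costs - min(costs)) < 1e-12))
}

# pair-counting AUC by explicit double loop over all pairs
brute_force_auc <- function(x, y) {
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  total / (length(x) * length(y))
}

# exact two-sided Mann-Whitney p by enumerating every group labelling
exact_mw_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); n <- length(pooled)
  u_of <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    total <- 0
    for (a in xs) for (b in ys) total <- total + (a > b) + 0.5 * (a == b)
    total
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# weighted FCM objective for fixed centroids with optimal memberships
fcm_objective_at <- function(values, centroids, m = 2) {
  d2 <- outer(values, centroids, function(a, b) (a - b)^2)
  u <- t(apply(d2, 1, function(row) {
    if (any(row == 0)) as.numeric(row == 0) / sum(row == 0)
    else { inv <- row^(-1 / (m - 1)); inv / sum(inv) }
  }))
  sum(u^m * d2)
}
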