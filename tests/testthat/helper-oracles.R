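# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# DTW cost by exhaustive enumeration of all monotone unit-step paths
# (feasible for very short series).
dtw_enumerate <- function(a, b) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    invisible()
  }
  recurse(1, 1, 0)
  best
}

# DTW cost by top-down memoised recursion (independent formulation of the
# same optimum; handles lengths ~12 comfortably)
dtw_recursive <- function(a, b) {
  memo <- array(NA_real_, dim = c(length(a), length(b)))
  go <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    c0 <- abs(a[i] - b[j])
    v <- if (i == 1 && j == 1) {
      c0
    } else if (i == 1) {
      c0 + go(i, j - 1)
    } else if (j == 1) {
      c0 + go(i - 1, j)
    } else {
      c0 + min(go(i - 1, j - 1), go(i - 1, j), go(i, j - 1))
    }
    memo[i, j] <<- v
    v
  }
  go(length(a), length(b))
}

# Hand sums-of-squares for a balanced two-way mixed design (a groups of
# ng subjects each, k within levels). Y: subjects x k matrix, group factor.
balanced_mixed_anova_oracle <- function(Y, group) {
  k <- ncol(Y)
  n <- nrow(Y)
  glev <- levels(group)
  ng <- unname(table(group)[1])
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, group, mean)
  cell_means <- do.call(rbind, lapply(glev, function(g) {
    colMeans(Y[group == g, , drop = FALSE])
  }))
  col_means <- colMeans(cell_means)
  ss_group <- k * sum(ng * (grp_means - grand)^2)
  ss_subj <- k * sum((subj_means - grp_means[group])^2)
  ss_news <- n * sum((col_means - grand)^2)
  ss_int <- ng * sum((cell_means - outer(grp_means, rep(1, k)) -
                        outer(rep(1, length(glev)), col_means) + grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err_w <- ss_tot - ss_group - ss_subj - ss_news - ss_int
  df_g <- length(glev) - 1
  df_s <- n - length(glev)
  df_n <- k - 1
  df_i <- df_g * df_n
  df_e <- df_s * df_n
  list(F_group = unname((ss_group / df_g) / (ss_subj / df_s)),
       F_news = unname((ss_news / df_n) / (ss_err_w / df_e)),
       F_int = unname((ss_int / df_i) / (ss_err_w / df_e)),
       df = c(group = df_g, subj = df_s, news = df_n, int = df_i,
              err = df_e))
}

# AUC by exhaustive concordant-pair counting
auc_pairs <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(ps) * length(ns))
}
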