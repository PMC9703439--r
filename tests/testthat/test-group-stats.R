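make_table <- function(Y, group) {
  conds <- c("negative", "neutral", "positive")
  do.call(rbind, lapply(seq_len(nrow(Y)), function(i) {
    data.frame(subject = sprintf("s%02d", i), group = group[i],
               news = conds, value = Y[i, ], stringsAsFactors = FALSE)
  }))
}

test_that("mixed ANOVA F values match hand-computed sums of squares", {
  # balanced 2 x 3 with n = 4 per group, constructed values
  set.seed(40)
  group <- factor(rep(c("depressed", "non-depressed"), each = 4))
  Y <- matrix(rnorm(24), 8) + outer(rep(1, 8), c(0, 1, 3)) +
    (as.integer(group) - 1.5) * 2
  oracle <- balanced_mixed_anova_oracle(Y, group)
  res <- mixed_anova(make_table(Y, as.character(group)))

  expect_equal(res$F[res$effect == "Group"], oracle$F_group,
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "News"], oracle$F_news,
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "Group:News"], oracle$F_int,
               tolerance = 1e-8)
  expect_equal(res$df1, c(1, 2, 2))
  expect_equal(res$df2, c(6, 12, 12))
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
})

test_that("group-effect p-values are calibrated under the null", {
  set.seed(41)
  ps <- replicate(400, {
    Y <- matrix(rnorm(30), 10)
    group <- sample(rep(c("a", "b"), each = 5))
    res <- mixed_anova(make_table(Y, group))
    res$p_uncorrected[res$effect == "Group"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("degenerate (constant) data returns F = 0 with a warning", {
  Y <- matrix(5, 6, 3)
  expect_warning(res <- mixed_anova(make_table(Y, rep(c("a", "b"), each = 3))),
                 "degenerate")
  expect_true(all(res$F == 0))
})

test_that("incomplete subjects are listwise excluded with a message", {
  set.seed(42)
  tab <- make_table(matrix(rnorm(18), 6), rep(c("a", "b"), each = 3))
  tab <- tab[-1, ]  # drop one cell of subject 1
  expect_message(res <- mixed_anova(tab), "excluding 1 subject")
  expect_equal(res$df2[res$effect == "Group"], 3)  # 5 subjects - 2
})

test_that("Greenhouse-Geisser epsilon respects its bounds and the sphericity limit", {
  # compound-symmetric (spherical) data -> epsilon ~ 1, Mauchly p large
  set.seed(43)
  n <- 40
  subj_eff <- rnorm(n, sd = 2)
  Y <- matrix(rnorm(3 * n), n) + subj_eff
  tab <- make_table(Y, rep(c("a", "b"), each = n / 2))
  expect_gt(gg_epsilon(tab), 0.9)
  expect_gt(mauchly_test(tab)$p, 0.05)

  # adversarial covariances stay within [1/(k-1), 1]
  for (s in 1:10) {
    set.seed(s)
    L <- matrix(rnorm(9), 3)
    Y2 <- matrix(rnorm(3 * 20), 20) %*% L
    e <- gg_epsilon(make_table(Y2, rep(c("a", "b"), each = 10)))
    expect_gte(e, 0.5)
    expect_lte(e, 1)
  }

  # own formula agrees with the multivariate-model implementation
  set.seed(44)
  Y3 <- matrix(rnorm(60), 20) %*% matrix(c(1, .8, 0, 0, 1, .2, 0, 0, 1), 3)
  tab3 <- make_table(Y3, rep(c("a", "b"), each = 10))
  res3 <- mixed_anova(tab3)
  expect_equal(gg_epsilon(tab3), res3$epsilon[res3$effect == "News"],
               tolerance = 1e-6)
})

test_that("aligned rank transform strips non-target effects", {
  # constructed cell means: news effect only
  groups <- rep(c("a", "b"), each = 6)
  conds <- c("negative", "neutral", "positive")
  news_eff <- c(negative = -2, neutral = 0, positive = 2)
  set.seed(45)
  tab <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(subject = sprintf("s%02d", i), group = groups[i],
               news = conds, value = news_eff + rnorm(3, sd = .2),
               stringsAsFactors = FALSE)
  }))
  art_news <- aligned_rank_transform(tab, "news")
  # rank ordering of news means survives alignment
  rmeans <- tapply(art_news$art_rank, art_news$news, mean)
  expect_true(rmeans["negative"] < rmeans["neutral"] &&
                rmeans["neutral"] < rmeans["positive"])

  # ART-for-group on noise-free news-only data: aligned values contain no
  # group signal (group means of aligned data equal)
  tab0 <- tab
  tab0$value <- news_eff[tab0$news]  # noise-free
  art_g <- aligned_rank_transform(tab0, "group")
  gm <- tapply(art_g$aligned, art_g$group, mean)
  expect_equal(unname(gm[1]), unname(gm[2]), tolerance = 1e-12)
  # and the ANOVA on those ranks shows a null group effect
  res <- suppressWarnings(mixed_anova(art_g, value = "art_rank"))
  expect_lt(res$F[res$effect == "Group"], 1e-8)

  # constant data -> all midranks equal
  tabc <- tab
  tabc$value <- 7
  artc <- aligned_rank_transform(tabc, "news")
  expect_true(all(artc$art_rank == mean(artc$art_rank)))
})

test_that("ART interaction F is not inflated by a pure news main effect", {
  set.seed(46)
  ps <- replicate(150, {
    tab <- null_rating_table(6)
    tab$value <- tab$value + c(negative = -0.5, neutral = 0,
                               positive = 0.5)[tab$news]
    art <- aligned_rank_transform(tab, "interaction")
    res <- mixed_anova(art, value = "art_rank")
    res$p_uncorrected[res$effect == "Group:News"]
  })
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("post-hoc families follow significance gating with Bonferroni", {
  # strong interaction: group b reverses the news effect
  set.seed(47)
  groups <- rep(c("a", "b"), each = 10)
  Y <- matrix(rnorm(60, sd = .3), 20)
  Y[groups == "a", ] <- Y[groups == "a", ] +
    matrix(c(-2, 0, 2), 10, 3, byrow = TRUE)
  Y[groups == "b", ] <- Y[groups == "b", ] +
    matrix(c(2, 0, -2), 10, 3, byrow = TRUE)
  tab <- make_table(Y, groups)
  res <- mixed_anova(tab)
  ph <- posthoc_contrasts(tab, res)
  expect_true(any(ph$kind == "paired"))
  expect_true(any(ph$kind == "unpaired"))
  # 2 groups x 3 pairs + 3 between-group contrasts
  expect_equal(nrow(ph[grepl(":", ph$contrast), ]), 9)

  # identical paired samples give t = 0, p = 1
  r <- moodtrf:::.t_row(c(1, 2, 3), c(1, 2, 3), TRUE, "x", 3)
  expect_equal(r$t, 0)
  expect_equal(r$p_bonferroni, 1)

  # Bonferroni multiplies and clamps
  set.seed(48)
  x <- rnorm(20); y <- x + rnorm(20, 0.4, 0.5)
  raw <- t.test(x, y, paired = TRUE)$p.value
  r2 <- moodtrf:::.t_row(x, y, TRUE, "x", 3)
  expect_equal(r2$p_bonferroni, min(raw * 3, 1), tolerance = 1e-12)

  # nothing significant -> empty table
  set.seed(49)
  tab0 <- make_table(matrix(rnorm(30), 10), rep(c("a", "b"), each = 5))
  res0 <- mixed_anova(tab0)
  if (all(res0$p > 0.05)) expect_equal(nrow(posthoc_contrasts(tab0, res0)), 0)
})

test_that("chi-square independence matches hand computation and edge cases", {
  # identical column proportions -> 0
  even <- cbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi2_independence(even)$chi2, 0, tolerance = 1e-12)

  # 2x2 hand computation
  tab <- rbind(c(10, 20), c(20, 10))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi2_independence(tab)$chi2, sum((tab - E)^2 / E))
  expect_equal(chi2_independence(tab)$df, 1)
})

test_that("independent t and Cohen's d follow the pooled closed forms", {
  r <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$cohens_d, 0)

  set.seed(50)
  x <- rnorm(12, 1); y <- rnorm(15)
  r2 <- independent_t(x, y)
  sp <- sqrt(((11) * var(x) + (14) * var(y)) / 25)
  expect_equal(r2$t, (mean(x) - mean(y)) / (sp * sqrt(1 / 12 + 1 / 15)))
  expect_equal(r2$df, 25)
  expect_equal(r2$cohens_d, (mean(x) - mean(y)) / sp)
  expect_equal(r2$p, t.test(x, y, var.equal = TRUE)$p.value)

  # shift equivariance
  r3 <- independent_t(x + 2, y)
  expect_equal(r3$mean_diff, r2$mean_diff + 2)
})

test_that("ANOVA detects group-by-news latency interactions at study scale", {
  # measure-level power check: injected 21 ms shift for positive news in
  # the depressed group, between/within noise at pipeline scale
  set.seed(51)
  hits <- replicate(60, {
    n_dep <- 32; n_non <- 103
    base <- 130
    Y <- rbind(
      matrix(base + rnorm(n_dep * 3, sd = 25), n_dep),
      matrix(base + rnorm(n_non * 3, sd = 25), n_non))
    Y[seq_len(n_dep), 3] <- Y[seq_len(n_dep), 3] + 21
    tab <- make_table(Y, rep(c("depressed", "non-depressed"),
                             c(n_dep, n_non)))
    res <- mixed_anova(tab)
    res$p[res$effect == "Group:News"] < 0.05
  })
  expect_gt(mean(hits), 0.5)
})
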