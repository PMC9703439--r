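#' Aligned rank transform for a two-factor mixed design
#'
#' For the chosen target effect, every estimated effect *except* the target
#' is subtracted from each observation (cell-mean decomposition with
#' unweighted cell means), and the aligned values are midranked. Running a
#' standard ANOVA on the ranks of the aligned-for-X data then tests effect
#' X nonparametrically; the other effects are stripped to (near) zero.
#'
#' @param table data.frame with columns subject, group, news, value
#'   (complete: every subject once per news level).
#' @param effect `"group"`, `"news"` or `"interaction"`.
#' @return The input table with extra columns `aligned` and `art_rank`.
#' @export
aligned_rank_transform <- function(table, effect = c("group", "news",
                                                     "interaction")) {
  effect <- match.arg(effect)
  .check_factorial(table)
  g <- as.character(table$group)
  j <- as.character(table$news)
  cell <- paste(g, j, sep = ":")
  cmeans <- tapply(table$value, list(g, j), mean)
  if (anyNA(cmeans)) stop("missing cells in the factorial table")
  mu <- mean(cmeans)
  a <- rowMeans(cmeans) - mu          # group effects
  b <- colMeans(cmeans) - mu          # news effects
  ab <- sweep(sweep(cmeans - mu, 1, a), 2, b)  # interaction effects
  resid <- table$value - cmeans[cbind(g, j)]
  target <- switch(effect,
                   group = a[g],
                   news = b[j],
                   interaction = ab[cbind(g, j)])
  out <- table
  out$aligned <- resid + target
  out$art_rank <- rank(out$aligned, ties.method = "average")
  out
}

.check_factorial <- function(table) {
  stopifnot(all(c("subject", "group", "news", "value") %in% names(table)))
  tab <- table(table$subject, table$news)
  if (any(tab != 1)) {
    stop("each subject must appear exactly once per news level")
  }
  gr <- tapply(as.character(table$group), table$subject,
               function(x) length(unique(x)))
  if (any(gr != 1)) stop("each subject must belong to exactly one group")
  invisible(TRUE)
}

# wide (subject x news) layout plus group vector; listwise-excludes
# subjects with missing levels
.factorial_wide <- function(table) {
  news_levels <- c("negative", "neutral", "positive")
  if (!all(table$news %in% news_levels)) {
    news_levels <- sort(unique(as.character(table$news)))
  }
  keep <- names(which(tapply(table$news, table$subject, function(x) {
    all(news_levels %in% x)
  })))
  dropped <- setdiff(unique(as.character(table$subject)), keep)
  if (length(dropped)) {
    message("excluding ", length(dropped),
            " subject(s) with incomplete within-subject data")
    table <- table[table$subject %in% keep, ]
  }
  wide <- matrix(NA_real_, nrow = length(keep), ncol = length(news_levels),
                 dimnames = list(keep, news_levels))
  wide[cbind(as.character(table$subject), as.character(table$news))] <-
    table$value
  group <- factor(tapply(as.character(table$group), table$subject,
                         `[`, 1)[keep])
  list(Y = wide, group = group, news_levels = news_levels)
}

#' Two-way mixed-design ANOVA
#'
#' Between-subjects factor Group (2 levels, unbalanced allowed),
#' within-subjects factor News (3 levels). Type-III (unweighted-cell-means)
#' sums of squares via a multivariate linear model with sum-to-zero
#' contrasts. Greenhouse-Geisser epsilon and Mauchly's sphericity test are
#' computed for the within effects; the reported p is Greenhouse-Geisser
#' corrected only when Mauchly's test rejects at 0.05 (the original degrees
#' of freedom and epsilon are always reported alongside). Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table data.frame with columns subject, group, news, value.
#' @param value optional column name to analyse instead of `value`.
#' @return data.frame with one row per effect (Group, News, Group:News):
#'   F, df1, df2, epsilon, p (sphericity-aware), p_uncorrected, p_gg,
#'   mauchly_w, mauchly_p, partial_eta_sq.
#' @export
mixed_anova <- function(table, value = "value") {
  table$value <- table[[value]]
  fw <- .factorial_wide(table)
  Y <- fw$Y
  group <- fw$group
  k <- ncol(Y)
  degenerate <- all(apply(Y, 2, var) < 1e-300) ||
    diff(range(Y)) == 0
  res <- try(silent = TRUE, {
    dat <- data.frame(group = group)
    fit <- lm(Y ~ group, data = dat,
              contrasts = list(group = "contr.sum"))
    av <- car::Anova(fit, idata = data.frame(news = factor(fw$news_levels)),
                     idesign = ~news, type = 3)
    suppressWarnings(summary(av, multivariate = FALSE))
  })
  if (inherits(res, "try-error") || degenerate) {
    warning("degenerate factorial data; returning F = 0 for all effects")
    return(data.frame(effect = c("Group", "News", "Group:News"), F = 0,
                      df1 = c(1, k - 1, k - 1),
                      df2 = c(nlevels(group) * 0 + length(group) - 2,
                              rep((length(group) - 2) * (k - 1), 2)),
                      epsilon = NA_real_, p = NA_real_,
                      p_uncorrected = NA_real_, p_gg = NA_real_,
                      mauchly_w = NA_real_, mauchly_p = NA_real_,
                      partial_eta_sq = 0, stringsAsFactors = FALSE))
  }
  uni <- res$univariate.tests
  sph <- res$sphericity.tests
  adj <- res$pval.adjustments
  grab <- function(row) {
    c(ss = uni[row, "Sum Sq"], df1 = uni[row, "num Df"],
      ess = uni[row, "Error SS"], df2 = uni[row, "den Df"],
      F = uni[row, "F value"], p = uni[row, "Pr(>F)"])
  }
  rows <- list(Group = grab("group"), News = grab("news"),
               `Group:News` = grab("group:news"))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    v <- rows[[nm]]
    is_within <- nm != "Group"
    eps <- mw <- mp <- pgg <- NA_real_
    if (is_within) {
      key <- if (nm == "News") "news" else "group:news"
      if (!is.null(sph) && key %in% rownames(sph)) {
        mw <- sph[key, "Test statistic"]
        mp <- sph[key, "p-value"]
      }
      if (!is.null(adj) && key %in% rownames(adj)) {
        eps <- adj[key, "GG eps"]
        pgg <- adj[key, "Pr(>F[GG])"]
      }
    }
    p_report <- if (is_within && !is.na(mp) && mp < 0.05 && !is.na(pgg)) {
      pgg
    } else {
      v[["p"]]
    }
    data.frame(effect = nm, F = v[["F"]], df1 = v[["df1"]],
               df2 = v[["df2"]], epsilon = eps, p = p_report,
               p_uncorrected = v[["p"]], p_gg = pgg, mauchly_w = mw,
               mauchly_p = mp,
               partial_eta_sq = v[["ss"]] / (v[["ss"]] + v[["ess"]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Greenhouse-Geisser epsilon
#'
#' Computed from the pooled within-group covariance of the repeated
#' measures (group means removed before pooling). Bounded between
#' `1/(k - 1)` and 1; equals 1 under perfect sphericity.
#'
#' @param table factorial data.frame (subject, group, news, value).
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(table) {
  fw <- .factorial_wide(table)
  Y <- fw$Y
  k <- ncol(Y)
  if (k < 3) return(1)
  resid <- do.call(rbind, lapply(levels(fw$group), function(g) {
    sweep(Y[fw$group == g, , drop = FALSE], 2,
          colMeans(Y[fw$group == g, , drop = FALSE]))
  }))
  S <- crossprod(resid) / (nrow(Y) - nlevels(fw$group))
  sbar <- mean(S)
  dbar <- mean(diag(S))
  rbar <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rbar^2) + k^2 * sbar^2)
  eps <- num / den
  min(max(eps, 1 / (k - 1)), 1)
}

#' Mauchly's test of sphericity
#'
#' @param table factorial data.frame (subject, group, news, value).
#' @return List with `W` (test statistic) and `p`.
#' @export
mauchly_test <- function(table) {
  fw <- .factorial_wide(table)
  dat <- data.frame(group = fw$group)
  fit <- lm(fw$Y ~ group, data = dat,
            contrasts = list(group = "contr.sum"))
  av <- car::Anova(fit, idata = data.frame(news = factor(fw$news_levels)),
                   idesign = ~news, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  list(W = s$sphericity.tests["news", "Test statistic"],
       p = s$sphericity.tests["news", "p-value"])
}

# paired / unpaired t helper returning a posthoc row
.t_row <- function(x, y, paired, contrast, family) {
  if (paired) {
    d <- x - y
    n <- length(d)
    t <- if (sd(d) == 0) 0 else mean(d) / (sd(d) / sqrt(n))
    df <- n - 1
  } else {
    res <- independent_t(x, y)
    t <- res$t
    df <- res$df
  }
  p_raw <- if (t == 0 && paired) 1 else 2 * pt(-abs(t), df)
  data.frame(contrast = contrast, t = t, df = df,
             p_bonferroni = min(p_raw * family, 1),
             kind = if (paired) "paired" else "unpaired",
             stringsAsFactors = FALSE)
}

#' Post-hoc contrasts after a mixed ANOVA
#'
#' Run only for effects significant at `alpha`. A significant News main
#' effect triggers paired t tests across the three condition pairs (all
#' subjects; Bonferroni family of 3). A significant Group x News
#' interaction triggers paired t tests across condition pairs within each
#' group (family of 3 per group) and unpaired t tests between groups per
#' condition (family of 3).
#'
#' @param table factorial data.frame.
#' @param anova result of [mixed_anova()].
#' @param alpha significance level gating each family (default 0.05).
#' @return data.frame of contrasts (possibly empty): contrast, t, df,
#'   p_bonferroni, kind.
#' @export
posthoc_contrasts <- function(table, anova, alpha = 0.05) {
  fw <- .factorial_wide(table)
  Y <- fw$Y
  group <- fw$group
  conds <- fw$news_levels
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  out <- list()
  p_of <- function(eff) anova$p[anova$effect == eff]
  if (isTRUE(p_of("News") < alpha) && !isTRUE(p_of("Group:News") < alpha)) {
    for (pr in pairs) {
      out[[length(out) + 1]] <- .t_row(Y[, pr[1]], Y[, pr[2]], TRUE,
                                       paste(pr[1], "vs", pr[2]), 3)
    }
  }
  if (isTRUE(p_of("Group:News") < alpha)) {
    for (g in levels(group)) {
      sel <- group == g
      for (pr in pairs) {
        out[[length(out) + 1]] <- .t_row(
          Y[sel, pr[1]], Y[sel, pr[2]], TRUE,
          paste0(g, ": ", pr[1], " vs ", pr[2]), 3)
      }
    }
    gl <- levels(group)
    for (cond in conds) {
      out[[length(out) + 1]] <- .t_row(
        Y[group == gl[1], cond], Y[group == gl[2], cond], FALSE,
        paste0(cond, ": ", gl[1], " vs ", gl[2]), 3)
    }
  }
  if (!length(out)) {
    return(data.frame(contrast = character(0), t = numeric(0),
                      df = numeric(0), p_bonferroni = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chi-square test of independence with Cramer's V
#'
#' Asymptotic chi-square (no continuity correction), expected counts from
#' the margins; `V = sqrt(chi2 / (N * (min(r, c) - 1)))`.
#'
#' @param counts 2-D contingency table of non-negative counts.
#' @return List: chi2, df, p, cramers_v, expected.
#' @export
chi2_independence <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), length(dim(counts)) == 2)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  n <- sum(counts)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       cramers_v = sqrt(unname(ct$statistic) /
                          (n * (min(dim(counts)) - 1))),
       expected = ct$expected)
}

#' Independent-samples t test with Cohen's d
#'
#' Pooled-variance t with `df = n1 + n2 - 2`; d is the mean difference over
#' the pooled standard deviation.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return List: t, df, p, cohens_d, mean_diff.
#' @export
independent_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  md <- mean(x) - mean(y)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else md / se
  df <- n1 + n2 - 2
  list(t = t, df = df, p = if (t == 0) 1 else 2 * pt(-abs(t), df),
       cohens_d = if (sp2 == 0) 0 else md / sqrt(sp2), mean_diff = md)
}
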