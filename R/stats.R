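# --- the statistical battery ------------------------------------------------
#
# Classical within-subject machinery: one-sample and paired t with Cohen's
# d, repeated-measures ANOVA with partial eta-squared (via aov with an
# Error stratum), Bonferroni-adjusted pairwise t, Pearson between-system
# consistency, Wilcoxon / Friedman / Mann-Whitney, and the bootstrap
# standardized measurement error. Effect sizes are reported as absolute
# values.

new_stat_result <- function(test, statistic, df, p, effect_size,
                            effect_name = "cohens_d", adjusted = "none",
                            extra = list()) {
  structure(c(list(test = test, statistic = unname(statistic), df = df,
                   p = unname(min(max(p, 0), 1)),
                   effect_size = unname(abs(effect_size)),
                   effect_name = effect_name, adjusted = adjusted), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: stat=%.3f, df=%s, p=%.4g, %s=%.3f (%s)\n", x$test,
              x$statistic, paste(round(x$df, 2), collapse = ","), x$p,
              x$effect_name, x$effect_size, x$adjusted))
  invisible(x)
}

#' One-sample t-test with Cohen's d
#'
#' Classical t against `mu` with `df = n - 1`;
#' `d = |mean - mu| / sd` (so `d = |t| / sqrt(n)`).
#'
#' @param values Numeric vector (NAs dropped).
#' @param mu Null value.
#' @param tails `"two"` or `"one"` (one-tailed in the direction of the
#'   observed mean difference).
#' @return A `stat_result`.
#' @export
one_sample_t <- function(values, mu = 0, tails = c("two", "one")) {
  tails <- match.arg(tails)
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2) stop_invalid("need at least 2 observations")
  ht <- stats::t.test(x, mu = mu)
  p <- if (tails == "one") ht$p.value / 2 else ht$p.value
  d <- abs(mean(x) - mu) / stats::sd(x)
  new_stat_result("one_sample_t", ht$statistic, n - 1, p, d,
                  extra = list(mean = mean(x), se = stats::sd(x) / sqrt(n),
                               tails = tails))
}

#' Paired t-test with Cohen's d for paired designs
#'
#' `d = |mean(diff)| / sd(diff)`.
#'
#' @param x,y Paired numeric vectors; pairs with NA are dropped.
#' @return A `stat_result`.
#' @export
paired_t <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop_invalid("need at least 2 complete pairs")
  ht <- stats::t.test(d, mu = 0)
  new_stat_result("paired_t", ht$statistic, n - 1, ht$p.value,
                  abs(mean(d)) / stats::sd(d))
}

# long table -> participant x cell wide matrix with listwise deletion;
# cell columns ordered lexicographically (first factor slowest)
complete_wide <- function(table, dv, within) {
  table[within] <- lapply(table[within], as.character)
  f <- interaction(table[within], drop = TRUE, lex.order = TRUE)
  wide <- tapply(table[[dv]], list(table$participant, f), mean)
  wide[stats::complete.cases(wide), , drop = FALSE]
}

#' Repeated-measures ANOVA with partial eta-squared
#'
#' One or two within-subject factors, fit with `aov` using the
#' participant Error stratum (no sphericity correction by default, per the
#' plain integer degrees of freedom convention;
#' `partial eta^2 = SS_effect / (SS_effect + SS_error)`). Participants
#' with any missing cell are removed listwise.
#'
#' @param table Long-format data frame with columns `participant`, the
#'   factor columns, and the dependent variable.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of 1 or 2 within-subject factor columns.
#' @return A list of `stat_result`s, one per effect (main effects and, for
#'   two factors, their interaction).
#' @export
rm_anova <- function(table, dv, within) {
  stopifnot(length(within) %in% 1:2, all(c("participant", within, dv) %in%
                                           names(table)))
  wide <- complete_wide(table, dv, within)
  n_sub <- nrow(wide)
  if (n_sub < 3) stop_invalid("need >= 3 complete participants")
  lv <- lapply(within, function(w) sort(unique(as.character(table[[w]]))))
  if (any(vapply(lv, length, 0L) < 2)) stop_invalid("factors need >= 2 levels")

  cells <- expand.grid(rev(lv), stringsAsFactors = FALSE)[, rev(seq_along(lv)),
                                                          drop = FALSE]
  names(cells) <- within
  long <- data.frame(
    participant = factor(rep(rownames(wide), times = ncol(wide))),
    value = as.vector(wide)
  )
  for (w in within) {
    long[[w]] <- factor(rep(cells[[w]], each = n_sub))
  }
  rhs <- paste(within, collapse = " * ")
  err <- if (length(within) == 1) {
    sprintf("Error(participant/%s)", within)
  } else {
    sprintf("Error(participant/(%s))", paste(within, collapse = " * "))
  }
  fml <- stats::as.formula(sprintf("value ~ %s + %s", rhs, err))
  fit <- stats::aov(fml, data = long)
  sm <- summary(fit)

  results <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    res_i <- which(rn == "Residuals")
    if (length(res_i) == 0) next
    ss_err <- tab[res_i, "Sum Sq"]
    df_err <- tab[res_i, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), res_i)) {
      eff <- rn[i]
      ss <- tab[i, "Sum Sq"]
      fval <- tab[i, "F value"]
      pval <- tab[i, "Pr(>F)"]
      eta <- ss / (ss + ss_err)
      if (ss < 1e-12) {  # degenerate all-equal data: no effect
        fval <- 0; pval <- 1; eta <- 0
      }
      results[[eff]] <- new_stat_result(
        paste0("rm_anova:", eff), fval,
        c(tab[i, "Df"], df_err), pval,
        eta, effect_name = "partial_eta_sq",
        extra = list(ss_effect = ss, ss_error = ss_err, n = n_sub))
    }
  }
  results
}

#' Pairwise paired t-tests with Bonferroni adjustment
#'
#' One paired t per level pair of `factor`;
#' `p_adj = min(1, p * n_comparisons)`.
#'
#' @param table Long-format data frame (`participant`, `factor` column,
#'   dv).
#' @param dv Dependent-variable column name.
#' @param factor_col Factor column name.
#' @return List of `stat_result`s named `"A-B"`, each with `p` adjusted
#'   and `p_unadjusted` retained.
#' @export
pairwise_t_bonferroni <- function(table, dv, factor_col) {
  wide <- complete_wide(table, dv, factor_col)
  levs <- colnames(wide)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  out <- list()
  for (pr in pairs) {
    r <- paired_t(wide[, pr[1]], wide[, pr[2]])
    r$p_unadjusted <- r$p
    r$p <- min(1, r$p * m)
    r$adjusted <- sprintf("bonferroni(m=%d)", m)
    r$test <- sprintf("paired_t:%s-%s", pr[1], pr[2])
    out[[paste(pr, collapse = "-")]] <- r
  }
  out
}

#' Pearson between-system consistency
#'
#' Correlation over participants present in both systems, with the
#' two-sided significance test.
#'
#' @param table Long table (`participant`, `system`, dv).
#' @param dv Dependent-variable column.
#' @param system_pair Length-2 character vector of system names.
#' @return A `stat_result` with `effect_size = |r|` and `r` (signed) in
#'   `$r`.
#' @export
pearson_consistency <- function(table, dv, system_pair) {
  stopifnot(length(system_pair) == 2)
  sub <- table[table$system %in% system_pair, c("participant", "system", dv)]
  wide <- complete_wide(sub, dv, "system")
  if (nrow(wide) < 3) stop_invalid("need >= 3 participants in both systems")
  ct <- stats::cor.test(wide[, 1], wide[, 2])
  r <- unname(ct$estimate)
  new_stat_result("pearson", ct$statistic, unname(ct$parameter), ct$p.value,
                  r, effect_name = "abs_r", extra = list(r = r, n = nrow(wide)))
}

#' Critical |r| for a two-sided Pearson test
#'
#' @param n Number of pairs.
#' @param alpha Significance level.
#' @return The smallest |r| reaching significance.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Wilcoxon signed-rank test
#'
#' Exact p for small samples without ties (base implementation), normal
#' approximation with continuity/tie correction otherwise. All-zero
#' difference pairs are dropped and reported.
#'
#' @param x,y Paired numeric vectors.
#' @return A `stat_result` with the rank-biserial correlation as effect
#'   size.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  d <- x[ok] - y[ok]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0) {
    return(new_stat_result("wilcoxon_signed_rank", NA_real_, length(x), 1, 0,
                           effect_name = "rank_biserial",
                           extra = list(n_dropped_zero = n_zero)))
  }
  ht <- suppressWarnings(stats::wilcox.test(d, mu = 0,
                                            exact = length(d) <= 12,
                                            correct = TRUE))
  v <- unname(ht$statistic)
  n <- length(d)
  rb <- 2 * v / (n * (n + 1)) - 1  # rank-biserial from V
  new_stat_result("wilcoxon_signed_rank", v, n, ht$p.value, rb,
                  effect_name = "rank_biserial",
                  extra = list(n_dropped_zero = n_zero))
}

#' Friedman test across >= 3 within-subject conditions
#'
#' @param mat Participants x conditions numeric matrix (complete cases
#'   used).
#' @return A `stat_result` with Kendall's W as effect size.
#' @export
friedman <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  ht <- stats::friedman.test(mat)
  n <- nrow(mat); k <- ncol(mat)
  w <- unname(ht$statistic) / (n * (k - 1))  # Kendall's W
  new_stat_result("friedman", ht$statistic, unname(ht$parameter),
                  ht$p.value, w, effect_name = "kendalls_w",
                  extra = list(n = n, k = k))
}

#' Mann-Whitney U test (two independent samples)
#'
#' @param x,y Numeric vectors.
#' @return A `stat_result` with the common-language effect size
#'   `U / (n_x * n_y)`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = length(x) <= 12 && length(y) <= 12,
                       correct = TRUE))
  u <- unname(ht$statistic)
  new_stat_result("mann_whitney", u, c(length(x), length(y)), ht$p.value,
                  u / (length(x) * length(y)), effect_name = "cles")
}

#' Bootstrap standardized measurement error
#'
#' For one participant's epoch set: resample the retained epochs with
#' replacement `n_boot` times, recompute the scored measure on each
#' bootstrap average, and return the standard deviation of the scores.
#' Smaller SME means a more precise single-participant measure.
#'
#' @param ep An `epoch_set` (or plain trials x samples matrix for a
#'   single-channel measure).
#' @param measure_fn Function taking an [erp_waveform()] (or, for a
#'   matrix input, the averaged numeric vector) and returning a scalar.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param label Optional condition label restricting the epochs used.
#' @return Scalar SME (same units as the measure), with attribute
#'   `scores` (the bootstrap distribution).
#' @export
sme_bootstrap <- function(ep, measure_fn, n_boot = 1000, seed = 1,
                          label = NULL) {
  if (is.matrix(ep)) {
    n <- nrow(ep)
    if (n < 2) stop_invalid("SME needs >= 2 epochs")
    scores <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      measure_fn(colMeans(ep[sample.int(n, n, replace = TRUE), ,
                             drop = FALSE]))
    }, 0))
  } else {
    stopifnot(inherits(ep, "epoch_set"))
    keep <- !ep$rejected
    if (!is.null(label)) keep <- keep & ep$labels == label
    idx <- which(keep)
    n <- length(idx)
    if (n < 2) stop_invalid("SME needs >= 2 retained epochs")
    d <- dim(ep$data)
    flat <- matrix(ep$data[idx, , , drop = FALSE], nrow = n)  # trials x (ch*samp)
    scores <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      avg <- colMeans(flat[sample.int(n, n, replace = TRUE), , drop = FALSE])
      w <- erp_waveform(matrix(avg, d[2], d[3]), ep$tmin_ms, ep$tmax_ms,
                        ep$rate_hz, ep$channel_names,
                        condition = label %||% "bootstrap",
                        n_epochs_averaged = n)
      measure_fn(w)
    }, 0))
  }
  out <- stats::sd(scores)
  attr(out, "scores") <- scores
  out
}
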