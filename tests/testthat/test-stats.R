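# the statistical battery

test_that("one-sample t matches the textbook formula and d = t/sqrt(n)", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)))  # mean 2, sd 1, n 3
  expect_equal(r$effect_size, 2)
  expect_equal(r$effect_size, r$statistic / sqrt(3))
  expect_equal(r$df, 2)

  same <- one_sample_t(c(5, 5.1, 4.9, 5), mu = 5)
  expect_equal(same$statistic, 0, tolerance = 1e-10)

  one_tail <- one_sample_t(c(1, 2, 3), tails = "one")
  expect_equal(one_tail$p, r$p / 2)
})

test_that("rm_anova recovers sums of squares and partial eta squared", {
  # identical values across levels: no effect at all
  tab <- data.frame(participant = rep(1:4, 3),
                    system = rep(c("A", "B", "C"), each = 4),
                    value = rep(c(1, 2, 3, 4), 3))
  r <- rm_anova(tab, "value", "system")$system
  expect_equal(r$statistic, 0)
  expect_equal(r$effect_size, 0)

  # two levels: F equals the paired t squared
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8) + 1
  tab2 <- data.frame(participant = rep(1:8, 2),
                     system = rep(c("A", "B"), each = 8),
                     value = c(x, y))
  fa <- rm_anova(tab2, "value", "system")$system
  tt <- paired_t(x, y)
  expect_equal(fa$statistic, tt$statistic^2, tolerance = 1e-8)
  expect_equal(fa$p, tt$p, tolerance = 1e-8)

  # partial eta^2 against a brute-force sums-of-squares oracle
  set.seed(4)
  n <- 10; k <- 3
  vals <- matrix(rnorm(n * k) + rep(c(0, 1, 2), each = n), n, k)
  tab3 <- data.frame(participant = rep(1:n, k),
                     system = rep(letters[1:k], each = n),
                     value = as.vector(vals))
  r3 <- rm_anova(tab3, "value", "system")$system
  gm <- mean(vals)
  ss_cond <- n * sum((colMeans(vals) - gm)^2)
  ss_subj <- k * sum((rowMeans(vals) - gm)^2)
  ss_tot <- sum((vals - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  expect_equal(r3$ss_effect, ss_cond, tolerance = 1e-10)
  expect_equal(r3$ss_error, ss_err, tolerance = 1e-10)
  expect_equal(r3$effect_size, ss_cond / (ss_cond + ss_err), tolerance = 1e-10)
  expect_equal(r3$df, c(k - 1, (n - 1) * (k - 1)))
})

test_that("a two-factor within design reports both mains and the interaction", {
  set.seed(5)
  d <- expand.grid(participant = 1:6, system = c("EM", "LA", "BA"),
                   condition = c("6Hz", "10Hz", "15Hz"))
  d$value <- rnorm(nrow(d)) + as.integer(factor(d$system))
  rs <- rm_anova(d, "value", c("system", "condition"))
  expect_setequal(names(rs), c("system", "condition", "system:condition"))
  expect_equal(rs$system$df, c(2, 10))
  expect_true(rs$system$p < 0.05)
})

test_that("Bonferroni pairwise t tests clip and never shrink p", {
  set.seed(6)
  tab <- data.frame(participant = rep(1:7, 3),
                    system = rep(c("A", "B", "C"), each = 7),
                    value = rnorm(21))
  out <- pairwise_t_bonferroni(tab, "value", "system")
  expect_equal(length(out), 3)
  for (r in out) {
    expect_equal(r$p, min(1, r$p_unadjusted * 3))
    expect_gte(r$p, r$p_unadjusted)
  }
  # hand check of one comparison
  wide <- tapply(tab$value, list(tab$participant, tab$system), mean)
  tt <- t.test(wide[, "A"] - wide[, "B"])
  expect_equal(out[["A-B"]]$statistic, unname(tt$statistic))
})

test_that("Pearson consistency and the critical r threshold agree", {
  tab <- data.frame(participant = rep(1:10, 2),
                    system = rep(c("EM", "BA"), each = 10),
                    value = c(1:10, 1:10))
  expect_equal(pearson_consistency(tab, "value", c("EM", "BA"))$r, 1)
  tab$value[11:20] <- -(1:10)
  expect_equal(pearson_consistency(tab, "value", c("EM", "BA"))$r, -1)
  expect_equal(round(critical_r(18), 2), 0.47)
})

test_that("nonparametric tests match base implementations and boundaries", {
  same <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$n_dropped_zero, 3)

  set.seed(7)
  x <- rnorm(9); y <- rnorm(9) + 0.5
  w <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x - y, exact = TRUE)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p, ref$p.value)

  # Friedman vs a brute-force rank computation
  m <- matrix(c(1, 3, 2, 2, 3, 1, 1, 2, 3, 1, 3, 2), 4, 3, byrow = TRUE)
  fr <- friedman(m)
  rk <- t(apply(m, 1, rank))
  n <- 4; k <- 3
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(rk)^2) - 3 * n * (k + 1)
  expect_equal(fr$statistic, stat)

  mw <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$statistic, 0)
  expect_equal(mann_whitney(c(10, 11, 12), c(1, 2, 3))$statistic, 9)
})

test_that("the bootstrap SME is zero for identical epochs and tracks sigma/sqrt(n)", {
  ident <- matrix(5, 30, 16)
  expect_equal(as.numeric(sme_bootstrap(ident, mean, n_boot = 50, seed = 1)),
               0)

  # averaged over datasets: the SME of a mean-amplitude measure on i.i.d.
  # noise approaches sigma / sqrt(n_values)
  set.seed(8)
  n_tr <- 40; sigma <- 6
  smes <- vapply(1:10, function(i) {
    ep <- matrix(rnorm(n_tr * 12, 0, sigma), n_tr, 12)
    as.numeric(sme_bootstrap(ep, mean, n_boot = 300, seed = i))
  }, 0)
  analytic <- sigma / sqrt(n_tr * 12)
  expect_lt(abs(mean(smes) / analytic - 1), 0.1)
  ep <- matrix(rnorm(n_tr * 12, 0, sigma), n_tr, 12)

  # reproducible given the seed
  expect_equal(as.numeric(sme_bootstrap(ep, mean, n_boot = 100, seed = 3)),
               as.numeric(sme_bootstrap(ep, mean, n_boot = 100, seed = 3)))
  expect_error(sme_bootstrap(ep[1, , drop = FALSE], mean), ">= 2")
})

test_that("SME works on epoch sets with an ERP measure function", {
  set.seed(9)
  arr <- array(rnorm(40 * 2 * 32, 0, 4), dim = c(40, 2, 32))
  ep <- epochs_fixture(arr, rep(c("standard", "deviant"), 20), rate_hz = 128,
                       tmin_ms = 0)
  sme <- sme_bootstrap(ep, function(w) {
    find_peak(w, "ch1", c(100, 200), "negative")$amplitude_uv
  }, n_boot = 200, seed = 4, label = "deviant")
  expect_gt(as.numeric(sme), 0)
  expect_equal(length(attr(sme, "scores")), 200)
})
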