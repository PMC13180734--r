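# Mixed models, partial correlations, bootstrap comparison, E-values and
# the caffeine analyses.

make_table <- function(n = 120, seed = 1, beta_gap = -0.22, noise = 0.3) {
  set.seed(seed)
  data.frame(
    infant_id = rep(sprintf("i%02d", 1:(n / 2)), each = 2),
    pma_weeks = runif(n, 31, 36),
    gap = rnorm(n, 0, 0.91),
    ip_length_h = runif(n, 1, 20),
    infection = factor(sample(c("no", "suspected", "treated"), n, TRUE)),
    stringsAsFactors = FALSE
  ) |> transform(apnoea_rate = pmax(0, 0.8 + beta_gap * gap +
                                      rnorm(n, 0, noise)),
                 resp_rate = 60 - 1.87 * (pma_weeks - 33.5) + rnorm(n, 0, 2))
}

test_that("partial correlation reduces to the plain correlation", {
  set.seed(1)
  y <- rnorm(50)
  x <- rnorm(50)
  expect_equal(apnoeagap:::partial_rho(y, x), stats::cor(y, x))
})

test_that("a zero-noise deterministic cohort recovers the slope exactly", {
  tab <- make_table(n = 80, seed = 2, noise = 0)
  tab$apnoea_rate <- 0.8 - 0.22 * tab$gap  # no truncation, no noise
  # a deterministic response makes the mixed model boundary-singular, which
  # is expected here
  f <- suppressWarnings(suppressMessages(
    fit_association(tab, "apnoea_rate", "gap")))
  expect_lt(abs(f$beta - (-0.22)), 1e-6)
  expect_lt(abs(f$partial_rho) - 1, 1e-6)
})

test_that("the mixed model recovers slopes on the default synthetic cohort", {
  co <- simulate_cohort(cohort_params(seed = 3))
  f <- fit_association(co$occasions, "apnoea_rate", "gap")
  expect_true(f$ci[1] <= -0.22 && -0.22 <= f$ci[2])
  expect_lt(f$p, 0.05)
  fr <- fit_association(co$occasions, "resp_rate", "pma")
  expect_true(fr$ci[1] <= -1.87 && -1.87 <= fr$ci[2])
})

test_that("fit_result contract holds: CI contains beta, p in [0,1]", {
  f <- fit_association(make_table(seed = 4), "apnoea_rate", "gap")
  expect_true(f$ci[1] <= f$beta && f$beta <= f$ci[2])
  expect_true(f$p >= 0 && f$p <= 1)
  expect_true(abs(f$partial_rho) <= 1)
})

test_that("bootstrap p is 0 when rho_gap lies below every resample", {
  tab <- make_table(n = 100, seed = 5, beta_gap = -0.8, noise = 0.05)
  tab$resp_rate <- NULL
  # PMA unrelated to apnoea here, so every bootstrap rho_pma ~ 0 while
  # rho_gap is strongly negative
  b <- bootstrap_compare(tab, n_reps = 400, seed = 6)
  expect_equal(b$p, 0)
  expect_true(all(b$boot_rho > b$rho_gap))
})

test_that("identical predictor columns give p near one half", {
  tab <- make_table(n = 140, seed = 7, beta_gap = 0, noise = 0.3)
  tab$apnoea_rate <- pmax(0, 0.8 - 0.3 * tab$pma_weeks + 0.3 * 33.5 +
                            rnorm(140, 0, 0.3))
  tab$gap <- tab$pma_weeks
  b <- bootstrap_compare(tab, n_reps = 2000, seed = 8)
  expect_gt(b$p, 0.35)
  expect_lt(b$p, 0.65)
})

test_that("bootstrap p is invariant to occasion order and reproducible", {
  tab <- make_table(n = 80, seed = 9)
  b1 <- bootstrap_compare(tab, n_reps = 300, seed = 10)
  o <- sample(nrow(tab))
  b2 <- bootstrap_compare(tab[o, ], n_reps = 300, seed = 10)
  expect_equal(b1$rho_gap, b2$rho_gap)
  expect_lt(abs(b1$p - b2$p), 0.06)
  expect_identical(bootstrap_compare(tab, n_reps = 300, seed = 10)$p, b1$p)
})

test_that("E-value follows the closed form and its symmetries", {
  expect_equal(evalue(1)$E_point, 1)
  expect_equal(evalue(2)$E_point, 2 + sqrt(2))
  expect_error(evalue(0), "positive")
  expect_error(evalue(-1), "positive")
  # strictly increasing in RR above 1
  rrs <- seq(1.05, 5, by = 0.05)
  es <- vapply(rrs, function(r) evalue(r)$E_point, numeric(1))
  expect_true(all(diff(es) > 0))
  # reciprocal symmetry
  for (r in c(1.3, 2, 4.7)) {
    expect_equal(evalue(1 / r)$E_point, evalue(r)$E_point)
  }
  # CI crossing the null
  expect_equal(evalue(2, ci_limit_rr = 1)$E_CI, 1)
  expect_equal(evalue(2, ci_limit_rr = 0.8)$E_CI, 1)
  expect_equal(evalue(2, ci_limit_rr = 1.5)$E_CI, 1.5 + sqrt(1.5 * 0.5))
  expect_equal(evalue(0.5, ci_limit_rr = 0.8)$E_CI,
               evalue(1 / 0.8)$E_point)
})

test_that("rho-to-RR conversion is monotone and null-preserving", {
  expect_equal(rho_to_rr(0), 1)
  rhos <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(rho_to_rr(rhos)) > 0))
  expect_error(rho_to_rr(1), "\\(-1, 1\\)")
})

test_that("caffeine-stop regression behaves per construction", {
  set.seed(11)
  n <- 27
  sub <- data.frame(
    caffeine_stop_pma_weeks = 34 + rnorm(n, 0, 0.8),
    gap = rnorm(n, 0, 0.9),
    infection = factor(sample(c("no", "treated"), n, TRUE))
  )
  # response orthogonal to gap by construction: slope near zero
  r <- caffeine_stop_regression(sub)
  expect_lt(abs(r$beta), 0.5)
  expect_true(r$ci[1] <= r$beta && r$beta <= r$ci[2])
  expect_true(all(is.finite(r$ci)))
  expect_error(caffeine_stop_regression(sub[1:4, ]), ">= 5")
})

test_that("caffeine-stop slope is recovered across simulated subsets", {
  hits <- 0
  n_sim <- 40
  for (s in 1:n_sim) {
    set.seed(400 + s)
    n <- 27
    g <- rnorm(n, 0, 0.9)
    sub <- data.frame(
      caffeine_stop_pma_weeks = 34 - 0.26 * g + rnorm(n, 0, 0.8),
      gap = g,
      infection = factor(sample(c("no", "suspected", "treated"), n, TRUE))
    )
    r <- caffeine_stop_regression(sub)
    if (r$ci[1] <= -0.26 && -0.26 <= r$ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.85)
})

test_that("post-caffeine group summary matches its construction", {
  post <- data.frame(
    gap = c(0.5, 1, 0.2, -0.4, -1, -0.6),
    post_apnoea_rate = c(0.4, 0.5, NA, 1.0, 1.1, 0.9),
    post_desat_rate = c(0.2, 0.3, 0.25, 0.5, 0.4, 0.45)
  )
  g <- post_caffeine_group_rates(post)
  # group sizes reported separately per outcome (one IP trace missing)
  expect_equal(g$apnoea$n, c(2, 3))
  expect_equal(g$desat$n, c(3, 3))
  expect_equal(g$apnoea$mean[1], 0.45)
  expect_equal(g$apnoea$mean[2], 1.0)
  expect_equal(g$apnoea_reduction_pct, 55)
  # all events removed: both group means zero
  post0 <- transform(post, post_apnoea_rate = 0, post_desat_rate = 0)
  g0 <- post_caffeine_group_rates(post0)
  expect_equal(g0$apnoea$mean, c(0, 0))
  expect_true(is.na(g0$apnoea_reduction_pct))
})

test_that("generated post-caffeine rate ratio is recovered", {
  co <- simulate_cohort(cohort_params(n_infants = 400, seed = 12))
  post <- transform(co$post_caffeine, gap = infant_gap)
  g <- post_caffeine_group_rates(post)
  truth_ratio <- mean(post$true_post_apnoea_rate[post$infant_gap < 0]) /
    mean(post$true_post_apnoea_rate[post$infant_gap > 0])
  obs_ratio <- g$apnoea$mean[g$apnoea$group == "immature"] /
    g$apnoea$mean[g$apnoea$group == "mature"]
  expect_lt(abs(obs_ratio - truth_ratio) / truth_ratio, 0.25)
})

test_that("percent reduction matches the reported group means", {
  expect_equal(percent_reduction(0.41, 1.02), 60)
  expect_equal(percent_reduction(0.26, 0.45), 42)
  expect_equal(percent_reduction(1, 1), 0)
  expect_error(percent_reduction(0.5, 0), "> 0")
})
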