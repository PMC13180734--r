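# Association models and sensitivity analyses: linear mixed-effects models
# with a random infant intercept, partial correlations via covariate-adjusted
# residuals, a one-tailed bootstrap comparison of the two predictors,
# E-values, the caffeine-stop regression and the post-caffeine group
# comparison.

# Covariate-adjusted partial correlation on occasion-level data: correlate
# the residuals of y and x after regressing each on the covariate matrix Z
# (which includes the intercept).
partial_rho <- function(y, x, Z = NULL) {
  n <- length(y)
  if (is.null(Z)) Z <- matrix(1, n, 1)
  ry <- stats::.lm.fit(Z, y)$residuals
  rx <- stats::.lm.fit(Z, x)$residuals
  stats::cor(ry, rx)
}

# Fisher-z confidence interval for a partial correlation with k covariates.
rho_ci <- function(rho, n, k, level = 0.95) {
  z <- atanh(rho)
  se <- 1 / sqrt(n - k - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

# Build the covariate model matrix the study adjusts for: data length of the
# IBI recordings (apnoea models only) and infection status (all models).
# Constant covariates are dropped so degenerate synthetic designs still fit.
covariate_matrix <- function(table, include_length) {
  terms <- character()
  if (include_length && stats::sd(table$ip_length_h) > 1e-12) {
    terms <- c(terms, "ip_length_h")
  }
  if (length(unique(table$infection)) > 1) terms <- c(terms, "infection")
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  stats::model.matrix(stats::as.formula(paste("~", rhs)), data = table)
}

resolve_column <- function(table, name) {
  if (name == "pma" && !"pma" %in% names(table)) "pma_weeks" else name
}

#' Fit one association model
#'
#' Linear mixed-effects model of a respiratory outcome (apnoea rate or
#' respiratory rate) on a predictor (PMA or bias-corrected brain age gap),
#' with data length (apnoea models) and infection as fixed covariates and a
#' random intercept per infant. Reports the predictor's slope, Wald 95% CI,
#' Satterthwaite p-value, and the partial correlation of covariate-adjusted
#' residuals with its Fisher-z CI.
#'
#' @param table occasion-level data frame with columns `infant_id`,
#'   `pma_weeks` (or `pma`), `gap`, `apnoea_rate`, `resp_rate`,
#'   `ip_length_h`, `infection`.
#' @param response `"apnoea_rate"` or `"resp_rate"`.
#' @param predictor `"gap"` or `"pma"`.
#' @return A list of class `fit_result`: `beta`, `ci`, `p`, `partial_rho`,
#'   `rho_ci`, `n`, `model`.
#' @export
fit_association <- function(table,
                            response = c("apnoea_rate", "resp_rate"),
                            predictor = c("gap", "pma")) {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  pred_col <- resolve_column(table, predictor)
  abort_if(length(unique(table$infant_id)) < 2, "need >= 2 infants")
  include_length <- response == "apnoea_rate"
  covs <- character()
  if (include_length && stats::sd(table$ip_length_h) > 1e-12) {
    covs <- c(covs, "ip_length_h")
  }
  if (length(unique(table$infection)) > 1) covs <- c(covs, "infection")
  rhs <- paste(c(pred_col, covs, "(1 | infant_id)"), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- lmerTest::lmer(fml, data = table,
                        control = lme4::lmerControl(
                          check.conv.singular = lme4::.makeCC(
                            action = "ignore", tol = 1e-4)))
  coefs <- stats::coef(summary(fit))
  beta <- coefs[pred_col, "Estimate"]
  p <- coefs[pred_col, "Pr(>|t|)"]
  se <- coefs[pred_col, "Std. Error"]
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  Z <- covariate_matrix(table, include_length)
  rho <- partial_rho(table[[response]], table[[pred_col]], Z)
  list_out <- list(beta = beta, ci = ci, p = p,
                   partial_rho = rho,
                   rho_ci = rho_ci(rho, nrow(table), ncol(Z) - 1),
                   n = nrow(table), response = response,
                   predictor = predictor, model = fit)
  structure(list_out, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s ~ %s: beta %.3f [%.3f, %.3f], p %.3g, rho %.3f, n %d\n",
              x$response, x$predictor, x$beta, x$ci[1], x$ci[2], x$p,
              x$partial_rho, x$n))
  invisible(x)
}

#' Bootstrap comparison of the two predictors' partial correlations
#'
#' Resamples occasions with replacement and recomputes the partial
#' correlation between apnoea rate and PMA on each resample. The one-tailed
#' significance value is the proportion of bootstrap coefficients that are
#' equal to or lower than the observed partial correlation between apnoea
#' rate and brain age gap. Degenerate resamples (constant predictor or
#' covariate) are redrawn and counted.
#'
#' @param table occasion-level data frame (see [fit_association()]).
#' @param n_reps bootstrap repetitions.
#' @param cluster if TRUE, resample infants (cluster bootstrap) instead of
#'   occasions.
#' @param seed integer seed.
#' @return A list of class `bootstrap_result`: `p`, `ci` (bootstrap 95% CI of
#'   the PMA partial correlation), `rho_gap`, `rho_pma`, `boot_rho`,
#'   `n_redrawn`.
#' @export
bootstrap_compare <- function(table, n_reps = 10000, cluster = FALSE,
                              seed = 1L) {
  pma_col <- resolve_column(table, "pma")
  y <- table$apnoea_rate
  x_pma <- table[[pma_col]]
  x_gap <- table$gap
  Z <- covariate_matrix(table, include_length = TRUE)
  rho_gap <- partial_rho(y, x_gap, Z)
  rho_pma <- partial_rho(y, x_pma, Z)
  infants <- unique(table$infant_id)
  rows_of <- split(seq_len(nrow(table)), table$infant_id)
  with_seed(seed, {
    boot <- numeric(n_reps)
    n_redrawn <- 0L
    for (r in seq_len(n_reps)) {
      repeat {
        idx <- if (cluster) {
          unlist(rows_of[sample(infants, length(infants), replace = TRUE)],
                 use.names = FALSE)
        } else {
          sample.int(nrow(table), replace = TRUE)
        }
        Zi <- Z[idx, , drop = FALSE]
        if (stats::sd(x_pma[idx]) > 1e-12 &&
              qr(Zi)$rank == ncol(Zi)) break
        n_redrawn <- n_redrawn + 1L
      }
      boot[r] <- partial_rho(y[idx], x_pma[idx], Zi)
    }
    structure(list(p = mean(boot <= rho_gap),
                   ci = unname(stats::quantile(boot, c(0.025, 0.975))),
                   rho_gap = rho_gap, rho_pma = rho_pma, boot_rho = boot,
                   n_reps = n_reps, n_redrawn = n_redrawn),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> rho_gap %.3f vs rho_pma %.3f; one-tailed p %.4f (%d reps)\n",
    x$rho_gap, x$rho_pma, x$p, x$n_reps))
  invisible(x)
}

#' E-value for an observed association
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both exposure and
#' outcome to fully explain away the observed association:
#' E = RR + sqrt(RR * (RR - 1)). Risk ratios below 1 are mapped to their
#' reciprocal first. The E-value of the confidence interval uses the limit
#' closest to the null; when the CI crosses the null it is 1.
#'
#' @param effect_rr observed effect on the risk-ratio scale (> 0).
#' @param ci_limit_rr the CI limit closest to the null, risk-ratio scale
#'   (optional).
#' @return A list of class `evalue_result`: `E_point`, `E_CI`.
#' @export
evalue <- function(effect_rr, ci_limit_rr = NULL) {
  abort_if(effect_rr <= 0, "risk ratio must be positive")
  e_of <- function(rr) {
    if (rr < 1) rr <- 1 / rr
    rr + sqrt(rr * (rr - 1))
  }
  e_ci <- if (is.null(ci_limit_rr)) {
    NA_real_
  } else if ((effect_rr >= 1 && ci_limit_rr <= 1) ||
               (effect_rr < 1 && ci_limit_rr >= 1)) {
    1  # CI crosses the null
  } else {
    e_of(ci_limit_rr)
  }
  structure(list(E_point = e_of(effect_rr), E_CI = e_ci,
                 effect_rr = effect_rr),
            class = "evalue_result")
}

#' Convert a partial correlation to an approximate risk ratio
#'
#' Standardised-difference route: d = 2 rho / sqrt(1 - rho^2),
#' RR = exp(0.91 d). One of several conventions in use; documented, not a
#' reproduction of any published calculator's internals.
#'
#' @param rho partial correlation in (-1, 1).
#' @return Approximate risk ratio.
#' @export
rho_to_rr <- function(rho) {
  abort_if(any(abs(rho) >= 1), "`rho` must lie in (-1, 1)")
  d <- 2 * rho / sqrt(1 - rho^2)
  exp(0.91 * d)
}

#' Regression of caffeine-stop age on brain age gap
#'
#' Ordinary linear regression of the PMA at caffeine discontinuation on the
#' brain age gap (assessed within two weeks before stopping), with infection
#' status as a fixed factor; data length is not included.
#'
#' @param subset data frame with columns `caffeine_stop_pma_weeks`, `gap`,
#'   `infection` (one row per infant).
#' @return A `fit_result` list (the `model` element is the `lm` fit).
#' @export
caffeine_stop_regression <- function(subset) {
  abort_if(nrow(subset) < 5,
           sprintf("need >= 5 infants for the caffeine-stop regression (got %d)",
                   nrow(subset)))
  covs <- if (length(unique(subset$infection)) > 1) "infection" else NULL
  rhs <- paste(c("gap", covs), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("caffeine_stop_pma_weeks ~", rhs)),
                   data = subset)
  sm <- summary(fit)$coefficients
  beta <- sm["gap", "Estimate"]
  ci <- stats::confint(fit)["gap", ]
  Z <- covariate_matrix(transform(subset, ip_length_h = 0), FALSE)
  rho <- partial_rho(subset$caffeine_stop_pma_weeks, subset$gap, Z)
  structure(list(beta = beta, ci = unname(ci), p = sm["gap", "Pr(>|t|)"],
                 partial_rho = rho,
                 rho_ci = rho_ci(rho, nrow(subset), ncol(Z) - 1),
                 n = nrow(subset), response = "caffeine_stop_pma_weeks",
                 predictor = "gap", model = fit),
            class = "fit_result")
}

#' Post-caffeine group comparison of apnoea and desaturation rates
#'
#' Groups infants by maturity (brain age gap > 0 vs < 0, assessed before
#' caffeine discontinuation) and reports the mean and SD of apnoea and
#' desaturation rates in the 7 days after caffeine was stopped. Group sizes
#' are reported separately for the apnoea analysis (IP signal available) and
#' the desaturation analysis. No hypothesis test is applied.
#'
#' @param post data frame with one row per infant: `gap` (weeks),
#'   `post_apnoea_rate` (apnoeas/h; NA when the IP signal was not recorded),
#'   `post_desat_rate` (desaturations/h).
#' @return A list of class `group_comparison` with `apnoea` and `desat`
#'   summary data frames and the percent reductions (mature vs immature).
#' @export
post_caffeine_group_rates <- function(post) {
  post$maturity <- classify_maturity(post$gap)
  summarise <- function(values, maturity) {
    keep <- !is.na(values)
    values <- values[keep]
    maturity <- maturity[keep]
    out <- do.call(rbind, lapply(c("mature", "immature"), function(g) {
      v <- values[maturity == g]
      data.frame(group = g, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))
    out
  }
  apn <- summarise(post$post_apnoea_rate, post$maturity)
  des <- summarise(post$post_desat_rate, post$maturity)
  red <- function(s) {
    m <- s$mean[s$group == "mature"]
    i <- s$mean[s$group == "immature"]
    if (anyNA(c(m, i)) || length(m) == 0 || i <= 0) NA_real_
    else percent_reduction(m, i)
  }
  structure(list(apnoea = apn, desat = des,
                 apnoea_reduction_pct = red(apn),
                 desat_reduction_pct = red(des)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\napnoea rate (apnoeas/h):\n")
  print(x$apnoea, row.names = FALSE)
  cat("desaturation rate (events/h):\n")
  print(x$desat, row.names = FALSE)
  cat(sprintf("reductions (mature vs immature): apnoeas %s%%, desaturations %s%%\n",
              x$apnoea_reduction_pct, x$desat_reduction_pct))
  invisible(x)
}

#' Percent reduction of the mature group relative to the immature group
#'
#' 100 * (1 - mature / immature), rounded to the nearest integer percent.
#'
#' @param mean_mature,mean_immature group means (immature must be > 0).
#' @return Integer percent.
#' @export
percent_reduction <- function(mean_mature, mean_immature) {
  abort_if(mean_immature <= 0, "`mean_immature` must be > 0")
  round(100 * (1 - mean_mature / mean_immature))
}
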