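# Synthetic cohort generator: metadata, latent maturity, and rate-level
# outcomes for a repeated-measures cohort of moderate-to-late preterm infants.

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline is built for: 74 infants on
#' ~138 test occasions at 31-36 weeks postmenstrual age (PMA), a latent brain
#' age gap of mean 0 and SD 0.91 weeks, apnoea rate decreasing with gap at
#' -0.22 apnoeas/h per week, and respiratory rate decreasing with PMA at
#' -1.87 breaths/min per week.
#'
#' The gap is decomposed into an infant-level component plus occasion-level
#' jitter (`gap_within_sd`), marginally N(`gap_mean`, `gap_sd`^2): repeated
#' occasions of one infant are correlated, and the infant-level component
#' drives the caffeine-stop age (slope `caffeine_stop_gap_slope`) and the
#' post-caffeine event rates.
#'
#' @param n_infants number of infants.
#' @param occasion_probs probabilities of an infant contributing 1, 2, or 3
#'   test occasions (mean ~1.86 gives ~138 occasions for 74 infants).
#' @param pma_range PMA range at recording, weeks.
#' @param gap_mean,gap_sd mean and SD of the latent brain age gap, weeks.
#' @param gap_within_sd occasion-to-occasion SD of the gap within an infant,
#'   weeks (capped at `gap_sd`).
#' @param apnoea_baseline expected apnoea rate at gap 0, apnoeas/h.
#' @param apnoea_gap_slope change in apnoea rate per week of gap, apnoeas/h.
#' @param resp_baseline expected respiratory rate at PMA 33.5 wk, breaths/min.
#' @param resp_pma_slope change in respiratory rate per week of PMA,
#'   breaths/min.
#' @param infant_random_sd SD of the infant-level apnoea-rate intercept,
#'   apnoeas/h.
#' @param resp_noise_sd occasion-level noise on observed respiratory rate,
#'   breaths/min.
#' @param infection_probs probabilities over infection status
#'   {no, suspected, treated}.
#' @param caffeine_prob probability an infant is on caffeine from birth.
#' @param caffeine_stop_mean mean PMA at caffeine discontinuation, weeks.
#' @param caffeine_stop_gap_slope change in stop PMA per week of infant-level
#'   gap, weeks/week.
#' @param caffeine_stop_sd residual SD of the stop PMA, weeks.
#' @param longitudinal_prob probability an infant has continuous vital-signs
#'   monitoring (eligible for the post-caffeine sub-study).
#' @param post_apnoea_base,post_apnoea_gap_slope post-caffeine-stop apnoea
#'   rate law: max(0.05, base + slope * infant gap), apnoeas/h.
#' @param post_desat_base,post_desat_gap_slope post-caffeine-stop
#'   desaturation rate law, desaturations/h.
#' @param ip_length_mean_h mean duration of inter-breath-interval data per
#'   occasion, hours.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_infants = 74,
                          occasion_probs = c(0.38, 0.38, 0.24),
                          pma_range = c(31, 36),
                          gap_mean = 0,
                          gap_sd = 0.91,
                          gap_within_sd = 0.45,
                          apnoea_baseline = 0.8,
                          apnoea_gap_slope = -0.22,
                          resp_baseline = 60,
                          resp_pma_slope = -1.87,
                          infant_random_sd = 0.25,
                          resp_noise_sd = 2,
                          infection_probs = c(0.44, 0.12, 0.44),
                          caffeine_prob = 0.7,
                          caffeine_stop_mean = 34,
                          caffeine_stop_gap_slope = -0.26,
                          caffeine_stop_sd = 0.8,
                          longitudinal_prob = 0.3,
                          post_apnoea_base = 0.7,
                          post_apnoea_gap_slope = -0.45,
                          post_desat_base = 0.35,
                          post_desat_gap_slope = -0.14,
                          ip_length_mean_h = 8.5,
                          seed = 1L) {
  p <- as.list(environment())
  num <- p[!vapply(p, is.character, logical(1))]
  abort_if(any(!vapply(num, function(x) all(is.finite(x)), logical(1))),
           "all cohort parameters must be finite")
  abort_if(n_infants < 1, "`n_infants` must be >= 1")
  abort_if(gap_sd < 0, "`gap_sd` must be >= 0")
  abort_if(abs(sum(infection_probs) - 1) > 1e-8,
           "`infection_probs` must sum to 1")
  abort_if(abs(sum(occasion_probs) - 1) > 1e-8,
           "`occasion_probs` must sum to 1")
  structure(p, class = "cohort_params")
}

#' Simulate a repeated-measures cohort with ground truth
#'
#' Draws infants, test occasions, metadata, latent gaps and the rate-level
#' outcomes downstream statistics consume. Observed apnoea counts are Poisson
#' over the available recording length; observed respiratory rates are the
#' true rate plus noise. The `gap` column carries the latent (true) gap --
#' the signal-level pipeline replaces it with an EEG-derived estimate.
#'
#' @param params a [cohort_params()] object.
#' @return A list of class `apg_cohort` with elements:
#'   \describe{
#'     \item{occasions}{data frame, one row per test occasion: `infant_id`,
#'       `occasion_id`, `ga_weeks`, `pma_weeks`, `infection`, `ip_length_h`,
#'       `caffeine_on`, `caffeine_stop_pma_weeks`, `longitudinal`,
#'       `gap`, `apnoea_rate`, `resp_rate`, `n_ibis`.}
#'     \item{truth}{data frame of per-occasion ground truth: `true_gap`,
#'       `infant_gap`, `true_apnoea_rate`, `true_resp_rate`,
#'       `true_brain_age`.}
#'     \item{post_caffeine}{data frame, one row per longitudinally monitored
#'       infant that stopped caffeine: true and observed post-stop apnoea and
#'       desaturation rates, IP availability.}
#'   }
#' @export
simulate_cohort <- function(params = cohort_params()) {
  abort_if(!inherits(params, "cohort_params"),
           "`params` must come from cohort_params()")
  p <- params
  with_seed(p$seed, {
    n_occ_per <- sample(1:3, p$n_infants, replace = TRUE, prob = p$occasion_probs)
    infant_id <- sprintf("inf%03d", seq_len(p$n_infants))

    within_sd <- min(p$gap_within_sd, p$gap_sd)
    between_sd <- sqrt(max(p$gap_sd^2 - within_sd^2, 0))
    infant_gap <- p$gap_mean + stats::rnorm(p$n_infants, 0, between_sd)
    infant_apnoea <- stats::rnorm(p$n_infants, 0, p$infant_random_sd)
    on_caffeine <- stats::runif(p$n_infants) < p$caffeine_prob
    stop_pma <- p$caffeine_stop_mean +
      p$caffeine_stop_gap_slope * (infant_gap - p$gap_mean) +
      stats::rnorm(p$n_infants, 0, p$caffeine_stop_sd)
    stop_pma <- pmin(pmax(stop_pma, 31.5), 38)
    longitudinal <- stats::runif(p$n_infants) < p$longitudinal_prob
    ga <- pmin(stats::runif(p$n_infants, 26, 34), p$pma_range[1] - 0.1)

    rows <- vector("list", p$n_infants)
    for (i in seq_len(p$n_infants)) {
      k <- n_occ_per[i]
      pma <- sort(stats::runif(k, p$pma_range[1], p$pma_range[2]))
      occ_gap <- infant_gap[i] + stats::rnorm(k, 0, within_sd)
      infec <- sample(c("no", "suspected", "treated"), k, replace = TRUE,
                      prob = p$infection_probs)
      ip_len <- pmin(pmax(stats::rgamma(k, shape = 1.2,
                                        scale = p$ip_length_mean_h / 1.2),
                          0.4), 24)
      true_apn <- pmax(0, p$apnoea_baseline +
                         p$apnoea_gap_slope * occ_gap + infant_apnoea[i])
      true_resp <- p$resp_baseline + p$resp_pma_slope * (pma - 33.5)
      obs_apn <- stats::rpois(k, true_apn * ip_len) / ip_len
      obs_resp <- true_resp + stats::rnorm(k, 0, p$resp_noise_sd)
      n_ibis <- pmax(50L, stats::rpois(k, obs_resp * 60 * ip_len))
      rows[[i]] <- data.frame(
        infant_id = infant_id[i],
        occasion_id = sprintf("%s_occ%d", infant_id[i], seq_len(k)),
        ga_weeks = ga[i],
        pma_weeks = pma,
        infection = infec,
        ip_length_h = ip_len,
        caffeine_on = as.integer(on_caffeine[i] & pma < stop_pma[i]),
        caffeine_stop_pma_weeks = if (on_caffeine[i]) stop_pma[i] else NA_real_,
        longitudinal = longitudinal[i],
        gap = occ_gap,
        apnoea_rate = obs_apn,
        resp_rate = obs_resp,
        n_ibis = n_ibis,
        true_gap = occ_gap,
        infant_gap = infant_gap[i],
        true_apnoea_rate = true_apn,
        true_resp_rate = true_resp,
        stringsAsFactors = FALSE
      )
    }
    occ <- do.call(rbind, rows)
    occ$infection <- factor(occ$infection,
                            levels = c("no", "suspected", "treated"))
    truth <- occ[, c("occasion_id", "infant_id", "true_gap", "infant_gap",
                     "true_apnoea_rate", "true_resp_rate")]
    truth$true_brain_age <- occ$pma_weeks + occ$true_gap
    occ <- occ[, setdiff(names(occ),
                         c("true_gap", "infant_gap", "true_apnoea_rate",
                           "true_resp_rate"))]

    # post-caffeine sub-study: longitudinally monitored infants that were on
    # caffeine; event rates over the 7 days after discontinuation
    sel <- which(longitudinal & on_caffeine)
    post <- data.frame(
      infant_id = infant_id[sel],
      infant_gap = infant_gap[sel],
      stop_pma_weeks = stop_pma[sel],
      stringsAsFactors = FALSE
    )
    if (nrow(post) > 0) {
      hrs <- pmin(pmax(stats::rnorm(nrow(post), 120, 30), 48), 168)
      true_pa <- pmax(0.05, p$post_apnoea_base +
                        p$post_apnoea_gap_slope * post$infant_gap)
      true_pd <- pmax(0.02, p$post_desat_base +
                        p$post_desat_gap_slope * post$infant_gap)
      post$monitored_h <- hrs
      post$ip_available <- stats::runif(nrow(post)) < 11 / 17
      post$true_post_apnoea_rate <- true_pa
      post$true_post_desat_rate <- true_pd
      post$post_apnoea_rate <- ifelse(
        post$ip_available, stats::rpois(nrow(post), true_pa * hrs) / hrs,
        NA_real_)
      post$post_desat_rate <- stats::rpois(nrow(post), true_pd * hrs) / hrs
    }
    structure(list(occasions = occ, truth = truth, post_caffeine = post,
                   params = p),
              class = "apg_cohort")
  })
}

#' @export
print.apg_cohort <- function(x, ...) {
  cat(sprintf("<apg_cohort> %d infants, %d occasions, %d post-caffeine infants\n",
              length(unique(x$occasions$infant_id)), nrow(x$occasions),
              nrow(x$post_caffeine)))
  invisible(x)
}
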