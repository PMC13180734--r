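# End-to-end orchestration: synthetic generation (or file ingestion) ->
# respiration & desaturation -> brain ages -> bias-corrected gap ->
# density grids -> association statistics. Every stage is a pure function
# of the upstream artifacts and the config seed.

#' Pipeline configuration
#'
#' Unknown arguments are rejected. All randomness derives from `seed`
#' through per-recording substreams, so identical configs give identical
#' outputs and adding one recording never perturbs the others.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read
#'   recordings from `input_dir`).
#' @param seed global integer seed.
#' @param outdir output directory for stage artifacts, or NULL to skip
#'   writing.
#' @param input_dir directory of input files (file mode).
#' @param cohort a [cohort_params()] object (synthetic mode).
#' @param ip_window_s duration of impedance pneumography simulated and
#'   analysed per occasion, seconds.
#' @param evoked_fs sampling rate of the simulated evoked EEG, Hz.
#' @param n_epochs stimulus epochs per modality.
#' @param artifact_frac fraction of epochs carrying a pre-stimulus artifact.
#' @param jitter_ms evoked latency jitter, ms.
#' @param evoked_noise_sd evoked white-noise SD, uV.
#' @param resting_fs sampling rate of the simulated resting EEG, Hz.
#' @param resting_duration_s simulated resting EEG duration, seconds.
#' @param desat_coupling fraction of apnoeas accompanied by a desaturation.
#' @param n_boot bootstrap repetitions for the predictor comparison.
#' @param classifier_n training windows per class for the apnoea classifier.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            seed = 1L,
                            outdir = NULL,
                            input_dir = NULL,
                            cohort = NULL,
                            ip_window_s = 900,
                            evoked_fs = 250,
                            n_epochs = 20,
                            artifact_frac = 0.1,
                            jitter_ms = 10,
                            evoked_noise_sd = 5,
                            resting_fs = 64,
                            resting_duration_s = 1260,
                            desat_coupling = 0.5,
                            n_boot = 10000,
                            classifier_n = 40) {
  mode <- match.arg(mode)
  if (is.null(cohort)) cohort <- cohort_params(seed = substream_seed(seed, 1))
  abort_if(mode == "files" && is.null(input_dir),
           "file mode needs `input_dir`")
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage <- function(outdir, name, df) {
  if (!is.null(outdir)) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  invisible(df)
}

# Respiration + desaturation analysis of one synthetic occasion.
analyse_occasion_signals <- function(true_apnoea_rate, true_resp_rate,
                                     cfg, clf, occ_seed) {
  resp_rate <- min(max(true_resp_rate, 20), 110)
  sim <- simulate_ip(cfg$ip_window_s, resp_rate = resp_rate,
                     apnoeas = apnoea_spec(rate_per_h = true_apnoea_rate),
                     noise = ip_noise_spec(),
                     seed = occ_seed)
  resp <- analyse_respiration(sim$signal, clf)

  # desaturations co-occur with a fraction of apnoeas, plus independent dips
  tru_ap <- sim$truth$apnoeas
  dip <- NULL
  if (nrow(tru_ap) > 0) {
    with_ds <- with_seed(substream_seed(occ_seed, 1),
                         stats::runif(nrow(tru_ap)) < cfg$desat_coupling)
    if (any(with_ds)) {
      dip <- data.frame(onset_s = tru_ap$onset_s[with_ds] + 3,
                        duration_s = pmin(tru_ap$duration_s[with_ds],
                                          cfg$ip_window_s -
                                            tru_ap$onset_s[with_ds] - 4),
                        depth_pct = 74)
      dip <- dip[dip$duration_s > 0, , drop = FALSE]
    }
  }
  n_ind <- with_seed(substream_seed(occ_seed, 2),
                     stats::rpois(1, 0.3 * cfg$ip_window_s / 3600))
  if (n_ind > 0) {
    ons <- with_seed(substream_seed(occ_seed, 3),
                     stats::runif(n_ind, 0, cfg$ip_window_s - 30))
    dip <- rbind(dip, data.frame(onset_s = ons, duration_s = 15,
                                 depth_pct = 75))
  }
  spo2 <- simulate_spo2(cfg$ip_window_s, desats = dip,
                        seed = substream_seed(occ_seed, 4))
  desats <- detect_desaturations(spo2$signal)
  list(resp = resp, ip_truth = sim$truth, desats = desats,
       desat_rate = desat_rate(desats, cfg$ip_window_s / 3600))
}

# Sensory + resting brain-age measurement of one synthetic occasion.
measure_occasion_eeg <- function(true_brain_age, cfg, basis, occ_seed) {
  ev <- simulate_evoked(true_brain_age, basis,
                        jitter_ms = cfg$jitter_ms,
                        noise_sd = cfg$evoked_noise_sd,
                        n_epochs = cfg$n_epochs,
                        artifact_frac = cfg$artifact_frac,
                        seed = substream_seed(occ_seed, 10))
  vis <- reject_artifacts(ev$visual)
  tac <- reject_artifacts(ev$tactile)
  slopes <- if (isTRUE(attr(vis, "available")) &&
                  isTRUE(attr(tac, "available"))) {
    vis <- woody_align(vis, basis = basis, max_jitter_ms = 50, n_iter = 1)
    tac <- woody_align(tac, basis = basis, max_jitter_ms = 50, n_iter = 1)
    fit_nrf_slopes(vis, tac, basis)
  } else {
    rep(NA_real_, 6)
  }
  rest <- simulate_resting_eeg(true_brain_age,
                               duration_s = cfg$resting_duration_s,
                               fs = cfg$resting_fs,
                               seed = substream_seed(occ_seed, 11))
  seg <- prepare_resting_segment(rest$rec)
  feats <- if (isTRUE(attr(seg, "available"))) epoch_30s(seg) else NULL
  list(slopes = slopes, resting_features = feats,
       n_kept = c(visual = sum(vis$kept), tactile = sum(tac$kept)))
}

# Out-of-fold brain-age predictions for the cohort: the surrogate models are
# trained on the cohort itself, so honest per-occasion ages come from k-fold
# cross-fitting (grouped by infant).
crossfit_ages <- function(slopes_mat, feats_list, pma, infant_id,
                          n_folds = 5, seed = 1L) {
  n <- length(pma)
  infants <- unique(infant_id)
  fold_of_infant <- with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(n_folds), length(infants))),
                    infants)
  })
  fold <- fold_of_infant[infant_id]
  sens <- rep(NA_real_, n)
  rest <- rep(NA_real_, n)
  sens_ok <- !is.na(slopes_mat[, 1])
  rest_ok <- !vapply(feats_list, is.null, logical(1))
  for (f in seq_len(n_folds)) {
    tr_s <- which(fold != f & sens_ok)
    te_s <- which(fold == f & sens_ok)
    if (length(tr_s) >= 20 && length(te_s) > 0 &&
          diff(range(pma[tr_s])) >= 3) {
      m <- train_sensory_model(slopes_mat[tr_s, , drop = FALSE], pma[tr_s],
                               seed = substream_seed(seed, 100 + f))
      sens[te_s] <- predict_sensory_age(m, slopes_mat[te_s, , drop = FALSE])
    }
    tr_r <- which(fold != f & rest_ok)
    te_r <- which(fold == f & rest_ok)
    if (length(tr_r) >= 20 && length(te_r) > 0) {
      m <- train_resting_model(feats_list[tr_r], pma[tr_r],
                               seed = substream_seed(seed, 200 + f))
      rest[te_r] <- vapply(te_r, function(i) {
        predict_resting_age(m, feats_list[[i]])
      }, numeric(1))
    }
  }
  # small cohorts cannot support grouped cross-fitting; fall back to
  # in-sample predictions so every occasion keeps at least one estimate
  in_sample <- FALSE
  miss_s <- which(is.na(sens) & sens_ok)
  if (length(miss_s) > 0 && sum(sens_ok) >= 20 &&
        diff(range(pma[sens_ok])) >= 3) {
    m <- train_sensory_model(slopes_mat[sens_ok, , drop = FALSE],
                             pma[sens_ok], seed = substream_seed(seed, 300))
    sens[miss_s] <- predict_sensory_age(m, slopes_mat[miss_s, , drop = FALSE])
    in_sample <- TRUE
  }
  miss_r <- which(is.na(rest) & rest_ok)
  if (length(miss_r) > 0 && sum(rest_ok) >= 20) {
    m <- train_resting_model(feats_list[rest_ok], pma[rest_ok],
                             seed = substream_seed(seed, 301))
    rest[miss_r] <- vapply(miss_r, function(i) {
      predict_resting_age(m, feats_list[[i]])
    }, numeric(1))
    in_sample <- TRUE
  }
  list(sensory = sens, resting = rest, in_sample = in_sample)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: simulate the cohort, analyse every occasion's signals
#' (respiration, desaturation, evoked and resting EEG), cross-fit the two
#' brain-age models, combine and bias-correct the gap, build the density
#' grids, and fit the association/bootstrap/E-value statistics plus the
#' caffeine-discontinuation analyses. Stage outputs are written as CSV/JSON
#' under `config$outdir` when given.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `cohort`,
#'   `occasions` (augmented occasion table), `respiration`, `brain_age`,
#'   `gap`, `densities`, `associations`, `bootstrap`, `evalues`,
#'   `caffeine_stop`, `post_caffeine`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  abort_if(!inherits(config, "pipeline_config"),
           "`config` must come from pipeline_config()")
  cfg <- config
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE)
  }
  log <- list()
  if (cfg$mode == "files") {
    return(run_pipeline_files(cfg))
  }

  cohort <- simulate_cohort(cfg$cohort)
  occ <- cohort$occasions
  truth <- cohort$truth
  n_occ <- nrow(occ)
  write_stage(cfg$outdir, "cohort.csv", occ)

  train <- make_apnoea_training_set(cfg$classifier_n,
                                    seed = substream_seed(cfg$seed, 2))
  clf <- train_apnoea_classifier(train$features, train$labels,
                                 seed = substream_seed(cfg$seed, 3))
  log$classifier_balanced_accuracy <- clf$holdout_balanced_accuracy

  basis <- make_nrf_basis(fs = cfg$evoked_fs)
  resp_rows <- vector("list", n_occ)
  events_rows <- vector("list", n_occ)
  slopes_mat <- matrix(NA_real_, n_occ, 6)
  feats_list <- vector("list", n_occ)
  ibis_list <- vector("list", n_occ)
  desat_rate_win <- numeric(n_occ)
  for (i in seq_len(n_occ)) {
    occ_seed <- substream_seed(cfg$seed, 1000 + i)
    sig <- analyse_occasion_signals(truth$true_apnoea_rate[i],
                                    truth$true_resp_rate[i],
                                    cfg, clf, occ_seed)
    resp_rows[[i]] <- cbind(occasion_id = occ$occasion_id[i],
                            sig$resp$summary)
    if (!is.null(sig$resp$events) && nrow(sig$resp$events) > 0) {
      events_rows[[i]] <- cbind(occasion_id = occ$occasion_id[i],
                                sig$resp$events)
    }
    ibis_list[[i]] <- sig$resp$ibis
    desat_rate_win[i] <- sig$desat_rate
    eeg <- measure_occasion_eeg(truth$true_brain_age[i], cfg, basis, occ_seed)
    slopes_mat[i, ] <- eeg$slopes
    feats_list[[i]] <- eeg$resting_features
  }
  resp_summary <- do.call(rbind, resp_rows)
  write_stage(cfg$outdir, "resp_summary.csv", resp_summary)
  events <- if (length(Filter(Negate(is.null), events_rows)) > 0) {
    do.call(rbind, Filter(Negate(is.null), events_rows))
  } else {
    data.frame(occasion_id = character(), start_time = numeric(),
               duration = numeric(), label = character())
  }
  write_stage(cfg$outdir, "apnoea_events.csv", events)
  log$n_sensory_unavailable <- sum(is.na(slopes_mat[, 1]))
  log$n_resting_unavailable <- sum(vapply(feats_list, is.null, logical(1)))

  ages <- crossfit_ages(slopes_mat, feats_list, occ$pma_weeks,
                        occ$infant_id, seed = substream_seed(cfg$seed, 4))
  combined <- combine_ages(ages$sensory, ages$resting)
  gaps <- bias_correct(combined, occ$pma_weeks)
  maturity <- classify_maturity(gaps$corrected_gap)
  gap_df <- data.frame(occasion_id = occ$occasion_id,
                       pma_weeks = occ$pma_weeks,
                       sensory_age = ages$sensory,
                       resting_age = ages$resting,
                       combined_age = combined,
                       raw_gap = gaps$raw_gap,
                       corrected_gap = gaps$corrected_gap,
                       maturity = maturity)
  write_stage(cfg$outdir, "gap.csv", gap_df)
  log$sensory_mae <- mean(abs(ages$sensory - occ$pma_weeks), na.rm = TRUE)
  log$resting_mae <- mean(abs(ages$resting - occ$pma_weeks), na.rm = TRUE)

  # density grids from the analysed windows' IBIs
  have_ibis <- !vapply(ibis_list, is.null, logical(1))
  dens <- lapply(ibis_list[have_ibis], recording_density)
  grid_pma <- build_density_grid(dens, occ$pma_weeks[have_ibis], axis = "pma")
  grid_gap <- build_density_grid(dens, gaps$corrected_gap[have_ibis],
                                 axis = "gap")
  write_stage(cfg$outdir, "density_pma.csv", density_grid_long(grid_pma))
  write_stage(cfg$outdir, "density_gap.csv", density_grid_long(grid_gap))

  # association stage at the recording-day data scale: day-level rates from
  # the cohort (all available IBIs on the day), EEG-derived corrected gap
  stats_tab <- occ
  stats_tab$gap <- gaps$corrected_gap
  stats_tab <- stats_tab[stats_tab$n_ibis >= MIN_IBIS_QC, ]
  fits <- list(
    apnoea_vs_pma = fit_association(stats_tab, "apnoea_rate", "pma"),
    apnoea_vs_gap = fit_association(stats_tab, "apnoea_rate", "gap"),
    resp_vs_pma = fit_association(stats_tab, "resp_rate", "pma"),
    resp_vs_gap = fit_association(stats_tab, "resp_rate", "gap")
  )
  assoc_df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, beta = f$beta, ci_lo = f$ci[1], ci_hi = f$ci[2],
               p = f$p, partial_rho = f$partial_rho, n = f$n)
  }))
  write_stage(cfg$outdir, "associations.csv", assoc_df)
  boot <- bootstrap_compare(stats_tab, n_reps = cfg$n_boot,
                            seed = substream_seed(cfg$seed, 5))
  if (!is.null(cfg$outdir)) {
    jsonlite::write_json(list(p = boot$p, ci = boot$ci,
                              rho_gap = boot$rho_gap, rho_pma = boot$rho_pma,
                              n_reps = boot$n_reps),
                         file.path(cfg$outdir, "bootstrap.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  evals <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    rr <- rho_to_rr(f$partial_rho)
    lim <- rho_to_rr(f$rho_ci[which.min(abs(f$rho_ci))])
    e <- evalue(rr, lim)
    data.frame(model = nm, rr = rr, E_point = e$E_point, E_CI = e$E_CI)
  }))
  write_stage(cfg$outdir, "evalues.csv", evals)

  # caffeine-stop subset: latest occasion within two weeks before stop
  sub <- stats_tab[!is.na(stats_tab$caffeine_stop_pma_weeks) &
                     stats_tab$caffeine_stop_pma_weeks - stats_tab$pma_weeks <= 2 &
                     stats_tab$caffeine_stop_pma_weeks > stats_tab$pma_weeks, ]
  sub <- sub[order(sub$infant_id, -sub$pma_weeks), ]
  sub <- sub[!duplicated(sub$infant_id), ]
  caffeine_fit <- if (nrow(sub) >= 5) caffeine_stop_regression(sub) else NULL
  log$n_caffeine_subset <- nrow(sub)

  # post-caffeine sub-study: gap from the infant's last occasion before stop
  post <- cohort$post_caffeine
  post_cmp <- NULL
  if (nrow(post) > 0) {
    last_gap <- vapply(post$infant_id, function(id) {
      rows <- which(occ$infant_id == id)
      if (length(rows) == 0) return(NA_real_)
      gaps$corrected_gap[rows[which.max(occ$pma_weeks[rows])]]
    }, numeric(1))
    post$gap <- ifelse(is.na(last_gap), post$infant_gap, last_gap)
    post_cmp <- post_caffeine_group_rates(post)
    write_stage(cfg$outdir, "post_caffeine_groups.csv",
                rbind(cbind(outcome = "apnoea", post_cmp$apnoea),
                      cbind(outcome = "desat", post_cmp$desat)))
  }

  res <- structure(list(cohort = cohort, occasions = stats_tab,
                        respiration = list(summary = resp_summary,
                                           events = events,
                                           desat_rate_window = desat_rate_win),
                        brain_age = list(slopes = slopes_mat,
                                         sensory = ages$sensory,
                                         resting = ages$resting),
                        gap = gap_df,
                        densities = list(pma = grid_pma, gap = grid_gap),
                        associations = fits,
                        associations_table = assoc_df,
                        bootstrap = boot,
                        evalues = evals,
                        caffeine_stop = caffeine_fit,
                        post_caffeine = post_cmp,
                        log = log),
                   class = "pipeline_result")
  if (!is.null(cfg$outdir)) {
    jsonlite::write_json(
      list(n_infants = length(unique(occ$infant_id)),
           n_occasions = n_occ,
           gap_mean = mean(gap_df$corrected_gap),
           gap_sd = stats::sd(gap_df$corrected_gap),
           pct_mature = 100 * mean(maturity == "mature"),
           sensory_mae = log$sensory_mae,
           resting_mae = log$resting_mae,
           log = log),
      file.path(cfg$outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d occasions; gap SD %.2f; %d/%d brain ages unavailable\n",
              nrow(x$gap), stats::sd(x$gap$corrected_gap),
              x$log$n_sensory_unavailable, nrow(x$gap)))
  invisible(x)
}

#' Validate an input file bundle
#'
#' Schema checks (presence, columns, sampling rate) for a file-mode input
#' directory: `cohort.csv` plus per-occasion `<occasion_id>_ip.csv`,
#' `<occasion_id>_spo2.csv` and optional `<occasion_id>_eeg.csv` /
#' `<occasion_id>_annotations.csv`. Reports only; never stops.
#'
#' @param input_dir input directory.
#' @return Data frame manifest: `file`, `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(input_dir) {
  man <- list()
  add <- function(file, check, pass, detail = "") {
    man[[length(man) + 1]] <<- data.frame(file = file, check = check,
                                          pass = pass, detail = detail)
  }
  meta_path <- file.path(input_dir, "cohort.csv")
  if (!file.exists(meta_path)) {
    add("cohort.csv", "exists", FALSE, "metadata table missing")
    return(do.call(rbind, man))
  }
  meta <- utils::read.csv(meta_path)
  need <- c("infant_id", "occasion_id", "pma_weeks")
  add("cohort.csv", "columns", all(need %in% names(meta)),
      paste("required:", paste(need, collapse = ", ")))
  check_rate <- function(path, expected_fs, tol = 0.05) {
    d <- utils::read.csv(path, nrows = 200)
    if (!all(c("time_s", "value") %in% names(d)) || nrow(d) < 3) {
      return(c(FALSE, "needs columns time_s, value"))
    }
    fs <- 1 / stats::median(diff(d$time_s))
    ok <- abs(fs - expected_fs) / expected_fs < tol
    c(ok, sprintf("fs %.3g Hz (expected %g)", fs, expected_fs))
  }
  for (oid in meta$occasion_id) {
    ip <- file.path(input_dir, paste0(oid, "_ip.csv"))
    if (file.exists(ip)) {
      r <- check_rate(ip, 62.5)
      add(basename(ip), "sampling_rate", as.logical(r[1]), r[2])
    } else {
      add(basename(ip), "exists", FALSE, "IP trace missing")
    }
    sp <- file.path(input_dir, paste0(oid, "_spo2.csv"))
    if (file.exists(sp)) {
      r <- check_rate(sp, 0.97)
      add(basename(sp), "sampling_rate", as.logical(r[1]), r[2])
    }
    eeg <- file.path(input_dir, paste0(oid, "_eeg.csv"))
    if (file.exists(eeg)) {
      hdr <- names(utils::read.csv(eeg, nrows = 1))
      add(basename(eeg), "sensory_channels",
          all(c("Oz", "Cz") %in% hdr),
          if (all(c("Oz", "Cz") %in% hdr)) "" else
            "missing Oz/Cz: sensory stage unavailable")
      add(basename(eeg), "resting_channels",
          all(c("C3", "C4") %in% hdr),
          if (all(c("C3", "C4") %in% hdr)) "" else
            "missing C3/C4: resting stage unavailable")
    }
  }
  do.call(rbind, man)
}

# File mode: respiration + desaturation over a directory of recordings.
run_pipeline_files <- function(cfg) {
  manifest <- validate_inputs(cfg$input_dir)
  meta_path <- file.path(cfg$input_dir, "cohort.csv")
  abort_if(!file.exists(meta_path),
           sprintf("missing input file: %s", meta_path))
  meta <- utils::read.csv(meta_path)
  train <- make_apnoea_training_set(cfg$classifier_n,
                                    seed = substream_seed(cfg$seed, 2))
  clf <- train_apnoea_classifier(train$features, train$labels,
                                 seed = substream_seed(cfg$seed, 3))
  rows <- list()
  events <- list()
  for (k in seq_len(nrow(meta))) {
    oid <- meta$occasion_id[k]
    ip_path <- file.path(cfg$input_dir, paste0(oid, "_ip.csv"))
    abort_if(!file.exists(ip_path),
             sprintf("missing input file: %s", ip_path))
    d <- utils::read.csv(ip_path)
    fs <- 1 / stats::median(diff(d$time_s))
    res <- analyse_respiration(ip_signal(d$value, fs = fs), clf)
    dr <- NA_real_
    sp_path <- file.path(cfg$input_dir, paste0(oid, "_spo2.csv"))
    if (file.exists(sp_path)) {
      ds <- utils::read.csv(sp_path)
      sfs <- 1 / stats::median(diff(ds$time_s))
      ev <- detect_desaturations(spo2_signal(ds$value, fs = sfs))
      dr <- desat_rate(ev, nrow(ds) / sfs / 3600)
    }
    rows[[k]] <- cbind(occasion_id = oid, res$summary, desat_rate = dr)
    if (!is.null(res$events) && nrow(res$events) > 0) {
      events[[length(events) + 1]] <- cbind(occasion_id = oid, res$events)
    }
  }
  summary <- do.call(rbind, rows)
  write_stage(cfg$outdir, "resp_summary.csv", summary)
  structure(list(manifest = manifest, respiration = list(summary = summary,
                 events = if (length(events)) do.call(rbind, events) else NULL),
                 log = list()),
            class = "pipeline_result")
}
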