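# Session- and experiment-level orchestration: analyze one session
# (stage -> preprocess -> detect -> rates), simulate and analyze a whole
# multi-treatment experiment, and run the group statistics over the
# resulting measure table.

#' Analyze one session end to end
#'
#' Stages the trajectory, segments the EEG into 10-s sweeps with artifact
#' flagging, detects SWDs (threshold statistics over artifact-free samples),
#' assigns each event the behavioral state of its start sweep, and computes
#' state-normalized rates.
#'
#' @param eeg An \code{\link{eeg_record}}.
#' @param traj The session's \code{\link{trajectory}}.
#' @param detector A \code{\link{detector_config}}.
#' @param artifact_thresh_mv2hz Sweep exclusion threshold, default 2e4.
#' @param manual_mask Optional manual sweep exclusions (indices or CSV
#'   path).
#' @param decisions Optional rater decisions for
#'   \code{\link{review_roundtrip}}.
#' @param smooth Smooth the trajectory during staging, default TRUE.
#' @return List of class \code{"session_analysis"}: \code{staging},
#'   \code{sweeps}, \code{qualified}, \code{events}, \code{rates}.
#' @export
analyze_session <- function(eeg, traj, detector = detector_config(),
                            artifact_thresh_mv2hz = 2e4, manual_mask = NULL,
                            decisions = NULL, smooth = TRUE) {
  staging <- stage_trajectory(traj, smooth = smooth)
  sweeps <- flag_artifact_sweeps(sweep_set(eeg), artifact_thresh_mv2hz)
  if (!is.null(manual_mask)) sweeps <- apply_manual_mask(sweeps, manual_mask)
  qualified <- qualify_channel(sweeps)
  events <- detect_swd(eeg, detector, sweeps = sweeps)
  events <- review_roundtrip(events, decisions)
  events <- assign_event_states(events, staging$sweeps, sweeps)
  rates <- per_state_rates(events, staging$sweeps, sweeps)
  structure(list(staging = staging, sweeps = sweeps, qualified = qualified,
                 events = events, rates = rates),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat("Session analysis", if (!x$qualified) "(channel NOT qualified)", "\n")
  print(x$events)
  print(x$rates)
  invisible(x)
}

#' Experiment configuration
#'
#' Describes a crossover experiment: each mouse receives every treatment in
#' a session apiece, with two saline sessions as controls. Per-treatment
#' effects are expressed as multipliers on the per-state SWD rates.
#'
#' @param n_mice Number of mice, default 9.
#' @param treatments Treatment labels in session order; must contain
#'   \code{"saline1"}. Default the two saline sessions plus the eight
#'   tested compounds.
#' @param effects Named list mapping treatment to a rate multiplier
#'   (default 1 for every treatment: a null experiment).
#' @param session A template \code{\link{session_config}} shared by all
#'   sessions (its seed is re-derived per session).
#' @param mouse_rate_sd Between-mouse log-normal SD of baseline rates,
#'   default 0.3.
#' @param detector A \code{\link{detector_config}}.
#' @param seed Experiment seed.
#' @return List of class \code{"experiment_config"}.
#' @export
experiment_config <- function(n_mice = 9,
                              treatments = c("saline1", "saline2", "ESM",
                                             "LEV", "DPZ", "ATR", "CGP",
                                             "BHB", "PYR", "LAC"),
                              effects = list(),
                              session = session_config(duration_s = 1800),
                              mouse_rate_sd = 0.3,
                              detector = detector_config(), seed = 1L) {
  if (!"saline1" %in% treatments) {
    stop("every experiment needs a first saline session ('saline1')")
  }
  eff <- stats::setNames(rep(1, length(treatments)), treatments)
  for (nm in names(effects)) eff[nm] <- effects[[nm]]
  structure(list(n_mice = n_mice, treatments = treatments, effects = eff,
                 session = session, mouse_rate_sd = mouse_rate_sd,
                 detector = detector, seed = as.integer(seed)),
            class = "experiment_config")
}

# deterministic per-session seed below 2^31
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 48271 + i * 7919) %% 2147483629 + 1)
}

#' Simulate and analyze a whole experiment
#'
#' For every mouse x treatment session: draw the mouse's baseline rates
#' (log-normal heterogeneity, fixed per mouse), scale them by the
#' treatment's effect multiplier, simulate the session, and run
#' \code{\link{analyze_session}}. Returns the long-format measure table
#' plus the group statistics from \code{\link{experiment_stats}}.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param out_dir Optional directory; when given, \code{measures.csv},
#'   \code{anova.csv}, \code{pairwise.csv} and a provenance log are
#'   written there.
#' @return List of class \code{"swd_experiment"}: \code{measures} (long
#'   data frame \code{mouse}, \code{treatment}, \code{state},
#'   \code{measure}, \code{value}), \code{stats}, \code{config}.
#' @export
run_swd_experiment <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  base_rates <- config$session$swd_rate_per_state
  mouse_mult <- exp(stats::rnorm(config$n_mice, 0, config$mouse_rate_sd))
  rows <- list()
  sess_i <- 0L
  for (m in seq_len(config$n_mice)) {
    for (tr in config$treatments) {
      sess_i <- sess_i + 1L
      scfg <- config$session
      scfg$swd_rate_per_state <- base_rates * mouse_mult[m] *
        config$effects[[tr]]
      scfg$seed <- derive_seed(config$seed, sess_i)
      sess <- simulate_session(scfg)
      ana <- analyze_session(sess$eeg, sess$trajectory, config$detector)
      r <- ana$rates
      rows[[sess_i]] <- data.frame(
        mouse = paste0("m", m), treatment = tr,
        state = rep(r$state, 3),
        measure = rep(c("swd_count_per_hour", "total_swd_s_per_hour",
                        "mean_single_duration_s"), each = nrow(r)),
        value = c(r$swd_count_per_hour, r$total_swd_s_per_hour,
                  r$mean_single_duration_s))
    }
  }
  measures <- do.call(rbind, rows)
  stats_out <- experiment_stats(measures)
  res <- structure(list(measures = measures, stats = stats_out,
                        config = config), class = "swd_experiment")
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' Group statistics over an experiment measure table
#'
#' For each measure x state family: a repeated-measures ANOVA with
#' Greenhouse-Geisser correction across treatments (listwise deletion), and
#' -- when the omnibus test is significant -- paired t-tests of each drug
#' against the first saline session, FDR-corrected across drugs within the
#' family.
#'
#' @param measures Long data frame \code{mouse}, \code{treatment},
#'   \code{state}, \code{measure}, \code{value}.
#' @param control Control treatment label, default \code{"saline1"}.
#' @param alpha Omnibus gate level, default 0.05.
#' @return List with \code{anova} (one row per family) and \code{pairwise}
#'   (per family x drug; empty when no omnibus passes).
#' @export
experiment_stats <- function(measures, control = "saline1", alpha = 0.05) {
  fams <- unique(measures[, c("measure", "state")])
  anova_rows <- list(); pair_rows <- list()
  for (i in seq_len(nrow(fams))) {
    sub <- measures[measures$measure == fams$measure[i] &
                    measures$state == fams$state[i], ]
    m <- stats::xtabs(value ~ mouse + treatment, data = sub,
                      na.action = stats::na.pass)
    m <- as.matrix(unclass(m))
    # xtabs fills absent cells with 0; restore NA for truly missing cells
    present <- stats::xtabs(~ mouse + treatment, data = sub)
    m[as.matrix(unclass(present)) == 0] <- NA
    keep <- colSums(!is.na(m)) >= 2
    m <- m[, keep, drop = FALSE]
    if (ncol(m) < 2L || sum(stats::complete.cases(m)) < 2L) next
    an <- rm_anova_gg(m)
    anova_rows[[length(anova_rows) + 1L]] <- data.frame(
      measure = fams$measure[i], state = fams$state[i], F = an$F,
      df1 = an$df1, df2 = an$df2, epsilon = an$epsilon, p = an$p)
    if (!is.na(an$p) && an$p < alpha && control %in% colnames(m)) {
      drugs <- setdiff(colnames(m), c(control, "saline2"))
      pt <- paired_t_fdr(m[, c(control, drugs), drop = FALSE],
                         control = control)
      pt <- cbind(measure = fams$measure[i], state = fams$state[i], pt)
      pair_rows[[length(pair_rows) + 1L]] <- pt
    }
  }
  list(anova = do.call(rbind, anova_rows),
       pairwise = if (length(pair_rows)) do.call(rbind, pair_rows))
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$measures, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)
  if (!is.null(res$stats$anova)) {
    utils::write.csv(res$stats$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$stats$pairwise)) {
    utils::write.csv(res$stats$pairwise, file.path(out_dir, "pairwise.csv"),
                     row.names = FALSE)
  }
  log <- c(sprintf("swdscope %s", as.character(utils::packageVersion("swdscope"))),
           sprintf("R %s", R.version.string),
           sprintf("seed %d", res$config$seed),
           sprintf("mice %d treatments %s", res$config$n_mice,
                   paste(res$config$treatments, collapse = ",")),
           sprintf("session duration_s %g eeg_fs %g",
                   res$config$session$duration_s, res$config$session$eeg_fs))
  writeLines(log, file.path(out_dir, "provenance.log"))
  invisible(out_dir)
}

#' @export
print.swd_experiment <- function(x, ...) {
  cat(sprintf("Experiment: %d mice x %d treatments\n", x$config$n_mice,
              length(x$config$treatments)))
  if (!is.null(x$stats$anova)) {
    cat("Omnibus families significant at 0.05:",
        sum(x$stats$anova$p < 0.05), "of", nrow(x$stats$anova), "\n")
  }
  invisible(x)
}

#' Summary table of an experiment (per state and treatment)
#'
#' Mirrors the layout of a per-state drug-response figure: mean and SEM of
#' each measure by state and treatment, with significance flags from the
#' FDR-corrected paired comparisons.
#'
#' @param x An object from \code{\link{run_swd_experiment}}.
#' @param measure Which measure to tabulate, default
#'   \code{"swd_count_per_hour"}.
#' @return Data frame \code{state}, \code{treatment}, \code{mean},
#'   \code{sem}, \code{n}, \code{sig}.
#' @export
pipeline_report <- function(x, measure = "swd_count_per_hour") {
  sub <- x$measures[x$measures$measure == measure, ]
  agg <- stats::aggregate(value ~ state + treatment, data = sub,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sem = stats::sd(v, na.rm = TRUE) /
                                                sqrt(sum(!is.na(v))),
                                              n = sum(!is.na(v))))
  out <- data.frame(state = agg$state, treatment = agg$treatment,
                    mean = agg$value[, "mean"], sem = agg$value[, "sem"],
                    n = agg$value[, "n"])
  out$sig <- FALSE
  pw <- x$stats$pairwise
  if (!is.null(pw)) {
    pw <- pw[pw$measure == measure & pw$sig, ]
    key <- paste(out$state, out$treatment)
    out$sig <- key %in% paste(pw$state, pw$condition)
  }
  out[order(out$state, out$treatment), ]
}

#' F-score sweep over the envelope threshold
#'
#' In the original workflow the envelope threshold is calibrated per record
#' by eye; on synthetic sessions the ground truth permits an objective
#' sweep instead. For each candidate \code{k_sd} the detector is run and
#' scored against the true events.
#'
#' @param session A \code{\link{simulate_session}} result.
#' @param k_values Thresholds to try, default \code{seq(1.8, 3.4, 0.2)}
#'   (the working range).
#' @param ... Passed to \code{\link{detector_config}}.
#' @return Data frame \code{k_sd}, \code{recall}, \code{precision},
#'   \code{f1}.
#' @export
ksd_fscore_sweep <- function(session, k_values = seq(1.8, 3.4, by = 0.2),
                             ...) {
  sweeps <- flag_artifact_sweeps(sweep_set(session$eeg))
  rows <- lapply(k_values, function(k) {
    ev <- detect_swd(session$eeg, detector_config(k_sd = k, ...),
                     sweeps = sweeps)
    perf <- detection_performance(ev, session$truth$events)
    f1 <- if (is.na(perf$recall) || is.na(perf$precision) ||
              perf$recall + perf$precision == 0) NA_real_ else {
      2 * perf$recall * perf$precision / (perf$recall + perf$precision)
    }
    data.frame(k_sd = k, recall = perf$recall, precision = perf$precision,
               f1 = f1)
  })
  do.call(rbind, rows)
}

#' Match detected events to ground truth and score the detector
#'
#' A true event is recalled when some accepted detection overlaps at least
#' \code{min_overlap} of the true duration; an accepted detection is a true
#' positive when it overlaps at least \code{min_overlap} of its own
#' duration with some true event.
#'
#' @param events Accepted \code{\link{swd_events}}.
#' @param truth_events Ground-truth event table (\code{start_s},
#'   \code{end_s}).
#' @param min_overlap Fractional overlap required, default 0.5.
#' @return List: \code{recall}, \code{precision}, \code{n_true},
#'   \code{n_detected}.
#' @export
detection_performance <- function(events, truth_events, min_overlap = 0.5) {
  acc <- events[events$accepted, , drop = FALSE]
  ov <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  rec <- if (nrow(truth_events) == 0) NA_real_ else {
    hit <- vapply(seq_len(nrow(truth_events)), function(i) {
      if (nrow(acc) == 0) return(FALSE)
      any(ov(truth_events$start_s[i], truth_events$end_s[i],
             acc$start_s, acc$end_s) >=
            min_overlap * (truth_events$end_s[i] - truth_events$start_s[i]))
    }, logical(1))
    mean(hit)
  }
  prec <- if (nrow(acc) == 0) NA_real_ else {
    tp <- vapply(seq_len(nrow(acc)), function(i) {
      if (nrow(truth_events) == 0) return(FALSE)
      any(ov(acc$start_s[i], acc$end_s[i], truth_events$start_s,
             truth_events$end_s) >=
            min_overlap * (acc$end_s[i] - acc$start_s[i]))
    }, logical(1))
    mean(tp)
  }
  list(recall = rec, precision = prec, n_true = nrow(truth_events),
       n_detected = nrow(acc))
}
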