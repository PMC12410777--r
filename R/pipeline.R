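#' Run the full group analysis on a cohort
#'
#' Preprocesses every recording, extracts the per-epoch features of each
#' available modality, assigns groups by median split of the questionnaire
#' change scores, and computes whole-task tests, per-epoch time-course
#' masks, and PSD comparisons (per-bin for head roll, per-channel-band for
#' EEG).
#'
#' Measures produced when their source streams are present: heart rate
#' (bpm), heart rate variability (ratio), tonic and phasic GSR (uS), pupil
#' size left/right (mm, first epoch zeroed), respiratory rate (brpm), and
#' head-roll variance (dps^2).
#'
#' @param cohort An `anx_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config Analysis configuration, see [default_config()].
#' @param verbose Print per-stage progress (default FALSE).
#' @return An `anx_results` list: `groups`, `features` (named list of
#'   participants x epochs matrices), `table` (data.frame shaped like the
#'   study's descriptive/inferential table), `tests` (list of
#'   `anx_test_result`), `timecourse` (per-measure p/mask), `roll_psd` and
#'   `eeg_psd` comparison maps, and `config`.
#' @export
analyze_cohort <- function(cohort, config = default_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "anx_cohort"))
  recs <- cohort$recordings
  say <- function(...) if (verbose) message(...)
  say("preprocessing ", length(recs), " recordings")
  processed <- lapply(recs, preprocess_recording, config = config)

  chg <- vapply(recs, function(r) gad7_change(r$gad7_pre, r$gad7_post), numeric(1))
  names(chg) <- vapply(recs, function(r) r$participant_id, character(1))
  groups <- median_split(chg)

  w <- config$window_s; st <- config$step_s
  have <- names(processed[[1]]$streams)
  feats <- list()
  say("extracting features")
  if ("hr_raw" %in% have) {
    feats[["HR"]] <- feature_matrix(processed, "hr_raw", extract_hr,
                                    window_s = w, step_s = st,
                                    measure = "HR", units = "bpm")
    feats[["HRV"]] <- feature_matrix(processed, "hr_raw",
                                     function(x, fs) extract_hrv(extract_beats(x, fs)),
                                     window_s = w, step_s = st,
                                     measure = "HRV", units = "ratio")
  }
  if ("tonic" %in% have) {
    feats[["Tonic GSR"]] <- feature_matrix(processed, "tonic", epoch_mean,
                                           window_s = w, step_s = st,
                                           measure = "Tonic GSR", units = "uS")
    feats[["Phasic GSR"]] <- feature_matrix(processed, "phasic", epoch_mean,
                                            window_s = w, step_s = st,
                                            measure = "Phasic GSR", units = "uS")
  }
  if ("pupil" %in% have) {
    feats[["Pupil size left"]] <- feature_matrix(processed, "pupil", epoch_mean,
                                                 channel = 1, window_s = w, step_s = st,
                                                 baseline_zero = TRUE,
                                                 measure = "Pupil size left", units = "mm")
    feats[["Pupil size right"]] <- feature_matrix(processed, "pupil", epoch_mean,
                                                  channel = 2, window_s = w, step_s = st,
                                                  baseline_zero = TRUE,
                                                  measure = "Pupil size right", units = "mm")
  }
  if ("resp" %in% have) {
    feats[["Respiratory Rate"]] <- feature_matrix(processed, "resp", extract_resp_rate,
                                                  window_s = w, step_s = st,
                                                  measure = "Respiratory Rate",
                                                  units = "brpm")
  }
  if ("roll" %in% have) {
    feats[["Head Roll Variance"]] <- feature_matrix(processed, "roll", roll_variance,
                                                    window_s = w, step_s = st,
                                                    measure = "Head Roll Variance",
                                                    units = "dps^2")
  }

  say("group statistics")
  tests <- lapply(feats, whole_task_test, groups = groups)
  timecourse <- lapply(feats, timecourse_tests, groups = groups,
                       alpha = config$alpha)
  tab <- if (!length(tests)) data.frame() else do.call(rbind, lapply(tests, function(ts) {
    data.frame(measure = ts$measure, units = ts$units,
               mean_anx = ts$mean_anx, mean_non = ts$mean_non,
               median_anx = ts$median_anx, median_non = ts$median_non,
               sd_anx = ts$sd_anx, sd_non = ts$sd_non,
               ci_lo_anx = ts$ci95_anx[1], ci_hi_anx = ts$ci95_anx[2],
               ci_lo_non = ts$ci95_non[1], ci_hi_non = ts$ci95_non[2],
               rank_sum = ts$rank_sum, p_value = ts$p_value,
               cohens_d = ts$cohens_d)
  }))
  if (nrow(tab)) rownames(tab) <- NULL

  roll_psd <- eeg_psd <- NULL
  if ("roll" %in% have) {
    say("head-roll PSD comparison")
    rp <- cohort_psd(processed, "roll", w, st)
    roll_psd <- psd_group_comparison(rp, groups, "per_bin", alpha = config$alpha)
  }
  if ("eeg25" %in% have) {
    say("EEG PSD comparison")
    epsd <- cohort_psd(processed, "eeg25", w, st)
    eeg_psd <- psd_group_comparison(epsd, groups, "per_channel_band",
                                    bands = config$bands, alpha = config$alpha)
  }
  structure(list(groups = groups, features = feats, table = tab, tests = tests,
                 timecourse = timecourse, roll_psd = roll_psd, eeg_psd = eeg_psd,
                 config = config),
            class = "anx_results")
}

#' @export
print.anx_results <- function(x, ...) {
  cat(sprintf("<anx_results> %d anxious / %d non-anxious; measures: %s\n",
              sum(x$groups$group == "anxious"),
              sum(x$groups$group == "non_anxious"),
              paste(names(x$features), collapse = ", ")))
  print(x$table, digits = 4)
  invisible(x)
}

#' Write analysis results to a directory
#'
#' Emits `results_table.tsv` (the descriptive/inferential table), one
#' `timecourse_<measure>.tsv` per measure (epoch start, raw p, mask), PSD
#' p-value maps where available, per-measure feature matrices, and
#' `run_metadata.json` echoing the configuration.
#'
#' @param results An `anx_results` object.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "anx_results"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(results$table, file.path(path, "results_table.tsv"), sep = "\t")
  slug <- function(m) gsub("[^a-z0-9]+", "_", tolower(m))
  for (m in names(results$timecourse)) {
    tc <- results$timecourse[[m]]
    starts <- (seq_along(tc$p) - 1) * results$config$step_s
    data.table::fwrite(
      data.frame(epoch_start_s = starts, p_raw = tc$p, significant = tc$mask),
      file.path(path, paste0("timecourse_", slug(m), ".tsv")), sep = "\t")
  }
  for (m in names(results$features)) {
    fm <- results$features[[m]]
    data.table::fwrite(data.frame(participant_id = rownames(fm), fm,
                                  check.names = FALSE),
                       file.path(path, paste0("features_", slug(m), ".tsv")),
                       sep = "\t")
  }
  if (!is.null(results$roll_psd)) {
    rp <- results$roll_psd
    data.table::fwrite(
      data.frame(freq_hz = rp$freq, p_raw = rp$p_raw, p_corrected = rp$p_corrected,
                 sig_raw = rp$mask_raw, sig_corrected = rp$mask_corrected),
      file.path(path, "roll_psd_pvalues.tsv"), sep = "\t")
  }
  if (!is.null(results$eeg_psd)) {
    ep <- results$eeg_psd
    long <- data.frame(
      channel = rep(rownames(ep$p_raw), ncol(ep$p_raw)),
      band = rep(colnames(ep$p_raw), each = nrow(ep$p_raw)),
      p_raw = as.vector(ep$p_raw), p_corrected = as.vector(ep$p_corrected),
      sig_raw = as.vector(ep$mask_raw), sig_corrected = as.vector(ep$mask_corrected))
    data.table::fwrite(long, file.path(path, "eeg_psd_pvalues.tsv"), sep = "\t")
  }
  groups_df <- data.frame(participant_id = names(results$groups$group),
                          group = unname(results$groups$group),
                          gad7_change = unname(results$groups$change_scores))
  data.table::fwrite(groups_df, file.path(path, "groups.tsv"), sep = "\t")
  meta <- list(
    package_version = as.character(utils::packageVersion("anxsig")),
    alpha = results$config$alpha,
    window_s = results$config$window_s, step_s = results$config$step_s,
    common_fs = results$config$common_fs,
    filters = lapply(results$config$filters, function(f) {
      list(kind = f$kind, cutoffs_hz = f$cutoffs_hz, order = f$order,
           zero_phase = f$zero_phase)
    }),
    bands = results$config$bands
  )
  jsonlite::write_json(meta, file.path(path, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble a human-readable summary of a results directory
#'
#' @param path Directory written by [write_results()].
#' @return Character vector of report lines (also of class
#'   `anx_report` with a print method).
#' @export
build_report <- function(path) {
  tf <- file.path(path, "results_table.tsv")
  if (!file.exists(tf)) stop("no results_table.tsv in ", path, "; run the analysis first")
  tab <- as.data.frame(data.table::fread(tf, sep = "\t"))
  lines <- c("Group comparison summary", "========================", "")
  gf <- file.path(path, "groups.tsv")
  if (file.exists(gf)) {
    g <- as.data.frame(data.table::fread(gf, sep = "\t"))
    lines <- c(lines, sprintf("Participants: %d anxious, %d non-anxious (median split on questionnaire change)",
                              sum(g$group == "anxious"), sum(g$group == "non_anxious")), "")
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    lines <- c(lines, sprintf(
      "%s [%s]: anxious mean %.3f (SD %.3f), non-anxious mean %.3f (SD %.3f); rank sum %g, p = %.4g, d = %.3f%s",
      r$measure, r$units, r$mean_anx, r$sd_anx, r$mean_non, r$sd_non,
      r$rank_sum, r$p_value, r$cohens_d,
      if (r$p_value < 0.05) "  *" else ""))
  }
  slugs <- list.files(path, pattern = "^timecourse_.*\\.tsv$")
  if (length(slugs)) {
    lines <- c(lines, "", "Significant epochs (uncorrected p < 0.05):")
    for (f in slugs) {
      tc <- as.data.frame(data.table::fread(file.path(path, f), sep = "\t"))
      m <- sub("^timecourse_(.*)\\.tsv$", "\\1", f)
      sig <- tc$epoch_start_s[which(tc$significant)]
      lines <- c(lines, sprintf("  %s: %s", m,
                                if (length(sig)) paste0(length(sig), " epochs (starts ",
                                                        paste(utils::head(sig, 8), collapse = ", "),
                                                        if (length(sig) > 8) ", ..." else "", " s)")
                                else "none"))
    }
  }
  rf <- file.path(path, "roll_psd_pvalues.tsv")
  if (file.exists(rf)) {
    rp <- as.data.frame(data.table::fread(rf, sep = "\t"))
    sig <- rp$freq_hz[rp$sig_corrected]
    lines <- c(lines, "", sprintf("Head-roll PSD bins significant after FDR correction: %s",
                                  if (length(sig)) paste0(length(sig), " bins in ",
                                                          min(sig), "-", max(sig), " Hz")
                                  else "none"))
  }
  ef <- file.path(path, "eeg_psd_pvalues.tsv")
  if (file.exists(ef)) {
    epv <- as.data.frame(data.table::fread(ef, sep = "\t"))
    nsig <- sum(epv$sig_corrected)
    lines <- c(lines, sprintf("EEG channel-band cells significant after FDR correction: %d of %d",
                              nsig, nrow(epv)))
  }
  structure(lines, class = "anx_report")
}

#' @export
print.anx_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
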