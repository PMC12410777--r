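# On-disk layout: one directory per participant containing one
# tab-separated file per stream (first column `t` = timestamp in seconds,
# one column per channel, header row) plus manifest.json (id, group,
# rates, generator parameters) and ground_truth.json. Cohort-level GAD-7
# item scores live in a single gad7.tsv beside the participant directories.

known_stream_names <- function() {
  c("ecg", "gsr", "resp", "pupil", "imu_roll", "eeg", "eog",
    "hr_raw", "tonic", "phasic", "roll", "eeg25")
}

#' Write a recording to a directory
#'
#' @param rec An [recording()] object.
#' @param path Directory to create/fill (one file per stream plus
#'   `manifest.json` and, if ground truth is present, `ground_truth.json`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "anx_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(rec$streams)) {
    s <- rec$streams[[nm]]
    dt <- data.table::data.table(t = stream_times(s))
    for (j in seq_along(s$channel_labels)) dt[[s$channel_labels[j]]] <- s$data[, j]
    data.table::fwrite(dt, file.path(path, paste0(nm, ".tsv")), sep = "\t")
  }
  manifest <- list(
    participant_id = rec$participant_id,
    streams = lapply(rec$streams, function(s) {
      list(fs = s$fs, t0 = s$t0, channels = s$channel_labels)
    }),
    gad7_pre = rec$gad7_pre, gad7_post = rec$gad7_post,
    meta = rec$meta
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (length(rec$ground_truth)) {
    jsonlite::write_json(rec$ground_truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a recording from a directory
#'
#' Validates timestamp uniformity of every stream (a gap larger than
#' 1.5 sampling intervals is an error naming the stream and the time of the
#' gap). A stream file whose name is not one of the canonical stream names
#' triggers a warning but is carried through untouched.
#'
#' @param path Directory written by [write_recording()].
#' @return An [recording()] object.
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
  streams <- list()
  for (f in files) {
    nm <- sub("\\.tsv$", "", basename(f))
    if (nm %in% c("gad7", "tonic_truth")) next
    if (!nm %in% known_stream_names()) {
      warning("unknown stream '", nm, "' carried through untouched")
    }
    dt <- data.table::fread(f, sep = "\t")
    if (!identical(names(dt)[1], "t")) {
      stop("stream '", nm, "': malformed header (first column must be 't')")
    }
    tt <- dt$t
    if (length(tt) < 2) stop("stream '", nm, "' has fewer than 2 samples")
    info <- manifest$streams[[nm]]
    fs <- if (!is.null(info)) info$fs else 1 / stats::median(diff(tt))
    gaps <- diff(tt)
    bad <- which(gaps > 1.5 / fs | gaps <= 0)
    if (length(bad)) {
      stop(sprintf("stream '%s': non-uniform timestamps at t = %.4f s (gap %.4f s, expected %.4f s)",
                   nm, tt[bad[1]], gaps[bad[1]], 1 / fs))
    }
    dat <- as.matrix(dt[, -1])
    streams[[nm]] <- stream(nm, fs, dat, colnames(dat), t0 = tt[1])
  }
  gt <- list()
  gf <- file.path(path, "ground_truth.json")
  if (file.exists(gf)) gt <- jsonlite::read_json(gf, simplifyVector = TRUE)
  recording(manifest$participant_id, streams,
            gad7_pre = unlist(manifest$gad7_pre),
            gad7_post = unlist(manifest$gad7_post),
            ground_truth = gt, meta = manifest$meta)
}

#' Write a cohort to disk
#'
#' One sub-directory per participant plus a cohort-level `gad7.tsv`
#' (columns `participant_id`, `item1_pre..item7_pre`,
#' `item1_post..item7_post`) and `cohort.json` with the generating spec.
#'
#' @param cohort An `anx_cohort` from [generate_cohort()].
#' @param path Output directory.
#' @param force Overwrite an existing non-empty directory (default FALSE).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, force = FALSE) {
  stopifnot(inherits(cohort, "anx_cohort"))
  if (dir.exists(path) && length(list.files(path)) && !force) {
    stop("output directory ", path, " is not empty; use force = TRUE to overwrite")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    write_recording(rec, file.path(path, rec$participant_id))
  }
  data.table::fwrite(cohort$gad7, file.path(path, "gad7.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth, file.path(path, "truth.tsv"), sep = "\t")
  spec <- cohort$spec
  spec$group_params <- NULL
  jsonlite::write_json(unclass(spec), file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from disk
#'
#' @param path Directory written by [write_cohort()].
#' @return An `anx_cohort` (without the generating group templates).
#' @export
read_cohort <- function(path) {
  gf <- file.path(path, "gad7.tsv")
  if (!file.exists(gf)) stop("no gad7.tsv in ", path, "; not a cohort directory")
  gad7 <- as.data.frame(data.table::fread(gf, sep = "\t"))
  dirs <- list.dirs(path, recursive = FALSE)
  recs <- lapply(dirs, read_recording)
  truth <- NULL
  tf <- file.path(path, "truth.tsv")
  if (file.exists(tf)) truth <- as.data.frame(data.table::fread(tf, sep = "\t"))
  spec <- NULL
  cf <- file.path(path, "cohort.json")
  if (file.exists(cf)) spec <- jsonlite::read_json(cf, simplifyVector = TRUE)
  structure(list(recordings = recs, gad7 = gad7, truth = truth, spec = spec),
            class = "anx_cohort")
}
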