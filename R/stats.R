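#' Questionnaire change score
#'
#' Mean-item change of the seven-item anxiety questionnaire: mean of the
#' post items minus mean of the pre items.
#'
#' @param pre,post Numeric vectors of 7 item scores each.
#' @return Scalar change score.
#' @export
gad7_change <- function(pre, post) {
  if (length(pre) != 7 || length(post) != 7) {
    stop("GAD-7 has 7 items; got ", length(pre), " pre and ", length(post), " post")
  }
  mean(post) - mean(pre)
}

#' Median split into anxious / non-anxious groups
#'
#' Participants with change scores strictly above the sample median are
#' anxious, strictly below non-anxious. For odd n the participant at the
#' median joins the anxious group, which is deterministic and reproduces a
#' 9/8 split for 17 participants. Tied scores at the median make the split
#' ill-defined and are rejected.
#'
#' @param change_scores Named numeric vector (names = participant ids).
#' @return An `anx_groups` object: list with `group` (named character
#'   vector, values "anxious"/"non_anxious"), `change_scores`, `median`.
#' @export
median_split <- function(change_scores) {
  n <- length(change_scores)
  if (n < 4) stop("median split needs at least 4 participants")
  if (is.null(names(change_scores))) {
    names(change_scores) <- sprintf("P%02d", seq_len(n))
  }
  med <- stats::median(change_scores)
  at_med <- sum(change_scores == med)
  if (at_med > 1) {
    stop("tied change scores at the median (", at_med,
         " participants at ", med, "); the split needs a tie policy")
  }
  grp <- ifelse(change_scores > med, "anxious",
                ifelse(change_scores < med, "non_anxious", NA))
  if (any(is.na(grp))) grp[is.na(grp)] <- "anxious" # odd n: median joins anxious
  structure(list(group = stats::setNames(grp, names(change_scores)),
                 change_scores = change_scores, median = med),
            class = "anx_groups")
}

#' @export
print.anx_groups <- function(x, ...) {
  cat(sprintf("<anx_groups> %d anxious / %d non-anxious (median change %.3f)\n",
              sum(x$group == "anxious"), sum(x$group == "non_anxious"), x$median))
  invisible(x)
}

#' Wilcoxon rank-sum test (exact for small untied samples)
#'
#' The statistic is the sum of the (mid)ranks of `x` in the pooled sample.
#' Without ties and with `n1 + n2 <= exact_limit` the two-sided p-value is
#' exact — twice the smaller tail of the null rank-sum distribution, capped
#' at 1. Otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric samples for the two groups (each of size >= 2).
#' @param exact_limit Largest pooled size for the exact p-value (default 25).
#' @return List: `statistic` (rank sum of `x`), `u` (Mann-Whitney U),
#'   `p_value` (two-sided), `method` ("exact" or "normal").
#' @export
ranksum_test <- function(x, y, exact_limit = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 non-missing values")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  u <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 + n2 <= exact_limit) {
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    nt <- n1 + n2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (nt * (nt - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nt + 1 - tie_term))
    mu <- n1 * n2 / 2
    z <- (abs(u - mu) - 0.5) / sigma
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal"
  }
  list(statistic = W, u = u, p_value = p, method = method)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_p` with
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return Cohen's d, or `NA` (with a warning) when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 non-missing values")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) {
    warning("zero pooled standard deviation; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sp
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output order matches input.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values (elementwise >= raw, <= 1).
#' @export
bh_correct <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-epoch group tests across a feature matrix
#'
#' One Wilcoxon rank-sum test per epoch column, anxious vs non-anxious.
#' Per the exploratory time-course convention, the significance mask uses
#' uncorrected p-values at level `alpha`.
#'
#' @param mat participants x epochs matrix (rownames = participant ids).
#' @param groups An `anx_groups` assignment covering the rownames.
#' @param alpha Significance level (default 0.05).
#' @return List: `p` (per-epoch raw p), `mask` (p < alpha), `n_eff`
#'   (per-epoch group sizes used). Epochs with fewer than 2 valid values in
#'   either group get `NA` p and mask.
#' @export
timecourse_tests <- function(mat, groups, alpha = 0.05) {
  stopifnot(inherits(groups, "anx_groups"))
  ids <- rownames(mat)
  ga <- groups$group[ids]
  anx <- which(ga == "anxious"); non <- which(ga == "non_anxious")
  ne <- ncol(mat)
  p <- rep(NA_real_, ne)
  for (k in seq_len(ne)) {
    xv <- mat[anx, k]; yv <- mat[non, k]
    if (sum(!is.na(xv)) >= 2 && sum(!is.na(yv)) >= 2) {
      p[k] <- ranksum_test(xv, yv)$p_value
    }
  }
  list(p = p, mask = !is.na(p) & p < alpha,
       n_eff = cbind(anxious = colSums(!is.na(mat[anx, , drop = FALSE])),
                     non_anxious = colSums(!is.na(mat[non, , drop = FALSE]))))
}

#' Whole-task group comparison for one measure
#'
#' Averages each participant's feature over all epochs, then runs the
#' rank-sum test, Cohen's d, and per-group descriptives (mean, median, SD,
#' empirical 2.5/97.5 percentile interval). Participants with no valid
#' epoch are excluded with a message.
#'
#' @param mat participants x epochs matrix (rownames = participant ids).
#' @param groups An `anx_groups` assignment.
#' @param measure,units Labels for the output row.
#' @return An `anx_test_result` list with descriptives and test fields.
#' @export
whole_task_test <- function(mat, groups, measure = attr(mat, "measure"),
                            units = attr(mat, "units")) {
  stopifnot(inherits(groups, "anx_groups"))
  avg <- rowMeans(mat, na.rm = TRUE)
  all_missing <- rowSums(!is.na(mat)) == 0
  if (any(all_missing)) {
    message("excluding participant(s) with no valid epoch: ",
            paste(rownames(mat)[all_missing], collapse = ", "))
    avg <- avg[!all_missing]
  }
  ga <- groups$group[names(avg)]
  xa <- avg[ga == "anxious"]; xn <- avg[ga == "non_anxious"]
  ts <- ranksum_test(xa, xn)
  ci <- function(v) unname(stats::quantile(v, c(0.025, 0.975), type = 7))
  structure(list(
    measure = if (is.null(measure)) "" else measure,
    units = if (is.null(units)) "" else units,
    n_anx = length(xa), n_non = length(xn),
    mean_anx = mean(xa), mean_non = mean(xn),
    median_anx = stats::median(xa), median_non = stats::median(xn),
    sd_anx = stats::sd(xa), sd_non = stats::sd(xn),
    ci95_anx = ci(xa), ci95_non = ci(xn),
    rank_sum = ts$statistic, p_value = ts$p_value,
    cohens_d = cohens_d(xa, xn),
    participant_means = avg
  ), class = "anx_test_result")
}

#' @export
print.anx_test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: anx %.3f +/- %.3f vs non-anx %.3f +/- %.3f | W = %g, p = %.4g, d = %.3f\n",
              x$measure, x$units, x$mean_anx, x$sd_anx, x$mean_non, x$sd_non,
              x$rank_sum, x$p_value, x$cohens_d))
  invisible(x)
}

#' Group comparison over PSD grids with FDR correction
#'
#' Input is whole-task-averaged PSD per participant (from [cohort_psd()]).
#' For a single-channel stream (head roll) one rank-sum test is run per
#' 1 Hz bin and corrected across bins; for EEG, per-channel band powers are
#' tested per (channel, band) cell and corrected across all cells.
#'
#' @param psd `list(freq, psd)` with `psd` participants x channels x bins.
#' @param groups An `anx_groups` assignment over the participant dimension.
#' @param level `"per_bin"` (roll) or `"per_channel_band"` (EEG).
#' @param bands Band definitions for `"per_channel_band"`.
#' @param alpha Significance level for the binary masks (default 0.05).
#' @param fmin Lowest bin tested for `"per_bin"` (default 1 Hz; the DC bin
#'   is excluded).
#' @return List with `p_raw`, `p_corrected`, `mask_raw`, `mask_corrected`
#'   (vectors over bins, or channel x band matrices).
#' @export
psd_group_comparison <- function(psd, groups,
                                 level = c("per_bin", "per_channel_band"),
                                 bands = eeg_bands(), alpha = 0.05, fmin = 1) {
  level <- match.arg(level)
  stopifnot(inherits(groups, "anx_groups"))
  arr <- psd$psd
  ids <- dimnames(arr)[[1]]
  ga <- groups$group[ids]
  anx <- ga == "anxious"; non <- ga == "non_anxious"
  if (level == "per_bin") {
    if (dim(arr)[2] != 1) stop("per_bin comparison expects a single-channel stream")
    sel <- psd$freq >= fmin
    fr <- psd$freq[sel]
    p <- vapply(which(sel), function(b) {
      ranksum_test(arr[anx, 1, b], arr[non, 1, b])$p_value
    }, numeric(1))
    names(p) <- fr
    pc <- bh_correct(p)
    list(freq = fr, p_raw = p, p_corrected = pc,
         mask_raw = p < alpha, mask_corrected = pc < alpha)
  } else {
    nch <- dim(arr)[2]
    chs <- dimnames(arr)[[2]]
    p <- matrix(NA_real_, nch, length(bands), dimnames = list(chs, names(bands)))
    for (ch in seq_len(nch)) {
      for (b in seq_along(bands)) {
        bp_a <- apply(arr[anx, ch, , drop = FALSE], 1,
                      function(v) band_power(v, psd$freq, bands[[b]]))
        bp_n <- apply(arr[non, ch, , drop = FALSE], 1,
                      function(v) band_power(v, psd$freq, bands[[b]]))
        p[ch, b] <- ranksum_test(bp_a, bp_n)$p_value
      }
    }
    pc <- matrix(bh_correct(as.vector(p)), nch, length(bands),
                 dimnames = dimnames(p))
    list(p_raw = p, p_corrected = pc,
         mask_raw = p < alpha, mask_corrected = pc < alpha)
  }
}
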