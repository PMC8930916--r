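#' AHA 16-segment labels for a short-axis myocardial mask
#'
#' Divides an annular myocardial mask into the standard American Heart
#' Association segments: 6 sectors of 60 degrees at the basal and
#' mid-ventricular levels, 4 sectors of 90 degrees at the apical level,
#' numbered counter-clockwise starting from the anterior right-ventricular
#' insertion (segments 1-6 basal, 7-12 mid, 13-16 apical).
#'
#' @param myo_mask logical matrix (the annulus).
#' @param centroid c(x, y) center in matrix (row, col) coordinates; default
#'   mask centroid.
#' @param rv_insertion_deg angle of the anterior RV insertion, degrees
#'   counter-clockwise from +x (matrix row axis).
#' @param slice_level one of "basal", "mid", "apical".
#' @return integer matrix: segment label per voxel (NA outside the mask).
#' @export
aha16_labels <- function(myo_mask, centroid = NULL, rv_insertion_deg = 90,
                         slice_level = c("basal", "mid", "apical")) {
  slice_level <- match.arg(slice_level)
  idx <- which(myo_mask, arr.ind = TRUE)
  if (nrow(idx) < 8) stop("mask too small")
  if (is.null(centroid)) centroid <- colMeans(idx)
  dx <- idx[, 1] - centroid[1]; dy <- idx[, 2] - centroid[2]
  r <- sqrt(dx^2 + dy^2)
  # annularity: the centroid must not be inside the mask itself
  ctr <- round(centroid)
  if (ctr[1] >= 1 && ctr[1] <= nrow(myo_mask) && ctr[2] >= 1 &&
      ctr[2] <= ncol(myo_mask) && isTRUE(myo_mask[ctr[1], ctr[2]]))
    stop("mask is not annular: centroid lies inside the mask")
  ang <- (atan2(dy, dx) * 180 / pi - rv_insertion_deg) %% 360
  nseg <- if (slice_level == "apical") 4L else 6L
  seg <- floor(ang / (360 / nseg)) + 1L
  offset <- switch(slice_level, basal = 0L, mid = 6L, apical = 12L)
  out <- matrix(NA_integer_, nrow(myo_mask), ncol(myo_mask))
  out[idx] <- seg + offset
  out
}

#' Per-segment summary table
#'
#' @param map numeric matrix of parameter values.
#' @param labels segment label matrix from \code{aha16_labels}.
#' @return data.frame: segment, mean, sd, n, slice level.
#' @export
segment_table <- function(map, labels) {
  segs <- sort(unique(labels[!is.na(labels)]))
  res <- lapply(segs, function(s) {
    v <- map[!is.na(labels) & labels == s]
    v <- v[!is.na(v)]
    data.frame(segment = s, mean = mean(v), sd = stats::sd(v), n = length(v),
               slice = if (s <= 6) "basal" else if (s <= 12) "mid" else "apical")
  })
  do.call(rbind, res)
}

#' Two-way mixed-effects, absolute-agreement, single-measure ICC
#'
#' Computed from the mean squares of the two-way (subject x method) layout:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)}}
#' with k = 2 raters here.
#'
#' @param x,y paired measurements (equal length >= 3).
#' @return the ICC (scalar).
#' @export
icc_two_way <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (all(x == y)) return(1)
    stop("zero variance with unequal values: ICC undefined")
  }
  n <- length(x); k <- 2
  m <- cbind(x, y)
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Consistency (two-way mixed, single-measure) ICC
#'
#' Companion to \code{icc_two_way}; insensitive to a systematic offset
#' between the two measurements.
#' @param x,y paired measurements.
#' @export
icc_consistency <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sse <- sum((m - gm)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Bland-Altman analysis
#'
#' @param x,y paired measurements.
#' @return named vector: bias (mean of x - y), loa_low, loa_high
#'   (bias -/+ 1.96 sample sd of the differences).
#' @export
bland_altman <- function(x, y) {
  d <- x - y
  b <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0
  c(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s)
}

#' Scan-rescan coefficients of variation (RMS-aggregated)
#'
#' Global mode: per subject, the two-point standard deviation of the two
#' global means (|x1 - x2|/sqrt(2)) divided by their mean, RMS-aggregated
#' over subjects. Segment-wise mode: per subject, the per-segment two-point
#' standard deviations are RMS-aggregated over segments, divided by the
#' subject's mean value, then RMS-aggregated over subjects.
#'
#' @param scan1,scan2 global mode: numeric vectors (one global mean per
#'   subject); segment-wise mode: matrices (subject x segment).
#' @param mode "global" or "segmentwise".
#' @return CoV in percent.
#' @export
cov_rms <- function(scan1, scan2, mode = c("global", "segmentwise")) {
  mode <- match.arg(mode)
  if (mode == "global") {
    stopifnot(length(scan1) == length(scan2))
    sd2 <- abs(scan1 - scan2) / sqrt(2)
    cv <- sd2 / ((scan1 + scan2) / 2)
    return(100 * sqrt(mean(cv^2)))
  }
  scan1 <- as.matrix(scan1); scan2 <- as.matrix(scan2)
  if (!all(dim(scan1) == dim(scan2)))
    stop("mismatched segment sets between the two scans")
  sd2 <- abs(scan1 - scan2) / sqrt(2)             # subject x segment
  rms_seg <- sqrt(rowMeans(sd2^2))
  subj_mean <- rowMeans((scan1 + scan2) / 2)
  cv <- rms_seg / subj_mean
  100 * sqrt(mean(cv^2))
}

#' Segment-wise SNR and SNR efficiency
#'
#' SNR per segment is the mean value divided by the voxelwise standard
#' deviation within the segment; SNR efficiency divides by the square root
#' of the total scan time in minutes.
#'
#' @param map parameter map (matrix).
#' @param labels segment labels.
#' @param scan_minutes total scan time (minutes).
#' @return list: per-segment data.frame (segment, snr, snr_eff, flagged) and
#'   the aggregate means over unflagged segments.
#' @export
snr_stats <- function(map, labels, scan_minutes) {
  tab <- segment_table(map, labels)
  flagged <- tab$sd == 0 | is.na(tab$sd)
  if (any(flagged))
    warning("segment(s) with zero variance excluded from the aggregate: ",
            paste(tab$segment[flagged], collapse = ", "))
  snr <- ifelse(flagged, NA_real_, tab$mean / tab$sd)
  eff <- snr / sqrt(scan_minutes)
  list(segments = data.frame(segment = tab$segment, snr = snr,
                             snr_eff = eff, flagged = flagged),
       mean_snr = mean(snr[!flagged]),
       mean_snr_eff = mean(eff[!flagged]))
}

#' SNR efficiency from an SNR value
#' @param snr signal-to-noise ratio. @param scan_minutes total scan time.
#' @export
snr_efficiency <- function(snr, scan_minutes) snr / sqrt(scan_minutes)

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors.
#' @return named vector: slope, intercept, r2.
#' @export
linear_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  c(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2)
}

#' Paired t-test p-value (thin wrapper)
#' @param x,y paired measurements.
#' @export
paired_t_p <- function(x, y) stats::t.test(x, y, paired = TRUE)$p.value
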