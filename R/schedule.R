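#' Pulse sequence configuration
#'
#' Describes the continuous T2prep-IR FLASH acquisition: a cycle of
#' preparation modules (an inversion optionally preceded by a T2-sensitizing
#' preparation of duration \code{prep_ms}) each followed by a recovery period
#' of FLASH readouts, with the excitation flip angle toggling between two
#' values from one recovery period to the next.
#'
#' @param tr_ms FLASH repetition time in ms.
#' @param te_ms echo time in ms (bookkeeping only; the signal model carries no
#'   TE term because TE is much shorter than the T2 values of interest).
#' @param flip_deg ordered pair of excitation flip angles in degrees.
#' @param prep_ms preparation durations in ms; 0 means a plain inversion.
#' @param recovery_ms length of each recovery period in ms.
#' @param n_periods number of recovery periods in the scan.
#' @param train_first if \code{TRUE}, the first excitation of every period is
#'   a training readout (0 degree projection line); readout roles alternate
#'   one-to-one thereafter.
#' @param combo_order optional integer matrix (10 x 2) giving, per period of
#'   the cycle, the 1-based indices into \code{prep_ms} and \code{flip_deg}.
#'   The default interleave pairs each preparation duration with the current
#'   flip angle while the flip angle toggles every period, so both flip
#'   angles visit every preparation duration across one 10-period cycle.
#' @return an object of class \code{mt_seq_config}.
#' @export
seq_config <- function(tr_ms = 3.5, te_ms = 1.6, flip_deg = c(3, 10),
                       prep_ms = c(0, 30, 40, 50, 60), recovery_ms = 2500,
                       n_periods = 73, train_first = TRUE,
                       combo_order = NULL) {
  stopifnot(tr_ms > 0, recovery_ms >= tr_ms, length(flip_deg) == 2,
            all(prep_ms >= 0), n_periods >= 1)
  n_prep <- length(prep_ms)
  if (is.null(combo_order)) {
    cyc <- 2L * n_prep
    combo_order <- cbind(prep = ((seq_len(cyc) - 1L) %% n_prep) + 1L,
                         flip = ((seq_len(cyc) - 1L) %% 2L) + 1L)
  }
  cfg <- list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
              prep_ms = prep_ms, recovery_ms = recovery_ms,
              n_periods = as.integer(n_periods),
              train_first = isTRUE(train_first),
              combo_order = combo_order)
  class(cfg) <- "mt_seq_config"
  cfg
}

#' Build the per-readout sequence timetable
#'
#' Expands a sequence configuration into the deterministic schedule executed
#' by the scanner: one row per preparation/recovery period and one row per
#' excitation. Imaging readouts advance the golden-angle counter
#' (111.24 degrees per imaging line) and the 3-step CAIPIRINHA phase cycle;
#' training readouts always sample the 0-degree line with no phase stepping.
#'
#' @param cfg an \code{mt_seq_config}.
#' @return an object of class \code{mt_schedule}: a list with elements
#'   \code{periods} (data.frame: period, combo, prep_ms, flip_deg,
#'   prev_flip_deg, n_readouts), \code{readouts} (data.frame: period, n, role,
#'   radial_angle_deg, phase_step, time_ms) and \code{cfg}.
#' @export
build_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "mt_seq_config"))
  if (cfg$recovery_ms < 2 * cfg$tr_ms)
    stop("period too short: recovery_ms must be at least 2 * tr_ms")
  n_read <- as.integer(floor(cfg$recovery_ms / cfg$tr_ms))
  cyc <- nrow(cfg$combo_order)
  p <- seq_len(cfg$n_periods) - 1L           # 0-based period index
  combo <- p %% cyc
  prep_i <- cfg$combo_order[combo + 1L, 1L]
  flip_i <- cfg$combo_order[combo + 1L, 2L]
  prev_combo <- (combo - 1L) %% cyc          # period 0 sees the nominal cycle end
  prev_flip_i <- cfg$combo_order[prev_combo + 1L, 2L]
  periods <- data.frame(
    period = p, combo = combo,
    prep_ms = cfg$prep_ms[prep_i],
    flip_deg = cfg$flip_deg[flip_i],
    prev_flip_deg = cfg$flip_deg[prev_flip_i],
    n_readouts = n_read)

  n <- rep(seq_len(n_read), times = cfg$n_periods)
  per <- rep(p, each = n_read)
  if (cfg$train_first) is_train <- (n %% 2L) == 1L else is_train <- (n %% 2L) == 0L
  m <- cumsum(!is_train) - 1L                # 0-based global imaging counter
  angle <- ifelse(is_train, 0, (m * golden_angle_deg()) %% 360)
  pstep <- ifelse(is_train, 0L, as.integer(m %% 3L))
  time_ms <- per * cfg$recovery_ms + (n - 1L) * cfg$tr_ms
  readouts <- data.frame(
    period = per, n = n,
    role = ifelse(is_train, "training", "imaging"),
    radial_angle_deg = angle, phase_step = pstep, time_ms = time_ms)

  out <- list(periods = periods, readouts = readouts, cfg = cfg)
  class(out) <- "mt_schedule"
  out
}

#' Golden-angle azimuthal increment (degrees)
#' @export
golden_angle_deg <- function() 111.24

#' The nominal cycle of preparation/flip combinations
#'
#' @param cfg an \code{mt_seq_config}.
#' @return data.frame with one row per combination of the cycle: combo
#'   (0-based), prep_ms, flip_deg, prev_flip_deg.
#' @export
cycle_combos <- function(cfg) {
  cyc <- nrow(cfg$combo_order)
  k <- seq_len(cyc)
  prev <- ((k - 2L) %% cyc) + 1L
  data.frame(combo = k - 1L,
             prep_ms = cfg$prep_ms[cfg$combo_order[k, 1L]],
             flip_deg = cfg$flip_deg[cfg$combo_order[k, 2L]],
             prev_flip_deg = cfg$flip_deg[cfg$combo_order[prev, 2L]])
}

#' @export
print.mt_schedule <- function(x, ...) {
  cat("<mt_schedule>", nrow(x$periods), "periods,",
      nrow(x$readouts), "readouts (",
      sum(x$readouts$role == "imaging"), "imaging /",
      sum(x$readouts$role == "training"), "training )\n")
  invisible(x)
}

#' Write a schedule as a flat tab-separated table
#'
#' @param schedule an \code{mt_schedule}.
#' @param path output file path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(schedule$readouts, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
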