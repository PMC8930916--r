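#' Default run configuration
#'
#' Nested configuration covering every pipeline stage. The \code{"default"}
#' preset mirrors the reference acquisition (160 matrix over a 270 mm FOV,
#' 73 recovery periods of 2.5 s, 8 coils); the \code{"tiny"} preset is a
#' desk-scale study (48 matrix, 16 periods, about 40 s of scan) small enough
#' for routine testing while exercising every stage.
#'
#' @param preset "tiny" or "default".
#' @return nested list of class \code{mt_config}.
#' @export
default_config <- function(preset = c("tiny", "default")) {
  preset <- match.arg(preset)
  tiny <- preset == "tiny"
  cfg <- list(
    seed = 1L,
    preset = preset,
    sequence = list(tr_ms = 3.5, te_ms = 1.6, flip_deg = c(3, 10),
                    prep_ms = c(0, 30, 40, 50, 60), recovery_ms = 2500,
                    n_periods = if (tiny) 16L else 73L, train_first = TRUE),
    phantom = list(grid_n = if (tiny) 48L else 160L, fov_mm = 270,
                   cardiac_period_ms = 920,
                   resp_period_ms = if (tiny) 2250 else 3800,
                   resp_amp_mm = 12, contraction_frac = 0.25,
                   n_coils = 8L, noise_sigma = 0,
                   n_card_frames = if (tiny) 64L else 32L,
                   resp_drift = !tiny),
    encoding = list(n_virtual_coils = if (tiny) 4L else 6L,
                    use_truth_coils = TRUE),
    gating = list(n_card = 20L, n_resp = 6L, resp_cut_hz = 0.7,
                  card_band_hz = c(0.5, 2.5)),
    lrt = list(feature_rank = 24L,
               dict_t1 = if (tiny) 11L else 21L,
               dict_t2 = if (tiny) 11L else 21L,
               dict_b1 = if (tiny) 5L else 7L,
               dict_eff = if (tiny) 4L else 7L,
               L_t1 = 6L, L_ta = 6L, L_c = 6L, L_r = 4L,
               iters = 60L),
    spatial = list(L1 = 24L, lambda_w = 0,
                   iters = 10L, dc_weight = FALSE),
    fit = list(refine = TRUE, support_frac = 0.08),
    metrics = list(scan_minutes = NULL))
  class(cfg) <- c("mt_config", "list")
  cfg
}

#' Build a run configuration from a preset plus overrides
#'
#' Unknown keys are rejected; known keys replace the preset values.
#'
#' @param preset "tiny" or "default".
#' @param overrides nested list of overrides.
#' @param seed optional global seed override.
#' @export
run_config <- function(preset = "tiny", overrides = list(), seed = NULL) {
  cfg <- default_config(preset)
  merge_cfg <- function(base, over, path = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", path, k)
      if (is.list(base[[k]]) && is.list(over[[k]]))
        base[[k]] <- merge_cfg(base[[k]], over[[k]], paste0(path, k, "/"))
      else base[[k]] <- over[[k]]
    }
    base
  }
  cfg <- merge_cfg(cfg, overrides)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- c("mt_config", "list")
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file with the same nesting as \code{default_config}.
#' @param preset base preset to override.
#' @export
read_config <- function(path, preset = "tiny") {
  run_config(preset, overrides = yaml::read_yaml(path))
}

dict_grids_from_cfg <- function(lrt) {
  list(t1_ms = exp(seq(log(100), log(3000), length.out = lrt$dict_t1)),
       t2_ms = exp(seq(log(10), log(3000), length.out = lrt$dict_t2)),
       b1 = seq(0.7, 1.3, length.out = lrt$dict_b1),
       eff = seq(-1, -0.7, length.out = lrt$dict_eff))
}

#' Save / load the scan container
#'
#' Single-file container holding the named groups (/schedule, /kspace,
#' /coils, /truth, and reconstruction products under /bins, /dictionary,
#' /subspaces, /factors). Round-trips bitwise.
#'
#' @param container named list. @param path file path.
#' @export
save_container <- function(container, path) {
  saveRDS(container, path)
  invisible(path)
}

#' @rdname save_container
#' @export
read_container <- function(path) readRDS(path)

#' Simulate a scan from a configuration
#'
#' Builds the schedule and phantom, runs the forward model, and returns (or
#' writes) the container.
#'
#' @param cfg an \code{mt_config}. @param out optional output file.
#' @return the container (invisibly if written).
#' @export
cmd_simulate <- function(cfg, out = NULL) {
  sq <- cfg$sequence
  scfg <- seq_config(tr_ms = sq$tr_ms, te_ms = sq$te_ms,
                     flip_deg = sq$flip_deg, prep_ms = sq$prep_ms,
                     recovery_ms = sq$recovery_ms, n_periods = sq$n_periods,
                     train_first = sq$train_first)
  schedule <- build_schedule(scfg)
  pc <- cfg$phantom
  pcfg <- phantom_config(grid_n = pc$grid_n, fov_mm = pc$fov_mm,
                         cardiac_period_ms = pc$cardiac_period_ms,
                         resp_period_ms = pc$resp_period_ms,
                         resp_amp_mm = pc$resp_amp_mm,
                         contraction_frac = pc$contraction_frac,
                         n_coils = pc$n_coils,
                         n_card_frames = pc$n_card_frames,
                         resp_drift = pc$resp_drift, seed = cfg$seed)
  phantom <- make_phantom(pcfg)
  raw <- simulate_scan(phantom, schedule, noise_sigma = pc$noise_sigma)
  container <- list(config = cfg, schedule = schedule, raw = raw,
                    version = as.character(utils::packageVersion("mtsms")))
  if (!is.null(out)) {
    save_container(container, out)
    return(invisible(container))
  }
  container
}

#' Reconstruct a container
#'
#' Runs the full chain: coil handling and compression, dictionary and
#' relaxation subspaces, self-gated binning, training-tensor assembly and
#' completion, HOSVD factor extraction, and the spatial-factor solve.
#'
#' @param container from \code{cmd_simulate} (or a path).
#' @param cfg optional config override (defaults to the stored one).
#' @return the container augmented with /bins, /dictionary, /subspaces,
#'   /factors (core factors, Phi, u_x) and a residual report.
#' @export
cmd_reconstruct <- function(container, cfg = NULL) {
  if (is.character(container)) container <- read_container(container)
  if (is.null(cfg)) cfg <- container$config
  raw <- container$raw
  schedule <- container$schedule
  if (!cfg$encoding$use_truth_coils)
    raw$coils <- estimate_coils(raw)
  raw <- compress_coils(raw, cfg$encoding$n_virtual_coils)
  dict <- build_dictionary(schedule, grids = dict_grids_from_cfg(cfg$lrt))
  sub <- fit_subspaces(dict, cfg$lrt$L_t1, cfg$lrt$L_ta)
  bins <- assign_bins(raw, dict, sub, n_card = cfg$gating$n_card,
                      n_resp = cfg$gating$n_resp,
                      resp_cut_hz = cfg$gating$resp_cut_hz,
                      card_band_hz = cfg$gating$card_band_hz,
                      seed = cfg$seed)
  st <- assemble_training_tensor(raw, bins, dict,
                                 feature_rank = cfg$lrt$feature_rank)
  rk <- pmin(c(cfg$spatial$L1, cfg$lrt$L_c, cfg$lrt$L_r),
             dim(st$data)[c(1, 4, 5)])
  cm <- complete_tensor(st, sub, iters = cfg$lrt$iters, ranks = rk)
  fs <- hosvd_factors(cm$data,
                      pmin(c(cfg$spatial$L1, cfg$lrt$L_t1, cfg$lrt$L_ta,
                             cfg$lrt$L_c, cfg$lrt$L_r), dim(st$data)), sub)
  phi <- build_phi(fs)
  ip <- imaging_phi(raw, bins, dict, sub, phi)
  traj <- make_trajectory(raw$grid_n, raw$oversample)
  E <- make_operator(traj, raw$coils, raw$imaging_meta$radial_angle_deg,
                     raw$imaging_meta$phase_step)
  sp <- solve_spatial(raw, E, ip$phi_lines, lambda_w = cfg$spatial$lambda_w,
                      iters = cfg$spatial$iters,
                      dc_weight = isTRUE(cfg$spatial$dc_weight))
  container$raw_recon <- raw
  container$dictionary <- dict
  container$subspaces <- sub
  container$bins <- bins
  container$factors <- list(factor_set = fs, phi = phi, u_x = sp$u_x,
                            imaging_phi = ip, completion = cm[c("trace",
                              "trace_polish", "lambda", "polish_ranks")],
                            spatial_trace = sp$trace)
  container
}

#' Fit parameter maps from a reconstructed container
#'
#' @param container reconstructed container (or path).
#' @param out_dir optional directory for NIfTI maps + segment CSV.
#' @return the container with \code{maps} added.
#' @export
cmd_fit <- function(container, out_dir = NULL) {
  if (is.character(container)) container <- read_container(container)
  cfg <- container$config
  f <- container$factors
  maps <- map_volume(f$u_x, f$phi, container$dictionary,
                     container$subspaces, container$bins,
                     grid_n = container$raw$grid_n,
                     support_frac = cfg$fit$support_frac,
                     refine = cfg$fit$refine)
  container$maps <- maps
  if (!is.null(out_dir)) {
    write_maps_nifti(maps, out_dir, fov_mm = container$raw$fov_mm)
  }
  container
}

#' Evaluate maps against the truth sidecar or a repeat run
#'
#' With one container: per-slice myocardial recovery errors against the
#' phantom truth. With two: scan-rescan repeatability (global/segment CoV,
#' ICC, Bland-Altman) over the myocardial masks.
#'
#' @param container fitted container. @param container2 optional repeat run.
#' @return data.frame of metrics.
#' @export
cmd_evaluate <- function(container, container2 = NULL) {
  if (is.character(container)) container <- read_container(container)
  maps <- container$maps
  if (is.null(maps)) stop("container has no fitted maps; run cmd_fit first")
  truth <- container$raw$truth
  if (is.null(container2)) {
    if (is.null(truth)) stop("no truth sidecar and no second run supplied")
    out <- list()
    for (p in c("t1_ms", "t2_ms")) {
      for (s in seq_len(maps$nslice)) {
        tm <- truth$maps[[s]]
        myo <- tm$class == 2
        e <- abs(maps[[p]][, , s][myo] - tm[[p]][myo]) / tm[[p]][myo]
        out[[length(out) + 1L]] <- data.frame(
          param = p, slice = s, metric = "myocardial_median_err_pct",
          value = 100 * stats::median(e, na.rm = TRUE))
      }
    }
    return(do.call(rbind, out))
  }
  if (is.character(container2)) container2 <- read_container(container2)
  maps2 <- container2$maps
  out <- list()
  for (p in c("t1_ms", "t2_ms")) {
    m1 <- c(); m2 <- c()
    for (s in seq_len(maps$nslice)) {
      myo <- container$raw$truth$maps[[s]]$class == 2
      m1[s] <- stats::median(maps[[p]][, , s][myo], na.rm = TRUE)
      m2[s] <- stats::median(maps2[[p]][, , s][myo], na.rm = TRUE)
    }
    ba <- bland_altman(m1, m2)
    out[[length(out) + 1L]] <- data.frame(
      param = p, slice = NA,
      metric = c("cov_global_pct", "icc", "ba_bias", "ba_loa_low",
                 "ba_loa_high"),
      value = c(cov_rms(m1, m2, "global"), icc_two_way(m1, m2), ba[1], ba[2],
                ba[3]))
  }
  do.call(rbind, out)
}
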