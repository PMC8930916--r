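# Shared simulated datasets, built once per test run and cached.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- builder()
  .sim_cache[[key]]
}

# minimal scan for unit-level checks: 2 periods, small grid, few coils
unit_sim <- function() cached("unit", function() {
  sch <- build_schedule(seq_config(n_periods = 2))
  ph <- make_phantom(phantom_config(grid_n = 32, n_coils = 2, seed = 11,
                                    n_card_frames = 8, resp_drift = FALSE))
  list(sch = sch, ph = ph, raw = simulate_scan(ph, sch))
})

# static scan (no motion) for linearity / coil-estimation checks
static_sim <- function() cached("static", function() {
  sch <- build_schedule(seq_config(n_periods = 2))
  ph <- make_phantom(phantom_config(grid_n = 32, n_coils = 4, seed = 12,
                                    n_card_frames = 4, resp_amp_mm = 0,
                                    contraction_frac = 0, resp_drift = FALSE))
  list(sch = sch, ph = ph, raw = simulate_scan(ph, sch))
})

# motion-rich scan for the self-gating checks (~35 s of simulated scan)
gating_sim <- function() cached("gating", function() {
  sch <- build_schedule(seq_config(n_periods = 14))
  # breathing period chosen so its overtones stay clear of the cardiac line
  ph <- make_phantom(phantom_config(grid_n = 32, n_coils = 4, seed = 13,
                                    n_card_frames = 32,
                                    resp_period_ms = 3300))
  raw <- simulate_scan(ph, sch)
  dict <- build_dictionary(sch, grids = list(
    t1_ms = exp(seq(log(100), log(3000), length.out = 9)),
    t2_ms = exp(seq(log(10), log(3000), length.out = 9)),
    b1 = seq(0.7, 1.3, length.out = 5),
    eff = seq(-1, -0.7, length.out = 3)))
  sub <- fit_subspaces(dict, 6, 6)
  list(sch = sch, ph = ph, raw = raw, dict = dict, sub = sub,
       bins = assign_bins(raw, dict, sub, seed = 2))
})

# the desk-scale study used by the headline acceptance checks: full pipeline
# on the tiny preset (48 matrix, 16 recovery periods, noiseless)
acceptance_pipeline <- function() cached("acceptance", function() {
  cfg <- run_config("tiny", seed = 1)
  ct <- cmd_simulate(cfg)
  ct <- cmd_reconstruct(ct)
  ct <- cmd_fit(ct)
  ct
})

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

random_tissue <- function() {
  tissue_params(amp = runif(1, 0.5, 2),
                eff = runif(1, -1, -0.7),
                b1 = runif(1, 0.5, 1.3),
                t1_ms = exp(runif(1, log(100), log(3000))),
                t2_ms = exp(runif(1, log(10), log(300))))
}
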