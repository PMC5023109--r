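# Shared simulation runs for the test suite. The heavyweight wild-type
# trajectory and the scaled-down perturbation baseline are computed once
# per session and reused across test blocks (the model is deterministic,
# so caching cannot change any result).

.run_cache <- new.env(parent = emptyenv())

# full wild-type development at the packaged defaults
wildtype_run <- function() {
  if (is.null(.run_cache$wt))
    .run_cache$wt <- simulate_eye_disc(eye_disc_parameters(), t_end = 75,
                                       output_every = 1,
                                       snapshot_times = c(20, 40, 60))
  .run_cache$wt
}

# small-disc configuration for perturbation studies: the geometry is
# scaled down and the margin influx raised somewhat above the furrow-
# initiation threshold so that influx titrations still initiate
perturbation_params <- function(...) {
  eye_disc_parameters(a = 35, b = 25, n_rings = 10, eta = 3e-4, ...)
}

perturbation_wt_run <- function() {
  if (is.null(.run_cache$mut_wt))
    .run_cache$mut_wt <- simulate_eye_disc(perturbation_params(), t_end = 30,
                                           output_every = 2)
  .run_cache$mut_wt
}

# furrow speed over the travelling-front window of a run
run_speed <- function(r, from = 8) {
  sel <- r$time >= from & r$PL > 0 & r$PL < 0.93 * r$L_AP
  if (sum(sel) < 3) return(NA_real_)
  fit_mf_kinetics(r$time[sel], r$PL[sel])$speed
}
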