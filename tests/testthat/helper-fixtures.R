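# Shared small fixtures, built in code at test time.

tiny_setup <- function(grid_size = 32L, n_angles = 48L,
                       framing = make_framing(list(c(4, 300), c(4, 600)))) {
  sim_setup(spec = phantom_spec(grid_size = grid_size),
            framing = framing,
            geom = projection_geometry(n_angles = n_angles,
                                       n_radial = grid_size,
                                       bin_size_mm = 0.776 * 128 / grid_size),
            dt_s = 5)
}

default_frame_tacs <- function() {
  fr <- make_framing()
  cr <- reference_tac()
  kin <- kinetic_params()
  act <- activation_shape()
  list(framing = fr,
       C_R = frame_activity(cr, fr),
       active = frame_activity(simulate_ntpet_tac(kin, act, cr), fr),
       rest = frame_activity(simulate_ntpet_tac(kin, NULL, cr), fr),
       kin = kin, act = act)
}

# TAC generated directly on the (0-prepended) frame mid-time grid with the
# same trapezoidal convention the fitter uses: exact linear-model data for
# recovery tests.
ongrid_tac <- function(kin, act, C_R_frames) {
  t0 <- c(0, C_R_frames$time_min)
  v0 <- c(0, C_R_frames$value)
  ct <- simulate_ntpet_tac(kin, act, new_region_tac_for_tests(t0, v0))
  new_region_tac_for_tests(C_R_frames$time_min, ct$value[-1])
}

new_region_tac_for_tests <- function(time_min, value) {
  out <- tibble::tibble(time_min = time_min, value = value)
  class(out) <- c("region_tac", class(out))
  out
}

as_frame_tac <- function(tac, framing) {
  out <- tibble::tibble(frame = framing$frame, time_min = tac$time_min,
                        value = tac$value)
  attr(out, "framing") <- framing
  class(out) <- c("region_tac", class(out))
  out
}
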