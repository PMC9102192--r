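# Small configurations used across tests: scaled-down image/curve/event
# counts keep runtimes low without changing the planted-signal settings.
quick_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    colony = colony_spec(n_images = 3, shift_max = 8, pixel_noise_sd = 3),
    afm = afm_spec(n_curves = 20, curve_length = 150),
    rtdc = rtdc_spec(n_events = 400),
    ...
  )
}

# flat RGB image filled with one colour
flat_image <- function(h, w, rgb = c(0, 0, 0)) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}
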