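#' Generate synthetic AFM approach curves with known moduli
#'
#' Builds approach segments from the Hertz-Sneddon forward model: heights
#' descend linearly from `z_max_um` to 0, the true contact point is drawn
#' uniformly from `z0_range_um` (so the early part of each curve is a pure
#' baseline region), and additive Gaussian force noise is applied. One batch
#' of `n_curves` is produced per entry of `E_true`.
#'
#' @param config A [sim_config()] object; settings under `config$afm`.
#' @return A list with
#'   * `curves`: list of [force_curve()] objects;
#'   * `truth`: data frame `curve`, `group`, `E_true` (Pa), `z0` (um),
#'     `F0` (nN);
#'   * `model`: the [indenter_model()] used to synthesise the forces.
#' @export
gen_force_curves <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  as <- config$afm
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "afm"))

  model <- indenter_model(as$geometry, as$half_angle_deg, as$poisson)
  groups <- seq_along(as$E_true)
  total <- length(groups) * as$n_curves
  curves <- vector("list", total)
  truth <- data.frame(curve = sprintf("c%04d", seq_len(total)),
                      group = rep(groups, each = as$n_curves),
                      E_true = rep(as$E_true, each = as$n_curves),
                      z0 = NA_real_, F0 = NA_real_)
  h <- seq(as$z_max_um, 0, length.out = as$curve_length)
  for (i in seq_len(total)) {
    z0 <- stats::runif(1, as$z0_range_um[1], as$z0_range_um[2])
    f <- as$f0_nn + model_force(pmax(0, z0 - h), truth$E_true[i], model)
    if (as$force_noise_nn > 0)
      f <- f + stats::rnorm(length(f), 0, as$force_noise_nn)
    curves[[i]] <- force_curve(h, f, meta = list(id = truth$curve[i],
                                                 speed_um_s = 30,
                                                 setpoint_nn = 1))
    truth$z0[i] <- z0
    truth$F0[i] <- as$f0_nn
  }
  list(curves = curves, truth = truth, model = model)
}

#' Generate a synthetic force map with a soft cell on a stiff substrate
#'
#' Arranges synthetic approach curves on an n x n grid (study default
#' 64 x 64): pixels inside a central circular cell mask use the first entry
#' of `E_true`, pixels outside use `E_substrate`.
#'
#' @param config A [sim_config()] object; settings under `config$afm`.
#' @param n Grid side length, overriding `config$afm$map_n`.
#' @return A list with `curves` (length n^2 list, column-major grid),
#'   `mask` (logical n x n, TRUE = cell), `E_grid` (true moduli, n x n),
#'   and `model`.
#' @export
gen_force_map <- function(config, n = config$afm$map_n) {
  stopifnot(inherits(config, "sim_config"))
  as <- config$afm
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "map"))

  model <- indenter_model(as$geometry, as$half_angle_deg, as$poisson)
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  c0 <- (n + 1) / 2
  mask <- (yy - c0)^2 + (xx - c0)^2 <= (as$map_cell_radius * n / 2)^2
  E_grid <- matrix(as$E_substrate, n, n)
  E_grid[mask] <- as$E_true[1]

  h <- seq(as$z_max_um, 0, length.out = as$curve_length)
  curves <- vector("list", n * n)
  for (i in seq_len(n * n)) {
    z0 <- stats::runif(1, as$z0_range_um[1], as$z0_range_um[2])
    f <- as$f0_nn + model_force(pmax(0, z0 - h), E_grid[i], model)
    if (as$force_noise_nn > 0)
      f <- f + stats::rnorm(length(f), 0, as$force_noise_nn)
    curves[[i]] <- force_curve(h, f)
  }
  list(curves = curves, mask = mask, E_grid = E_grid, model = model)
}
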