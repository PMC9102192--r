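#' Indenter model for Hertz-Sneddon contact mechanics
#'
#' Describes the AFM tip geometry used in the quadratic Hertz-Sneddon force
#' law `F = C(theta) * E / (1 - nu^2) * delta^2`. For a cone
#' `C = (2/pi) tan(theta)`; for a four-sided pyramid the Bilodeau prefactor
#' `C = 0.7453 tan(theta)` applies, the appropriate default for pyramidal
#' silicon tips on silicon-nitride cantilevers. The half angle is probe
#' territory (datasheet, not assay output) and must be supplied.
#'
#' @param geometry `"four_sided_pyramid"` (default) or `"cone"`.
#' @param half_angle Tip half-opening angle in degrees, in (0, 90).
#' @param poisson Poisson ratio of the sample; 0.5 (incompressible cell) is
#'   the near-universal AFM convention.
#' @return An object of class `indenter_model`.
#' @export
#' @examples
#' indenter_model("cone", half_angle = 35)
indenter_model <- function(geometry = c("four_sided_pyramid", "cone"),
                           half_angle = 35, poisson = 0.5) {
  geometry <- match.arg(geometry)
  if (!is.finite(half_angle) || half_angle <= 0 || half_angle >= 90)
    stop("`half_angle` must be in (0, 90) degrees", call. = FALSE)
  if (!is.finite(poisson) || poisson < 0 || poisson > 0.5 + 1e-9)
    stop("`poisson` must be in [0, 0.5]", call. = FALSE)
  structure(list(geometry = geometry, half_angle = half_angle,
                 poisson = poisson),
            class = "indenter_model")
}

#' @export
print.indenter_model <- function(x, ...) {
  cat(sprintf("Indenter: %s, half angle %.1f deg, Poisson %.2f\n",
              x$geometry, x$half_angle, x$poisson))
  invisible(x)
}

# Geometric prefactor C(theta) of F = C * E/(1-nu^2) * delta^2.
hs_prefactor <- function(model) {
  tan_t <- tan(model$half_angle * pi / 180)
  switch(model$geometry,
         cone = (2 / pi) * tan_t,
         four_sided_pyramid = 0.7453 * tan_t)
}

#' Hertz-Sneddon forward force model
#'
#' Force exerted by a conical or pyramidal indenter at indentation depth
#' `delta` into an elastic half-space of Young's modulus `E`. Units are the
#' instrument's: `delta` in um, `E` in Pa, force in nN
#' (Pa x um^2 = 1e-3 nN).
#'
#' @param delta Indentation depth(s) in um, >= 0.
#' @param E Young's modulus in Pa.
#' @param model An [indenter_model()].
#' @return Force in nN, same length as `delta`.
#' @export
#' @examples
#' model_force(1, E = 1000, indenter_model("cone", 35))
model_force <- function(delta, E, model) {
  stopifnot(inherits(model, "indenter_model"))
  if (any(delta < 0)) stop("`delta` must be >= 0", call. = FALSE)
  hs_prefactor(model) * E / (1 - model$poisson^2) * delta^2 * 1e-3
}

#' Construct a force-distance approach curve
#'
#' @param height Piezo height samples in um, in acquisition (time) order:
#'   the tip approaches, so heights decrease towards the surface.
#' @param force Measured force in nN, same length.
#' @param meta Optional named list (probe id, speed, setpoint, position).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(height, force, meta = list()) {
  if (length(height) != length(force))
    stop("`height` and `force` must have equal length", call. = FALSE)
  if (length(height) < 50L)
    stop("a force curve needs at least 50 samples", call. = FALSE)
  if (any(!is.finite(height)) || any(!is.finite(force)))
    stop("force curve samples must be finite", call. = FALSE)
  d <- diff(height)
  if (!(all(d <= 0) || all(d >= 0)))
    stop("`height` must be monotone", call. = FALSE)
  structure(list(height = as.numeric(height), force = as.numeric(force),
                 meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force-distance curve: %d samples, height %.2f to %.2f um, force %.3f to %.3f nN\n",
              length(x$height), max(x$height), min(x$height),
              min(x$force), max(x$force)))
  invisible(x)
}

#' Fit the Hertz-Sneddon model to an approach curve
#'
#' The force baseline `F0` is the median force over the first 20% of the
#' approach (tip far from the sample). The contact point `z0` and modulus
#' `E` are then found by a coarse grid over candidate contact points (every
#' `grid_step` of the height span) followed by local refinement, minimising
#' `sum((F - F0 - model_force(delta))^2)` with `delta = max(0, z0 - height)`.
#' Indentation is computed from piezo height without cantilever-deflection
#' correction (the exported curves carry force vs height and no spring
#' constant), a documented approximation.
#'
#' The fit is declared non-converged - not an error - when fewer than 10
#' post-contact samples exist at the best contact point, when the relative
#' improvement over the baseline-only model is below 1%, or when `E` hits
#' the bounds.
#'
#' @param curve A [force_curve()].
#' @param model An [indenter_model()].
#' @param baseline_frac Fraction of the approach used for `F0` (default 0.2).
#' @param grid_step Coarse contact-point grid spacing as a fraction of the
#'   height span (default 0.02).
#' @param e_bounds Plausible modulus range in Pa; default `[1, 1e6]`.
#' @param min_contact Minimum number of post-contact samples (default 10).
#' @return An object of class `hs_fit`: list with `E` (Pa), `z0` (um),
#'   `F0` (nN), `rms_residual` (nN), `converged`, `n_contact`.
#' @export
#' @examples
#' m <- indenter_model("cone", 35)
#' h <- seq(5, 0, length.out = 200)
#' f <- model_force(pmax(0, 1.5 - h), E = 1000, m)
#' fit_curve(force_curve(h, f), m)
fit_curve <- function(curve, model, baseline_frac = 0.2, grid_step = 0.02,
                      e_bounds = c(1, 1e6), min_contact = 10L) {
  stopifnot(inherits(curve, "force_curve"), inherits(model, "indenter_model"))
  h <- curve$height; f <- curve$force
  n <- length(h)
  n_base <- max(2L, ceiling(baseline_frac * n))
  F0 <- stats::median(f[seq_len(n_base)])
  fr <- f - F0

  kappa <- hs_prefactor(model) / (1 - model$poisson^2) * 1e-3  # nN per Pa um^2
  sse_at <- function(z0) {
    delta <- pmax(0, z0 - h)
    d2 <- delta^2
    s4 <- sum(d2 * d2)
    k <- if (s4 > 0) max(0, sum(fr * d2) / s4) else 0
    sum((fr - k * d2)^2)
  }
  k_at <- function(z0) {
    delta <- pmax(0, z0 - h)
    d2 <- delta^2
    s4 <- sum(d2 * d2)
    if (s4 > 0) max(0, sum(fr * d2) / s4) else 0
  }

  span <- range(h)
  grid <- seq(span[1], span[2], by = grid_step * diff(span))
  sse <- vapply(grid, sse_at, numeric(1))
  i <- which.min(sse)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse_at, c(lo, hi), tol = 1e-7 * diff(span))
  z0 <- opt$minimum
  if (sse_at(grid[i]) < opt$objective) z0 <- grid[i]

  k <- k_at(z0)
  E <- k / kappa
  n_contact <- sum(h < z0)
  sse_fit <- sse_at(z0)
  sse_baseline <- sum(fr^2)
  improvement <- if (sse_baseline > 0) 1 - sse_fit / sse_baseline else 0
  converged <- n_contact >= min_contact &&
    improvement >= 0.01 &&
    E > e_bounds[1] && E < e_bounds[2]

  structure(list(E = E, z0 = z0, F0 = F0,
                 rms_residual = sqrt(sse_fit / n),
                 converged = converged, n_contact = n_contact,
                 improvement = improvement, model = model, curve = curve),
            class = "hs_fit")
}

#' @export
print.hs_fit <- function(x, ...) {
  cat("Hertz-Sneddon fit\n")
  if (x$converged) {
    cat(sprintf("  E = %.4g Pa, contact point z0 = %.4g um, baseline F0 = %.4g nN\n",
                x$E, x$z0, x$F0))
    cat(sprintf("  rms residual %.4g nN over %d samples (%d post-contact)\n",
                x$rms_residual, length(x$curve$height), x$n_contact))
  } else {
    cat("  did not converge (flat curve, too few post-contact samples, or E at bounds)\n")
  }
  invisible(x)
}

#' @export
coef.hs_fit <- function(object, ...) {
  c(E = object$E, z0 = object$z0, F0 = object$F0)
}

#' @export
predict.hs_fit <- function(object, height = object$curve$height, ...) {
  delta <- pmax(0, object$z0 - height)
  object$F0 + model_force(delta, object$E, object$model)
}

#' @export
residuals.hs_fit <- function(object, ...) {
  object$curve$force - predict(object)
}

#' @export
plot.hs_fit <- function(x, ...) {
  graphics::plot(x$curve$height, x$curve$force, pch = 16, cex = 0.4,
                 xlab = "height (um)", ylab = "force (nN)",
                 xlim = rev(range(x$curve$height)), ...)
  o <- order(x$curve$height)
  graphics::lines(x$curve$height[o], predict(x)[o], col = 2, lwd = 2)
  graphics::abline(v = x$z0, lty = 2, col = "grey40")
  invisible(x)
}

#' Fit a batch of force curves
#'
#' @param curves List of [force_curve()] objects.
#' @param model An [indenter_model()].
#' @param ... Passed to [fit_curve()].
#' @return Data frame with one row per curve: `E`, `z0`, `F0`,
#'   `rms_residual`, `converged`, `n_contact`.
#' @export
fit_curves <- function(curves, model, ...) {
  fits <- lapply(curves, fit_curve, model = model, ...)
  data.frame(
    E = vapply(fits, `[[`, numeric(1), "E"),
    z0 = vapply(fits, `[[`, numeric(1), "z0"),
    F0 = vapply(fits, `[[`, numeric(1), "F0"),
    rms_residual = vapply(fits, `[[`, numeric(1), "rms_residual"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    n_contact = vapply(fits, `[[`, integer(1), "n_contact")
  )
}

#' Summarise a force map over a cell mask
#'
#' Fits every masked pixel of an n x n force map and reports the per-cell
#' Young's modulus as the median over converged fits, together with the
#' converged fraction.
#'
#' @param map A force map as returned by [gen_force_map()]: list with
#'   `curves` (list of length n^2, grid column-major) and `mask`
#'   (logical n x n).
#' @param model An [indenter_model()].
#' @param mask Optional logical matrix overriding `map$mask`.
#' @param ... Passed to [fit_curve()].
#' @return List with `E_median` (Pa), `converged_fraction`, `n_masked`,
#'   and the per-pixel `fits` data frame (masked pixels only).
#' @export
summarize_map <- function(map, model, mask = map$mask, ...) {
  idx <- which(as.vector(mask))
  if (length(idx) == 0L) stop("mask selects no pixels", call. = FALSE)
  fits <- fit_curves(map$curves[idx], model, ...)
  conv <- fits$converged
  if (!any(conv)) stop("no converged fits under the mask", call. = FALSE)
  list(E_median = stats::median(fits$E[conv]),
       converged_fraction = mean(conv),
       n_masked = length(idx),
       fits = fits)
}
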