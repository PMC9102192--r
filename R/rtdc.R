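#' RT-DC event filter configuration
#'
#' The study's gating: cell area 70-2000 um^2 (removes debris and
#' multicellular clusters), porosity 1.00-1.05 (removes damaged cells),
#' and a minimum of 1000 filtered cells per measurement.
#'
#' @param area_range Closed area interval in um^2.
#' @param porosity_range Closed porosity interval.
#' @param min_events Minimum retained events per measurement before the
#'   measurement is flagged.
#' @return An object of class `rtdc_filter_config`.
#' @export
rtdc_filter_config <- function(area_range = c(70, 2000),
                               porosity_range = c(1.00, 1.05),
                               min_events = 1000L) {
  if (area_range[1] >= area_range[2])
    stop("`area_range` lower bound must be below upper", call. = FALSE)
  if (porosity_range[1] >= porosity_range[2])
    stop("`porosity_range` lower bound must be below upper", call. = FALSE)
  structure(list(area_range = area_range, porosity_range = porosity_range,
                 min_events = as.integer(min_events)),
            class = "rtdc_filter_config")
}

#' Filter RT-DC events by area and porosity gates
#'
#' An event is retained iff its area lies in the closed area interval AND
#' its porosity in the closed porosity interval. Exclusions are attributed
#' to the first failing rule (area, then porosity) so per-rule counts plus
#' the retained count add up to the input count.
#'
#' @param events Data frame with at least `area_um2` and `porosity` columns
#'   (plus any others, e.g. `deformation`, `E_kpa`, carried through).
#' @param config An [rtdc_filter_config()].
#' @return A list with
#'   * `retained`: the retained subset of `events`;
#'   * `qc`: an `rtdc_qc` object with `n_input`, `n_retained`,
#'     `excluded_area`, `excluded_porosity`, and `low_count`
#'     (TRUE when fewer than `min_events` events survive).
#' @export
#' @examples
#' ev <- data.frame(area_um2 = c(50, 100, 100), porosity = c(1.02, 1.06, 1.01))
#' filter_events(ev, rtdc_filter_config())$qc
filter_events <- function(events, config = rtdc_filter_config()) {
  stopifnot(inherits(config, "rtdc_filter_config"))
  if (!all(c("area_um2", "porosity") %in% names(events)))
    stop("`events` needs columns `area_um2` and `porosity`", call. = FALSE)
  a_ok <- events$area_um2 >= config$area_range[1] &
    events$area_um2 <= config$area_range[2]
  p_ok <- events$porosity >= config$porosity_range[1] &
    events$porosity <= config$porosity_range[2]
  keep <- a_ok & p_ok
  qc <- structure(
    list(n_input = nrow(events), n_retained = sum(keep),
         excluded_area = sum(!a_ok),
         excluded_porosity = sum(a_ok & !p_ok),
         min_events = config$min_events,
         low_count = sum(keep) < config$min_events),
    class = "rtdc_qc"
  )
  list(retained = events[keep, , drop = FALSE], qc = qc)
}

#' @export
print.rtdc_qc <- function(x, ...) {
  cat(sprintf("RT-DC gating: %d of %d events retained (%d excluded by area, %d by porosity)\n",
              x$n_retained, x$n_input, x$excluded_area, x$excluded_porosity))
  if (x$low_count)
    cat(sprintf("  WARNING: fewer than %d filtered cells in this measurement\n",
                x$min_events))
  invisible(x)
}

#' Summarise RT-DC measurements and average duplicates per treatment
#'
#' Computes per-measurement medians of Young's modulus, deformation and
#' area over (already filtered) events, then averages duplicate measurement
#' medians within each treatment, matching the study's
#' duplicates-per-treatment design.
#'
#' @param events Data frame of retained events with columns `E_kpa`,
#'   `deformation`, `area_um2` plus `measurement` and `treatment` ids.
#' @param measurement,treatment Column names of the measurement and
#'   treatment identifiers.
#' @return A list with `per_measurement` and `per_treatment` data frames of
#'   medians (`E_kpa`, `deformation`, `area_um2`) and event counts.
#' @export
summarize_measurement <- function(events, measurement = "measurement",
                                  treatment = "treatment") {
  if (nrow(events) == 0L) stop("no events to summarise", call. = FALSE)
  if (!measurement %in% names(events))
    events[[measurement]] <- "m1"
  if (!treatment %in% names(events))
    events[[treatment]] <- "t1"
  vars <- intersect(c("E_kpa", "deformation", "area_um2"), names(events))
  med <- stats::aggregate(events[vars], by = list(
    treatment = events[[treatment]], measurement = events[[measurement]]),
    FUN = stats::median)
  med$n_events <- stats::aggregate(
    seq_len(nrow(events)),
    by = list(treatment = events[[treatment]],
              measurement = events[[measurement]]),
    FUN = length)$x
  per_trt <- stats::aggregate(med[vars], by = list(treatment = med$treatment),
                              FUN = mean)
  list(per_measurement = med, per_treatment = per_trt)
}

#' Correlate paired AFM and RT-DC modulus summaries
#'
#' Pearson product-moment correlation between per-sample Young's moduli
#' obtained by the two methods.
#'
#' @param afm,rtdc Paired numeric vectors (same samples, same order).
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
correlate_moduli <- function(afm, rtdc) {
  if (length(afm) != length(rtdc))
    stop("`afm` and `rtdc` must be paired (equal length)", call. = FALSE)
  if (length(afm) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(afm) == 0 || stats::sd(rtdc) == 0)
    stop("zero variance in one of the modulus vectors", call. = FALSE)
  ct <- stats::cor.test(afm, rtdc, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(afm))
}

#' Generate synthetic RT-DC events with planted gate membership
#'
#' Planted in-gate events satisfy both study gates; contaminants violate at
#' least one bound (small debris, oversized clusters, or high-porosity
#' damaged cells). Deformation is uniform on [0, 0.3) and the Young's
#' modulus column is log-normal, standing in for the upstream
#' deformation-to-modulus conversion the acquisition software performs.
#'
#' @param config A [sim_config()] object; settings under `config$rtdc`.
#' @return A list with
#'   * `events`: data frame `area_um2`, `deformation`, `porosity`, `E_kpa`;
#'   * `truth`: data frame with logical `in_gate`, one row per event.
#' @export
gen_rtdc_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rs <- config$rtdc
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "rtdc"))

  n <- rs$n_events
  in_gate <- stats::runif(n) < rs$fraction_in_gate
  ar <- rs$area_range_um2; pr <- rs$porosity_range
  area <- stats::runif(n, ar[1], ar[2])
  porosity <- stats::runif(n, pr[1], pr[2])
  # contaminants: pick a violation mode per event
  bad <- which(!in_gate)
  mode <- sample(c("debris", "cluster", "damaged"), length(bad), replace = TRUE)
  area[bad[mode == "debris"]] <-
    stats::runif(sum(mode == "debris"), 5, ar[1] - 0.1)
  area[bad[mode == "cluster"]] <-
    stats::runif(sum(mode == "cluster"), ar[2] + 1, 2 * ar[2])
  area[bad[mode == "damaged"]] <-
    stats::runif(sum(mode == "damaged"), ar[1], ar[2])
  porosity[bad[mode == "damaged"]] <-
    stats::runif(sum(mode == "damaged"), pr[2] + 0.005, pr[2] + 0.25)

  events <- data.frame(
    area_um2 = area,
    deformation = stats::runif(n, 0, 0.3),
    porosity = porosity,
    E_kpa = stats::rlnorm(n, rs$e_meanlog, rs$e_sdlog)
  )
  truth <- data.frame(
    in_gate = events$area_um2 >= ar[1] & events$area_um2 <= ar[2] &
      events$porosity >= pr[1] & events$porosity <= pr[2]
  )
  list(events = events, truth = truth)
}
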