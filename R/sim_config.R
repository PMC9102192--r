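#' Simulation configuration for the synthetic coculture study
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults reproduce the dimensions of the 55-patient HNSCC
#' cohort (subtype mix 18 AT / 11 BA / 14 CL / 12 ME, 16 of 55 patients in
#' lactate-gene cluster 2) and the instrument settings of the assays the
#' pipeline processes (1 nN AFM setpoint, 64 x 64 force maps, RT-DC gates
#' 70-2000 um^2 and porosity 1.00-1.05).
#'
#' All generators derive their random streams deterministically from `seed`,
#' so regenerating with an identical configuration reproduces identical
#' output byte for byte.
#'
#' @param seed Integer master seed; per-generator substreams are derived
#'   from it deterministically.
#' @param n_patients Cohort size (at least 8).
#' @param subtype_proportions Named non-negative weights for AT/BA/CL/ME
#'   summing to 1.
#' @param marker_effect Signed z-scale shift applied to each subtype's
#'   signature markers ("high" = `+marker_effect`, "low" = `-marker_effect`).
#' @param noise_sd Standard deviation of marker noise on the standardised
#'   scale.
#' @param flip_prob Probability that a forced binary covariate (smoking = 1
#'   for classical, p16 = 1 for atypical) is flipped.
#' @param colony List from [colony_spec()].
#' @param afm List from [afm_spec()].
#' @param rtdc List from [rtdc_spec()].
#' @param qpcr List from [qpcr_spec()].
#' @param survival List from [survival_spec()].
#' @return An object of class `sim_config`.
#' @seealso [gen_cohort()], [gen_colony_images()], [gen_force_curves()],
#'   [gen_rtdc_events()], [gen_qpcr()], [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_patients = 55)
#' cfg
sim_config <- function(seed = 1L,
                       n_patients = 55L,
                       subtype_proportions = c(AT = 18, BA = 11, CL = 14, ME = 12) / 55,
                       marker_effect = 3,
                       noise_sd = 0.5,
                       flip_prob = 0.05,
                       colony = colony_spec(),
                       afm = afm_spec(),
                       rtdc = rtdc_spec(),
                       qpcr = qpcr_spec(),
                       survival = survival_spec()) {
  seed <- as.integer(seed)
  n_patients <- as.integer(n_patients)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  if (is.na(n_patients) || n_patients < 8L)
    stop("`n_patients` must be an integer >= 8", call. = FALSE)
  p <- subtype_proportions
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0))
    stop("`subtype_proportions` must be 4 finite non-negative values", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("`subtype_proportions` must sum to 1 (within 1e-9)", call. = FALSE)
  if (is.null(names(p))) names(p) <- c("AT", "BA", "CL", "ME")
  if (!setequal(names(p), c("AT", "BA", "CL", "ME")))
    stop("`subtype_proportions` must be named AT, BA, CL, ME", call. = FALSE)
  p <- p[c("AT", "BA", "CL", "ME")]
  for (nm in c("marker_effect", "noise_sd", "flip_prob")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (flip_prob < 0 || flip_prob > 1)
    stop("`flip_prob` must be in [0, 1]", call. = FALSE)

  structure(
    list(seed = seed, n_patients = n_patients, subtype_proportions = p,
         marker_effect = marker_effect, noise_sd = noise_sd,
         flip_prob = flip_prob, colony = colony, afm = afm, rtdc = rtdc,
         qpcr = qpcr, survival = survival),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic coculture study configuration\n")
  cat(sprintf("  seed: %d   patients: %d\n", x$seed, x$n_patients))
  cat(sprintf("  subtype mix: %s\n",
              paste(sprintf("%s %.3f", names(x$subtype_proportions),
                            x$subtype_proportions), collapse = ", ")))
  cat(sprintf("  marker effect: %+.2f sd, noise sd %.2f, flip prob %.2f\n",
              x$marker_effect, x$noise_sd, x$flip_prob))
  cat(sprintf("  colony: %d images %dx%d px | afm: %d curves, E %s Pa | rtdc: %d events (%.0f%% in gate)\n",
              x$colony$n_images, x$colony$height, x$colony$width,
              x$afm$n_curves, paste(x$afm$E_true, collapse = "/"),
              x$rtdc$n_events, 100 * x$rtdc$fraction_in_gate))
  invisible(x)
}

#' Colony-image generator settings
#'
#' Colonies are rendered as filled disks whose blue channel exceeds the
#' background by `contrast_margin`, emulating trypan-blue staining, so that
#' a single fixed segmentation threshold between the two levels separates
#' them exactly in the noiseless render.
#'
#' @param n_images Number of shifted plate images besides the reference.
#' @param width,height Image dimensions in pixels (at least 128).
#' @param n_colonies_lambda Poisson mean of the colony count per plate.
#' @param radius_range Min/max colony radius in pixels.
#' @param shift_max Maximum absolute planted integer shift (pixels) per axis.
#' @param background_blue Blue-channel level of the empty plate (0-255).
#' @param contrast_margin Blue-channel excess of colony pixels over the
#'   background (default 60 of 255).
#' @param pixel_noise_sd Gaussian pixel noise sd added per channel.
#' @return A list of settings consumed by [sim_config()].
#' @export
colony_spec <- function(n_images = 6L, width = 128L, height = 128L,
                        n_colonies_lambda = 8, radius_range = c(4, 10),
                        shift_max = 10L, background_blue = 100,
                        contrast_margin = 60, pixel_noise_sd = 5) {
  if (width < 128L || height < 128L)
    stop("colony images must be at least 128x128 px", call. = FALSE)
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    stop("`radius_range` must be an increasing positive pair", call. = FALSE)
  if (2 * max(radius_range) >= min(width, height))
    stop("colony radius larger than image", call. = FALSE)
  if (pixel_noise_sd < 0) stop("`pixel_noise_sd` must be >= 0", call. = FALSE)
  if (background_blue + contrast_margin > 255)
    stop("background_blue + contrast_margin must stay within 0-255", call. = FALSE)
  list(n_images = as.integer(n_images), width = as.integer(width),
       height = as.integer(height), n_colonies_lambda = n_colonies_lambda,
       radius_range = radius_range, shift_max = as.integer(shift_max),
       background_blue = background_blue, contrast_margin = contrast_margin,
       pixel_noise_sd = pixel_noise_sd)
}

#' AFM force-curve generator settings
#'
#' Approach segments emulate the study's acquisition settings (15 um ramp,
#' 1 nN setpoint, 30 um/s): heights descend linearly, the baseline region
#' (tip far from the cell) occupies the early part of the curve, and contact
#' points are drawn uniformly so at least one micron of indentation is
#' reached.
#'
#' @param E_true True Young's moduli in Pa, one per group/condition.
#' @param n_curves Curves generated per group.
#' @param curve_length Samples per approach segment (>= 50).
#' @param force_noise_nn Additive Gaussian force noise sd in nN.
#' @param f0_nn True force baseline offset in nN.
#' @param z_max_um Ramp start height above the surface in um.
#' @param z0_range_um Range the true contact point is drawn from (um).
#' @param geometry,half_angle_deg,poisson Indenter model defaults used both
#'   to synthesise and to refit curves; see [indenter_model()].
#' @param map_n Side length of a square force map (study default 64).
#' @param map_cell_radius Radius of the circular "cell" region of a map,
#'   as a fraction of the half-side.
#' @param E_substrate Substrate modulus in Pa for map pixels off the cell.
#' @return A list of settings consumed by [sim_config()].
#' @export
afm_spec <- function(E_true = 1000, n_curves = 200L, curve_length = 300L,
                     force_noise_nn = 0.02, f0_nn = 0.05, z_max_um = 5,
                     z0_range_um = c(1, 2), geometry = "four_sided_pyramid",
                     half_angle_deg = 35, poisson = 0.5, map_n = 64L,
                     map_cell_radius = 0.6, E_substrate = 1e5) {
  if (any(E_true <= 0)) stop("`E_true` must be positive", call. = FALSE)
  if (curve_length < 50L) stop("`curve_length` must be >= 50", call. = FALSE)
  if (force_noise_nn < 0) stop("`force_noise_nn` must be >= 0", call. = FALSE)
  if (z0_range_um[1] > z0_range_um[2] || z0_range_um[1] <= 0 ||
      z0_range_um[2] >= z_max_um)
    stop("`z0_range_um` must lie strictly inside (0, z_max_um)", call. = FALSE)
  list(E_true = E_true, n_curves = as.integer(n_curves),
       curve_length = as.integer(curve_length),
       force_noise_nn = force_noise_nn, f0_nn = f0_nn, z_max_um = z_max_um,
       z0_range_um = z0_range_um, geometry = geometry,
       half_angle_deg = half_angle_deg, poisson = poisson,
       map_n = as.integer(map_n), map_cell_radius = map_cell_radius,
       E_substrate = E_substrate)
}

#' RT-DC event generator settings
#'
#' In-gate events satisfy the study's filters (area 70-2000 um^2, porosity
#' 1.00-1.05); contaminants violate at least one bound, emulating debris
#' (small area), multicellular clusters (large area) or damaged cells
#' (high porosity).
#'
#' @param n_events Events per measurement.
#' @param fraction_in_gate Expected fraction of events passing both gates.
#' @param area_range_um2 Area range of in-gate events.
#' @param porosity_range Porosity range of in-gate events.
#' @param e_meanlog,e_sdlog Log-normal parameters of the planted Young's
#'   modulus column (kPa), as computed upstream by the acquisition software.
#' @return A list of settings consumed by [sim_config()].
#' @export
rtdc_spec <- function(n_events = 2000L, fraction_in_gate = 0.8,
                      area_range_um2 = c(70, 2000),
                      porosity_range = c(1.00, 1.05),
                      e_meanlog = log(1.2), e_sdlog = 0.3) {
  if (n_events < 1L) stop("`n_events` must be >= 1", call. = FALSE)
  if (fraction_in_gate < 0 || fraction_in_gate > 1)
    stop("`fraction_in_gate` must be in [0, 1]", call. = FALSE)
  list(n_events = as.integer(n_events), fraction_in_gate = fraction_in_gate,
       area_range_um2 = area_range_um2, porosity_range = porosity_range,
       e_meanlog = e_meanlog, e_sdlog = e_sdlog)
}

#' qPCR plate generator settings
#'
#' Target Ct values are built as
#' `Ct_target = Ct_ref + baseline_dct - true_log2fc + noise`, so the
#' comparative-Ct analysis recovers the planted log2 fold change in
#' expectation. The reference gene is PSMB2 in every sample, as in the
#' study's TaqMan panel.
#'
#' @param genes Target genes on the plate.
#' @param conditions Coculture conditions besides the control.
#' @param control Name of the non-cocultured control condition.
#' @param true_log2fc Matrix (genes x conditions) or single number of
#'   planted log2 fold changes vs control.
#' @param baseline_dct Per-gene baseline delta-Ct (target minus reference)
#'   in the control condition; recycled.
#' @param ct_ref_mean Mean reference-gene Ct.
#' @param ct_noise_sd Gaussian Ct noise sd (cycles).
#' @param n_replicates Biological replicates per condition.
#' @return A list of settings consumed by [sim_config()].
#' @export
qpcr_spec <- function(genes = c("MCT1", "MCT4", "CD147", "CAV1", "ACTA2"),
                      conditions = c("coculture"),
                      control = "none",
                      true_log2fc = 1.5,
                      baseline_dct = 5,
                      ct_ref_mean = 20,
                      ct_noise_sd = 0.2,
                      n_replicates = 3L) {
  if (control %in% conditions)
    stop("`control` must not appear in `conditions`", call. = FALSE)
  if (ct_noise_sd < 0) stop("`ct_noise_sd` must be >= 0", call. = FALSE)
  if (is.matrix(true_log2fc)) {
    if (nrow(true_log2fc) != length(genes) ||
        ncol(true_log2fc) != length(conditions))
      stop("`true_log2fc` matrix must be genes x conditions", call. = FALSE)
  } else {
    true_log2fc <- matrix(true_log2fc, nrow = length(genes),
                          ncol = length(conditions))
  }
  dimnames(true_log2fc) <- list(genes, conditions)
  list(genes = genes, conditions = conditions, control = control,
       true_log2fc = true_log2fc,
       baseline_dct = rep_len(baseline_dct, length(genes)),
       ct_ref_mean = ct_ref_mean, ct_noise_sd = ct_noise_sd,
       n_replicates = as.integer(n_replicates))
}

#' Survival and lactate-cluster generator settings
#'
#' Survival times are exponential with hazard scaled by the patient's
#' planted lactate-gene cluster; censoring is independent uniform on
#' `(0, censor_max)`, where `censor_max` is solved so the expected censoring
#' fraction matches `censor_rate` under the baseline hazard.
#'
#' @param baseline_hazard Event hazard per day for cluster 1.
#' @param cluster_hr Hazard ratio of cluster 2 vs cluster 1.
#' @param censor_rate Target expected fraction of censored records.
#' @param cluster2_prob Probability a patient is planted in cluster 2
#'   (study: 16 of 55).
#' @param cluster_sep z-scale upward shift of the five lactate-shuttle panel
#'   genes (MCT1, MCT4, CD147, CAV1, ACTA2) in cluster-2 patients.
#' @param cluster_noise_sd Noise sd of panel-gene expression.
#' @return A list of settings consumed by [sim_config()].
#' @export
survival_spec <- function(baseline_hazard = 1 / 1500, cluster_hr = 3,
                          censor_rate = 0.3, cluster2_prob = 16 / 55,
                          cluster_sep = 4, cluster_noise_sd = 1) {
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be > 0", call. = FALSE)
  if (cluster_hr <= 0) stop("`cluster_hr` must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("`censor_rate` must be in [0, 1)", call. = FALSE)
  list(baseline_hazard = baseline_hazard, cluster_hr = cluster_hr,
       censor_rate = censor_rate, cluster2_prob = cluster2_prob,
       cluster_sep = cluster_sep, cluster_noise_sd = cluster_noise_sd)
}

# Deterministic substream seed for one generator; kept below 2^31.
sim_seed <- function(config, stream) {
  offsets <- c(cohort = 101L, colony = 211L, afm = 307L, map = 401L,
               rtdc = 503L, qpcr = 601L)
  off <- offsets[[stream]]
  as.integer((as.numeric(config$seed) * 7919 + off) %% 2147483647)
}
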