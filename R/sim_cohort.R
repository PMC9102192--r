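#' Marker genes of the subtype classifier
#'
#' The six marker genes whose log2 expression, together with smoking and p16
#' status, drives the prototype mRNA-subtype rule.
#' @export
MARKER_GENES <- c("TP63", "EGFR", "SOX2", "VIM", "DES", "NFE2L2")

#' Lactate-shuttle gene panel
#'
#' The five genes whose tumour-tissue expression defines the two lactate
#' clusters: the monocarboxylate transporters MCT1/MCT4, their chaperone
#' CD147, plus CAV1 and ACTA2.
#' @export
LACTATE_PANEL <- c("MCT1", "MCT4", "CD147", "CAV1", "ACTA2")

#' Generate a synthetic patient cohort with planted subtypes and clusters
#'
#' Each patient is drawn from one of the four mRNA subtypes (AT, BA, CL,
#' ME): its signature markers are shifted by `+marker_effect` ("high") or
#' `-marker_effect` ("low") on the standardised scale, non-signature markers
#' are pure noise, smoking is forced to 1 for classical-planted and p16 to 1
#' for atypical-planted patients (flipped with probability `flip_prob`), and
#' background rates elsewhere follow the 55-patient cohort frequencies.
#' Patients also receive a planted lactate-gene cluster (1/2) driving both
#' the five-gene panel expression and an exponential survival hazard, with
#' independent uniform censoring.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   * `cohort`: data frame of one row per patient with marker-gene log2
#'     expression, `smoking`, `p16`, clinical factors (`gender`, `site`,
#'     `pN`, `stage`), lactate-panel expression, and `time`/`event`;
#'   * `truth`: data frame `id`, `subtype`, `cluster` (one record per
#'     patient).
#' @export
#' @examples
#' sim <- gen_cohort(sim_config(seed = 1, n_patients = 55))
#' table(sim$truth$subtype)
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "cohort"))

  n <- config$n_patients
  id <- sprintf("P%03d", seq_len(n))
  subtype <- sample(c("AT", "BA", "CL", "ME"), n, replace = TRUE,
                    prob = config$subtype_proportions)

  spec <- marker_spec()
  expr <- matrix(stats::rnorm(n * length(MARKER_GENES), 0, config$noise_sd),
                 nrow = n, dimnames = list(id, MARKER_GENES))
  for (cat in names(spec)) {
    sig <- spec[[cat]]
    sig <- sig[names(sig) %in% MARKER_GENES]
    rows <- subtype == cat
    for (g in names(sig))
      expr[rows, g] <- expr[rows, g] + sig[[g]] * config$marker_effect
  }

  flip <- function(x) ifelse(stats::runif(n) < config$flip_prob, 1L - x, x)
  # cohort background rates: 37/55 smokers, 20/55 p16-positive
  smoking <- ifelse(subtype == "CL", 1L, stats::rbinom(n, 1L, 37 / 55))
  smoking <- flip(smoking)
  p16 <- ifelse(subtype == "AT", 1L, stats::rbinom(n, 1L, 20 / 55))
  p16 <- flip(p16)

  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(14, 41) / 55)
  site <- sample(c("oropharynx", "larynx", "hypopharynx", "tongue",
                   "floor of the mouth", "oral cavity"),
                 n, replace = TRUE, prob = c(24, 16, 6, 5, 3, 1) / 55)
  pN <- sample(c("<2", ">2"), n, replace = TRUE, prob = c(37, 18) / 55)
  stage <- sample(c("I-II", "III-IV"), n, replace = TRUE, prob = c(28, 27) / 55)

  sv <- config$survival
  cluster <- 1L + stats::rbinom(n, 1L, sv$cluster2_prob)
  panel <- matrix(stats::rnorm(n * length(LACTATE_PANEL), 0, sv$cluster_noise_sd),
                  nrow = n, dimnames = list(id, LACTATE_PANEL))
  panel[cluster == 2L, ] <- panel[cluster == 2L, ] + sv$cluster_sep

  hazard <- sv$baseline_hazard * sv$cluster_hr^(cluster - 1L)
  t_event <- stats::rexp(n, rate = hazard)
  cmax <- censor_horizon(sv$baseline_hazard, sv$censor_rate)
  t_cens <- stats::runif(n, 0, cmax)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  cohort <- data.frame(id = id, expr, smoking = smoking, p16 = p16,
                       gender = gender, site = site, pN = pN, stage = stage,
                       panel, time = time, event = event,
                       stringsAsFactors = FALSE, check.names = FALSE)
  truth <- data.frame(id = id, subtype = subtype, cluster = cluster,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

# Censoring horizon u with C ~ U(0, u) giving the requested expected
# censoring fraction under the baseline exponential hazard:
# P(C < T) = (1 - exp(-lambda u)) / (lambda u).
censor_horizon <- function(lambda, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(u) (1 - exp(-lambda * u)) / (lambda * u) - censor_rate
  stats::uniroot(f, lower = 1e-6 / lambda, upper = 1e6 / lambda)$root
}

# Save/restore the global RNG state so generators behave as pure functions
# of their config and do not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
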