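#' Marker specification of the four mRNA subtypes
#'
#' The prototype rule's signed feature lists: basal (BA) is high TP63 and
#' EGFR with low SOX2; mesenchymal (ME) high VIM and DES with low TP63;
#' classical (CL) high SOX2 and NFE2L2 with positive smoking history;
#' atypical (AT) high SOX2 with p16 positivity. "High" is encoded as sign
#' +1 and "low" as sign -1 on the standardised scale.
#'
#' @param spec Optional named list of four named sign vectors overriding
#'   the default; names must be AT, BA, CL, ME and every feature must be a
#'   marker gene or one of the binary covariates `smoking`/`p16`.
#' @return A named list of four named numeric vectors (values +1/-1).
#' @export
#' @examples
#' marker_spec()
marker_spec <- function(spec = NULL) {
  if (is.null(spec)) {
    spec <- list(
      AT = c(SOX2 = 1, p16 = 1),
      BA = c(TP63 = 1, EGFR = 1, SOX2 = -1),
      CL = c(SOX2 = 1, NFE2L2 = 1, smoking = 1),
      ME = c(VIM = 1, DES = 1, TP63 = -1)
    )
  }
  if (!setequal(names(spec), c("AT", "BA", "CL", "ME")))
    stop("marker spec must define exactly AT, BA, CL, ME", call. = FALSE)
  allowed <- c(MARKER_GENES, "smoking", "p16")
  for (cat in names(spec)) {
    s <- spec[[cat]]
    if (is.null(names(s)) || !all(names(s) %in% allowed))
      stop("unknown feature in marker spec for ", cat,
           " (allowed: ", paste(allowed, collapse = ", "), ")",
           call. = FALSE)
    if (!all(s %in% c(-1, 1)))
      stop("marker signs must be +1 or -1", call. = FALSE)
  }
  spec[c("AT", "BA", "CL", "ME")]
}

#' Standardise cohort features to z-scores
#'
#' Each feature is centred on the cohort mean and scaled by the cohort
#' standard deviation (denominator n - 1). Binary covariates are
#' standardised identically to expression when included.
#'
#' @param cohort Data frame with one row per patient.
#' @param features Character vector of column names to standardise.
#' @return Numeric matrix (patients x features) of z-scores, with
#'   attributes `center` and `scale`.
#' @export
#' @examples
#' standardize_cohort(data.frame(TP63 = c(1, 3)), "TP63")
standardize_cohort <- function(cohort, features) {
  if (nrow(cohort) < 2L)
    stop("standardisation needs at least 2 patients", call. = FALSE)
  missing_cols <- setdiff(features, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort lacks feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(cohort[features])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    bad <- cohort$id[rowSums(is.na(x)) > 0]
    if (is.null(bad)) bad <- which(rowSums(is.na(x)) > 0)
    stop("missing feature values for record(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  s <- apply(x, 2, stats::sd)
  if (any(s == 0))
    stop("zero-variance feature(s): ",
         paste(features[s == 0], collapse = ", "), call. = FALSE)
  z <- scale(x, center = TRUE, scale = s)
  out <- z[, , drop = FALSE]
  attributes(out) <- list(dim = dim(z), dimnames = list(cohort$id, features),
                          center = attr(z, "scaled:center"),
                          scale = attr(z, "scaled:scale"))
  out
}

#' Score the four subtypes from standardised features
#'
#' The score of a category is the mean, over its signed features, of
#' `sign x z(feature)`.
#'
#' @param z Matrix of z-scores (patients x features) from
#'   [standardize_cohort()], or a single named numeric vector.
#' @param spec A [marker_spec()].
#' @return Matrix (patients x 4) of scores with columns AT, BA, CL, ME.
#' @export
#' @examples
#' z <- c(TP63 = 2, EGFR = 2, SOX2 = -2, VIM = 0, DES = 0, NFE2L2 = 0,
#'        smoking = 0, p16 = 0)
#' score_subtypes(z, marker_spec())
score_subtypes <- function(z, spec = marker_spec()) {
  spec <- marker_spec(spec)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  feats <- unique(unlist(lapply(spec, names)))
  missing_f <- setdiff(feats, colnames(z))
  if (length(missing_f) > 0L)
    stop("z lacks feature(s) named in the marker spec: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  scores <- vapply(spec, function(s) {
    rowMeans(sweep(z[, names(s), drop = FALSE], 2, s, `*`))
  }, numeric(nrow(z)))
  if (nrow(z) == 1L) scores <- matrix(scores, nrow = 1,
                                      dimnames = list(rownames(z),
                                                      names(spec)))
  scores
}

#' Assign the subtype with the highest score
#'
#' The label is the argmax of the four scores. When the top two scores
#' differ by less than `tol` the tie is resolved by the fixed priority
#' order AT > BA > CL > ME and flagged.
#'
#' @param scores Numeric vector of four named scores (AT, BA, CL, ME), or a
#'   matrix with those columns (one row per patient).
#' @param tol Tie tolerance (default 1e-12).
#' @return For a vector: list with `label`, `margin` (best minus
#'   second-best), `tied`, `scores`. For a matrix: data frame with those
#'   columns.
#' @export
#' @examples
#' assign_subtype(c(AT = -1, BA = 2, CL = -0.667, ME = -0.667))
assign_subtype <- function(scores, tol = 1e-12) {
  priority <- c("AT", "BA", "CL", "ME")
  one <- function(s) {
    s <- s[priority]
    if (any(!is.finite(s))) stop("non-finite subtype score", call. = FALSE)
    sorted <- sort(s, decreasing = TRUE)
    margin <- unname(sorted[1] - sorted[2])
    tied <- margin < tol
    # within-tolerance ties resolve to the first category in priority order
    best <- priority[which(s > sorted[1] - tol)[1]]
    list(label = best, margin = margin, tied = tied)
  }
  if (is.null(dim(scores))) {
    res <- one(scores)
    res$scores <- scores
    return(res)
  }
  rows <- lapply(seq_len(nrow(scores)), function(i) one(scores[i, ]))
  data.frame(label = vapply(rows, `[[`, character(1), "label"),
             margin = vapply(rows, `[[`, numeric(1), "margin"),
             tied = vapply(rows, `[[`, logical(1), "tied"))
}

#' Classify a cohort into mRNA subtypes
#'
#' End-to-end prototype classification: standardise the marker features over
#' the cohort, compute per-category mean signed z-scores, and attribute each
#' patient to the category with the highest mean.
#'
#' @param cohort Data frame with the six marker genes plus `smoking` and
#'   `p16` (0/1) columns; an `id` column is used for row names if present.
#' @param spec A [marker_spec()].
#' @param standardize_binary If TRUE (default) smoking and p16 are z-scored
#'   like expression; if FALSE they enter as raw 0/1 values. The default
#'   reads "standardised log2 expression/smoking/p16 status values" as
#'   standardising all three kinds of feature.
#' @return An object of class `subtype_classification`: data frame with
#'   `id`, `score_AT` .. `score_ME`, `label`, `margin`, `tied`.
#' @export
#' @examples
#' sim <- gen_cohort(sim_config(seed = 1))
#' cls <- classify_subtypes(sim$cohort)
#' table(cls$label, sim$truth$subtype)
classify_subtypes <- function(cohort, spec = marker_spec(),
                              standardize_binary = TRUE) {
  spec <- marker_spec(spec)
  feats <- unique(unlist(lapply(spec, names)))
  bin <- intersect(c("smoking", "p16"), feats)
  if (length(bin) > 0L && !all(unlist(cohort[bin]) %in% c(0, 1)))
    stop("smoking/p16 must be coded 0/1", call. = FALSE)
  if (standardize_binary) {
    z <- standardize_cohort(cohort, feats)
  } else {
    cont <- setdiff(feats, bin)
    z <- standardize_cohort(cohort, cont)
    z <- cbind(z, as.matrix(cohort[bin]))
  }
  scores <- score_subtypes(z, spec)
  asg <- assign_subtype(scores)
  out <- data.frame(
    id = if (!is.null(cohort$id)) cohort$id else seq_len(nrow(cohort)),
    score_AT = scores[, "AT"], score_BA = scores[, "BA"],
    score_CL = scores[, "CL"], score_ME = scores[, "ME"],
    label = asg$label, margin = asg$margin, tied = asg$tied,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("subtype_classification", "data.frame")
  out
}

#' @export
print.subtype_classification <- function(x, ...) {
  cat(sprintf("mRNA subtype classification of %d patients\n", nrow(x)))
  print(table(factor(x$label, levels = c("AT", "BA", "CL", "ME"))))
  if (any(x$tied)) cat(sprintf("  %d tie(s) resolved by priority AT > BA > CL > ME\n",
                               sum(x$tied)))
  invisible(x)
}

#' Cross-tabulate labels against a clinical factor
#'
#' Counts and row percentages in the presentation of the study's
#' clinico-pathological table: rows are factor levels, columns are labels,
#' and percentages are per row, rounded to one decimal.
#'
#' @param labels Character/factor vector of per-patient labels (subtype or
#'   cluster).
#' @param by Clinical factor vector, same length.
#' @return An object of class `caf_crosstab` with `counts` and `row_pct`
#'   matrices.
#' @export
#' @examples
#' crosstab(c("AT", "AT", "BA"), by = c("pos", "pos", "neg"))
crosstab <- function(labels, by) {
  if (length(labels) == 0L) stop("empty cohort", call. = FALSE)
  if (length(labels) != length(by))
    stop("`labels` and `by` must have equal length", call. = FALSE)
  counts <- table(factor(by), factor(labels))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  row_pct <- round(100 * counts / rowSums(counts), 1)
  structure(list(counts = counts, row_pct = row_pct),
            class = "caf_crosstab")
}

#' @export
print.caf_crosstab <- function(x, ...) {
  disp <- matrix(sprintf("%d (%.1f%%)", x$counts, x$row_pct),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(noquote(disp))
  invisible(x)
}
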