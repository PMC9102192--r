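#' Clinico-pathological cross-tabulations of the 55-patient cohort
#'
#' The in-study dataset: counts of the 55 HNSCC patients cross-tabulated by
#' clinical factor (gender, tumour location, p16 status, pN, stage,
#' smoking) against mRNA subtype (AT/BA/CL/ME) and against the two
#' lactate-shuttle gene expression clusters. Shipped as a plain-text
#' fixture in `extdata`.
#'
#' @return A list with two named lists of integer count matrices,
#'   `subtype` and `cluster`, one matrix per clinical factor (rows =
#'   factor levels).
#' @export
#' @examples
#' hn_cohort_tables()$subtype$pN
hn_cohort_tables <- function() {
  path <- system.file("extdata", "hnscc_cohort_crosstabs.csv",
                      package = "cafcoculture", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE)
  split_fac <- split(d, d$factor)
  mk <- function(block, cols) {
    m <- as.matrix(block[cols])
    storage.mode(m) <- "integer"
    rownames(m) <- block$level
    m
  }
  factors <- unique(d$factor)
  list(
    subtype = stats::setNames(
      lapply(factors, function(f) mk(split_fac[[f]], c("AT", "BA", "CL", "ME"))),
      factors),
    cluster = stats::setNames(
      lapply(factors, function(f) {
        m <- mk(split_fac[[f]], c("cluster1", "cluster2"))
        colnames(m) <- c("1", "2")
        m
      }),
      factors)
  )
}

#' Expand a cohort cross-tabulation to patient level
#'
#' Turns one count matrix of [hn_cohort_tables()] into a per-patient data frame
#' (one row per patient with the factor level and the label), the form
#' consumed by [crosstab()].
#'
#' @param counts Integer count matrix, rows = factor levels, columns =
#'   labels.
#' @return Data frame with columns `level` and `label`.
#' @export
#' @examples
#' long <- cohort_table_long(hn_cohort_tables()$subtype$p16)
#' crosstab(long$label, long$level)
cohort_table_long <- function(counts) {
  rows <- rep(rownames(counts), times = rowSums(counts))
  labs <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(colnames(counts), times = counts[i, ])))
  data.frame(level = rows, label = labs, stringsAsFactors = FALSE)
}
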