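#' One-sample t-test of log2 fold changes against zero
#'
#' Two-sided test on the log2 scale, the study's comparison of coculture
#' gene expression vs controls.
#'
#' @param x Numeric vector of log2 fold changes, n >= 2.
#' @param mu Null value (default 0 = no change).
#' @return List with `t`, `p`, `df`, `mean`, `n`.
#' @export
one_sample_test <- function(x, mu = 0) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in `x`", call. = FALSE)
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean = mean(x), n = length(x))
}

#' Paired t-test
#'
#' @param before,after Paired numeric vectors of equal length, n >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff`, `n`.
#' @export
paired_test <- function(before, after) {
  if (length(before) != length(after))
    stop("`before` and `after` must be paired (equal length)", call. = FALSE)
  if (length(before) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0) {
    # degenerate: constant within-pair difference
    zero <- all(d == 0)
    return(list(t = if (zero) 0 else sign(mean(d)) * Inf,
                p = if (zero) 1 else 0,
                df = length(d) - 1, mean_diff = mean(d), n = length(d)))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), n = length(d))
}

#' Pairwise Pearson correlation matrix with significance mask
#'
#' Pairwise-complete Pearson correlations between assay readouts (colony
#' fraction, expression, lactate, moduli, metabolic rates ...) with
#' two-sided p-values and a significance mask at p < 0.05, the asterisk
#' convention of the study's correlation heatmaps. Constant columns yield
#' `NA` correlations and are listed in `flags` rather than raising an
#' error.
#'
#' @param data Data frame of numeric measurement columns.
#' @param variables Columns to correlate (default all).
#' @param alpha Mask threshold (default 0.05).
#' @return An object of class `caf_cormat`: list with matrices `r`, `p`,
#'   `n`, logical `significant`, and `flags`.
#' @export
correlation_matrix <- function(data, variables = names(data), alpha = 0.05) {
  x <- data[variables]
  k <- length(variables)
  r <- p <- nmat <- matrix(NA_real_, k, k,
                           dimnames = list(variables, variables))
  diag(r) <- 1
  flags <- character(0)
  const <- vapply(variables, function(v) {
    xv <- x[[v]][is.finite(x[[v]])]
    length(unique(xv)) < 2L
  }, logical(1))
  if (any(const))
    flags <- paste0("constant column: ", variables[const])
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- is.finite(x[[i]]) & is.finite(x[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L || const[i] || const[j]) next
      ct <- stats::cor.test(x[[i]][ok], x[[j]][ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nmat,
                 significant = !is.na(p) & p < alpha, flags = flags),
            class = "caf_cormat")
}

#' @export
print.caf_cormat <- function(x, digits = 2, ...) {
  disp <- matrix(sprintf("%.*f%s", digits, x$r,
                         ifelse(!is.na(x$significant) & x$significant,
                                "*", "")),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  print(noquote(disp))
  if (length(x$flags) > 0) cat(paste(x$flags, collapse = "\n"), "\n")
  cat("* p <", format(0.05), "(two-sided)\n")
  invisible(x)
}

#' Two-cluster lactate-shuttle gene clustering
#'
#' Hierarchical clustering of samples on the five-gene lactate panel
#' (MCT1, MCT4, CD147, CAV1, ACTA2): per-gene z-scoring, Euclidean
#' distance, Ward linkage (`ward.D2`), tree cut at k = 2. Cluster 1 is
#' deterministically the cluster with the lower mean panel expression
#' (on the z scale), so labels are reproducible across sample orderings.
#'
#' @param mat Numeric matrix or data frame, samples x genes, containing at
#'   least the panel genes.
#' @param panel Gene panel used for clustering.
#' @return Integer vector of cluster labels (1/2) named by sample.
#' @export
#' @examples
#' sim <- gen_cohort(sim_config(seed = 1))
#' cl <- cluster_two(sim$cohort[LACTATE_PANEL])
#' table(cl, sim$truth$cluster)
cluster_two <- function(mat, panel = LACTATE_PANEL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 samples", call. = FALSE)
  missing_g <- setdiff(panel, colnames(mat))
  if (length(missing_g) > 0L)
    stop("expression matrix lacks panel gene(s): ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  x <- mat[, panel, drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite expression values", call. = FALSE)
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant gene carries no signal
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = 2)
  m1 <- mean(z[raw == 1, , drop = FALSE])
  m2 <- mean(z[raw == 2, , drop = FALSE])
  labels <- if (m1 <= m2) raw else 3L - raw
  stats::setNames(as.integer(labels), rownames(mat))
}
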