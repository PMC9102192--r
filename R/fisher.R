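#' Exact Fisher test for r x c contingency tables
#'
#' Exact conditional test on an r x c table of counts: all tables sharing
#' the observed row and column margins are enumerated recursively (cell by
#' cell, pruning margin-infeasible branches), each is assigned its
#' multivariate hypergeometric probability
#' `P = (prod r_i! prod c_j!) / (n! prod a_ij!)`, and the two-sided p-value
#' is the total probability of tables at most as probable as the observed
#' one (probability-mass criterion, with relative numerical slack 1e-7).
#' This is the convention of mainstream statistics environments; other
#' two-sided definitions exist.
#'
#' Exact enumeration is guarded at `total <= max_total`; beyond that a
#' seeded Monte-Carlo version is available via `method = "montecarlo"`,
#' which samples tables from the conditional null distribution
#' (Patefield's algorithm, [stats::r2dtable()]).
#'
#' @param table Matrix of non-negative integer counts (r x c), total > 0.
#' @param method `"exact"` (default) or `"montecarlo"`.
#' @param max_total Enumeration guard on the table total (default 500).
#' @param mc_reps Monte-Carlo replicates (default 1e6).
#' @param mc_seed Seed for the Monte-Carlo fallback.
#' @return An object of class `fisher_exact_test`: list with `p_value`,
#'   `method`, `n` (table total).
#' @export
#' @examples
#' pn_subtype <- matrix(c(12, 9, 12, 4, 6, 2, 2, 8), nrow = 2, byrow = TRUE)
#' fisher_exact(pn_subtype)  # p = 0.03059
fisher_exact <- function(table, method = c("exact", "montecarlo"),
                         max_total = 500L, mc_reps = 1e6, mc_seed = 1L) {
  method <- match.arg(method)
  a <- as.matrix(table)
  if (any(a < 0) || any(a != round(a)) || any(!is.finite(a)))
    stop("`table` must contain non-negative integer counts", call. = FALSE)
  n <- sum(a)
  if (n == 0) stop("`table` total must be positive", call. = FALSE)
  # drop all-zero margins: they carry no information and inflate recursion
  a <- a[rowSums(a) > 0, colSums(a) > 0, drop = FALSE]
  if (nrow(a) < 2L || ncol(a) < 2L)
    return(structure(list(p_value = 1, method = method, n = n),
                     class = "fisher_exact_test"))
  if (method == "exact") {
    if (n > max_total)
      stop("table total ", n, " exceeds the exact enumeration guard (",
           max_total, "); use method = \"montecarlo\" (seeded, ",
           format(mc_reps, scientific = FALSE), " permutations)",
           call. = FALSE)
    p <- fisher_enumerate(a)
  } else {
    p <- fisher_montecarlo(a, reps = mc_reps, seed = mc_seed)
  }
  structure(list(p_value = p, method = method, n = n),
            class = "fisher_exact_test")
}

#' @export
print.fisher_exact_test <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s): two-sided p = %.6g  (n = %d)\n",
              x$method, x$p_value, x$n))
  invisible(x)
}

# log probability of a table under fixed margins
fisher_logp <- function(a, lr, lc, ln) {
  lr + lc - ln - sum(lgamma(a + 1))
}

fisher_enumerate <- function(a) {
  rs <- rowSums(a); cs <- colSums(a); n <- sum(a)
  lr <- sum(lgamma(rs + 1)); lc <- sum(lgamma(cs + 1)); ln <- lgamma(n + 1)
  const <- lr + lc - ln
  logp_obs <- const - sum(lgamma(a + 1))
  cutoff <- logp_obs + log(1 + 1e-7)
  r <- nrow(a); c <- ncol(a)

  psum <- 0
  # fill the table cell by cell in row-major order; the last column of each
  # row and the whole last row are forced by the margins
  cell <- matrix(0L, r, c)
  recurse <- function(i, j, row_rem, col_rem, lg_acc) {
    # lg_acc = sum lgamma(a+1) over cells already fixed
    if (i == r) {
      # last row forced by column remainders
      lg <- lg_acc + sum(lgamma(col_rem + 1))
      logp <- const - lg
      if (logp <= cutoff) psum <<- psum + exp(logp)
      return(invisible(NULL))
    }
    if (j == c) {
      # last cell of the row forced by the row remainder
      v <- row_rem
      if (v > col_rem[c]) return(invisible(NULL))
      cr <- col_rem; cr[c] <- cr[c] - v
      recurse(i + 1L, 1L, rs[i + 1L], cr, lg_acc + lgamma(v + 1))
      return(invisible(NULL))
    }
    rest <- sum(col_rem[(j + 1L):c])
    lo <- max(0L, row_rem - rest)
    hi <- min(row_rem, col_rem[j])
    if (lo > hi) return(invisible(NULL))
    for (v in lo:hi) {
      cr <- col_rem; cr[j] <- cr[j] - v
      recurse(i, j + 1L, row_rem - v, cr, lg_acc + lgamma(v + 1))
    }
    invisible(NULL)
  }
  recurse(1L, 1L, rs[1L], cs, 0)
  min(1, psum)
}

fisher_montecarlo <- function(a, reps, seed) {
  rs <- rowSums(a); cs <- colSums(a); n <- sum(a)
  lr <- sum(lgamma(rs + 1)); lc <- sum(lgamma(cs + 1)); ln <- lgamma(n + 1)
  logp_obs <- fisher_logp(a, lr, lc, ln)
  cutoff <- logp_obs + log(1 + 1e-7)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  hits <- 0
  block <- 10000L
  done <- 0
  while (done < reps) {
    b <- min(block, reps - done)
    tabs <- stats::r2dtable(b, rs, cs)
    lp <- vapply(tabs, function(t) fisher_logp(t, lr, lc, ln), numeric(1))
    hits <- hits + sum(lp <= cutoff)
    done <- done + b
  }
  (hits + 1) / (reps + 1)
}
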