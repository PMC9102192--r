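#' Generate a synthetic qPCR plate with planted fold changes
#'
#' Builds Ct records for each gene x condition x replicate with PSMB2 as
#' the reference gene in every sample:
#' `Ct_target = Ct_ref + baseline_dct - true_log2fc + noise`
#' (with `true_log2fc = 0` in the control condition), so the
#' comparative-Ct analysis recovers the planted log2 fold change in
#' expectation.
#'
#' @param config A [sim_config()] object; settings under `config$qpcr`.
#' @return A list with
#'   * `records`: data frame `sample`, `condition`, `gene`, `ct_target`,
#'     `ct_ref`, `ref_gene`;
#'   * `truth`: data frame `gene`, `condition`, `log2fc`.
#' @export
gen_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  qs <- config$qpcr
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "qpcr"))

  conds <- c(qs$control, qs$conditions)
  grid <- expand.grid(rep = seq_len(qs$n_replicates), gene = qs$genes,
                      condition = conds, stringsAsFactors = FALSE)
  n <- nrow(grid)
  base_dct <- stats::setNames(qs$baseline_dct, qs$genes)
  fc <- numeric(n)
  is_cc <- grid$condition != qs$control
  fc[is_cc] <- qs$true_log2fc[cbind(grid$gene[is_cc], grid$condition[is_cc])]
  ct_ref <- stats::rnorm(n, qs$ct_ref_mean, 0.1)
  ct_target <- ct_ref + base_dct[grid$gene] - fc +
    stats::rnorm(n, 0, qs$ct_noise_sd)
  records <- data.frame(
    sample = sprintf("%s_r%d", grid$condition, grid$rep),
    condition = grid$condition,
    gene = grid$gene,
    ct_target = ct_target,
    ct_ref = ct_ref,
    ref_gene = "PSMB2",
    stringsAsFactors = FALSE
  )
  truth <- expand.grid(gene = qs$genes, condition = qs$conditions,
                       stringsAsFactors = FALSE)
  truth$log2fc <- qs$true_log2fc[cbind(truth$gene, truth$condition)]
  list(records = records, truth = truth)
}

#' Comparative-Ct (delta-delta-Ct) relative quantification
#'
#' For each record, `dCt = Ct_target - Ct_ref` (PSMB2 reference); per gene,
#' `ddCt = dCt - mean(dCt of the control condition)`; the log2 fold change
#' is `-ddCt` and the fold change `2^(-ddCt)`.
#'
#' @param records Data frame with columns `sample`, `condition`, `gene`,
#'   `ct_target`, `ct_ref`.
#' @param control Name of the control condition; every gene must have at
#'   least one control record.
#' @return Data frame with `sample`, `condition`, `gene`, `dct`, `ddct`,
#'   `log2fc`, `fold_change` (control rows included, centred on the control
#'   mean).
#' @export
#' @examples
#' rec <- data.frame(sample = c("ctl", "cc"), condition = c("none", "co"),
#'                   gene = "MCT4", ct_target = c(25, 23), ct_ref = 20)
#' ddct(rec, control = "none")
ddct <- function(records, control = "none") {
  need <- c("sample", "condition", "gene", "ct_target", "ct_ref")
  if (!all(need %in% names(records)))
    stop("`records` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  records$dct <- records$ct_target - records$ct_ref
  genes <- unique(records$gene)
  ctl <- records[records$condition == control, ]
  missing_ctl <- setdiff(genes, unique(ctl$gene))
  if (length(missing_ctl) > 0L)
    stop("no control condition records for gene(s): ",
         paste(missing_ctl, collapse = ", "), call. = FALSE)
  ctl_mean <- tapply(ctl$dct, ctl$gene, mean)
  records$ddct <- records$dct - as.numeric(ctl_mean[records$gene])
  records$log2fc <- -records$ddct
  records$fold_change <- 2^(-records$ddct)
  rownames(records) <- NULL
  records
}
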