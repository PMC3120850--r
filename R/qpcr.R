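#' Relative quantification by the 2^-ddCt method
#'
#' For each condition the target Ct is normalized to the reference gene
#' (dCt = mean over replicates of Ct_target - Ct_reference); the fold
#' change is `2^-(dCt_treated - dCt_control)`.
#'
#' @param treated,control data.frames with numeric columns `ct_target`
#'   and `ct_reference`, one row per replicate (>= 1 each).
#' @return the fold change (treated relative to control).
#' @examples
#' trt <- data.frame(ct_target = c(24.1, 23.9), ct_reference = c(12, 12))
#' ctl <- data.frame(ct_target = c(25.0, 25.0), ct_reference = c(12, 12))
#' ddct_fold_change(trt, ctl)  # ~2-fold induction
#' @export
ddct_fold_change <- function(treated, control) {
  for (d in list(treated, control)) {
    if (!all(c("ct_target", "ct_reference") %in% names(d))) {
      stop("need ct_target and ct_reference columns")
    }
    if (nrow(d) < 1) stop("need at least one replicate per condition")
    if (anyNA(d$ct_reference) || anyNA(d$ct_target)) {
      stop("missing Ct value")
    }
  }
  dct_t <- mean(treated$ct_target - treated$ct_reference)
  dct_c <- mean(control$ct_target - control$ct_reference)
  2^-(dct_t - dct_c)
}

#' Fold changes for every gene of a Ct table
#'
#' @param ct data.frame as from [read_ct_table()]: `gene_id`, `condition`
#'   (treated/control), `replicate`, `ct_target`, `ct_reference`.
#' @return data.frame with `gene_id`, `fold_change`, `log2_ratio`.
#' @export
qpcr_fold_changes <- function(ct) {
  genes <- unique(ct$gene_id)
  fc <- vapply(genes, function(g) {
    ddct_fold_change(ct[ct$gene_id == g & ct$condition == "treated", ],
                     ct[ct$gene_id == g & ct$condition == "control", ])
  }, numeric(1))
  data.frame(gene_id = genes, fold_change = unname(fc),
             log2_ratio = log2(unname(fc)), stringsAsFactors = FALSE)
}

#' Concordance between qPCR and array log2 ratios
#'
#' Pearson correlation and the determination coefficient (R^2) of the
#' least-squares fit of array on qPCR log2 ratios, over the genes named in
#' both vectors.
#'
#' @param qpcr_log2,array_log2 named numeric vectors of per-gene log2
#'   ratios; >= 3 shared genes required.
#' @return list with `r`, `r_squared`, `slope`, `intercept`, `n`.
#' @export
platform_concordance <- function(qpcr_log2, array_log2) {
  shared <- intersect(names(qpcr_log2), names(array_log2))
  if (length(shared) < 3) stop("need >= 3 shared genes")
  x <- qpcr_log2[shared]
  y <- array_log2[shared]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance on one platform")
  }
  fit <- stats::lm(y ~ x)
  list(r = unname(stats::cor(x, y)),
       r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(shared))
}
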