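#' Classify genes of one organ at a fold-change threshold
#'
#' Labels every gene `up`, `down` or `unchanged` from its log2 ratio at a
#' fold threshold. The boundary is inclusive: a gene whose ratio is exactly
#' the threshold fold counts as changed, i.e. `up` iff
#' `log2_ratio >= log2(threshold)` and `down` iff
#' `log2_ratio <= -log2(threshold)`.
#'
#' @param x an [expression_table()].
#' @param threshold fold-change threshold (>= 1); default 2, the
#'   two-fold cutoff used throughout the study design this package targets.
#' @return object of class `organ_class`: list with `organ`, `threshold`,
#'   `status` (named factor over up/down/unchanged), `log2_ratio` (named),
#'   `counts` (named integer `up`, `down`, `unchanged`) and `total`.
#' @examples
#' tab <- expression_table(c("a", "b", "c"), c(1, -1, 0.5), "liver")
#' classify(tab)
#' @export
classify <- function(x, threshold = 2) {
  stopifnot(inherits(x, "expression_table"))
  if (nrow(x) == 0) stop("empty expression table")
  if (!is.finite(threshold) || threshold < 1) stop("threshold must be >= 1")
  cut <- log2(threshold)
  status <- ifelse(x$log2_ratio >= cut, "up",
                   ifelse(x$log2_ratio <= -cut, "down", "unchanged"))
  status <- factor(status, levels = c("up", "down", "unchanged"))
  names(status) <- x$gene_id
  lr <- x$log2_ratio
  names(lr) <- x$gene_id
  counts <- table(status)
  out <- list(organ = attr(x, "organ"), threshold = threshold,
              status = status, log2_ratio = lr,
              counts = c(up = unname(counts["up"]), down = unname(counts["down"]),
                         unchanged = unname(counts["unchanged"])),
              total = length(status))
  out$counts <- vapply(out$counts, as.integer, integer(1))
  class(out) <- "organ_class"
  out
}

#' Build an organ classification from category counts only
#'
#' Some downstream statistics (expected concordance counts, genome-
#' background deviation tests) need only the per-category totals, e.g. the
#' counts printed in a publication table. This constructor makes an
#' `organ_class` carrying counts without per-gene labels.
#'
#' @param up,down,unchanged category counts.
#' @param organ organ label.
#' @param threshold fold threshold the counts were taken at.
#' @export
organ_class_counts <- function(up, down, unchanged, organ = "organ",
                               threshold = 2) {
  out <- list(organ = organ, threshold = threshold,
              status = NULL, log2_ratio = NULL,
              counts = c(up = as.integer(up), down = as.integer(down),
                         unchanged = as.integer(unchanged)),
              total = as.integer(up + down + unchanged))
  class(out) <- "organ_class"
  out
}

#' @export
print.organ_class <- function(x, ...) {
  cat(sprintf("Organ classification: %s (threshold %g-fold)\n", x$organ,
              x$threshold))
  cat(sprintf("  up %d | down %d | unchanged %d | total %d (%.1f%% modified)\n",
              x$counts["up"], x$counts["down"], x$counts["unchanged"],
              x$total, modified_fraction(x)))
  invisible(x)
}

#' @export
summary.organ_class <- function(object, ...) {
  bias <- directional_bias_test(object)
  cat(sprintf("Organ: %s  threshold: %g-fold\n", object$organ, object$threshold))
  cat(sprintf("  modified fraction: %.2f%%\n", modified_fraction(object)))
  cat(sprintf("  directional bias: excess %s (chi2 = %.3g, p = %.3g)\n",
              bias$direction, bias$statistic, bias$p_value))
  invisible(object)
}

#' Percentage of genes modified beyond the threshold
#'
#' @param cls an `organ_class`.
#' @return `100 * (n_up + n_down) / total`.
#' @examples
#' organ_class_counts(3642, 4418, 15396, "lung") |> modified_fraction()
#' @export
modified_fraction <- function(cls) {
  stopifnot(inherits(cls, "organ_class"), cls$total > 0)
  100 * (cls$counts[["up"]] + cls$counts[["down"]]) / cls$total
}

#' Test for directional bias among changed genes
#'
#' Two-sided test of the null that, among genes changed beyond the
#' threshold, up- and down-regulation are equally likely. `chi2` is the
#' Pearson 1-df goodness-of-fit test on (n_up, n_down) against (1/2, 1/2)
#' without continuity correction; `exact_binomial` is the exact two-sided
#' binomial test. When no gene is changed the result is flagged undefined
#' and p = 1 by convention.
#'
#' @param cls an `organ_class`.
#' @param method `"chi2"` (default) or `"exact_binomial"`.
#' @return list with `statistic` (chi2, or NA for the exact test),
#'   `p_value`, `direction` (`"up"`, `"down"` or `"none"`), `method`,
#'   `defined` (FALSE when n_up + n_down = 0).
#' @export
directional_bias_test <- function(cls, method = c("chi2", "exact_binomial")) {
  method <- match.arg(method)
  stopifnot(inherits(cls, "organ_class"))
  n_up <- cls$counts[["up"]]
  n_down <- cls$counts[["down"]]
  n <- n_up + n_down
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = 1, direction = "none",
                method = method, defined = FALSE))
  }
  direction <- if (n_up > n_down) "up" else if (n_down > n_up) "down" else "none"
  if (method == "chi2") {
    ct <- stats::chisq.test(c(n_up, n_down), p = c(0.5, 0.5), correct = FALSE)
    stat <- unname(ct$statistic)
    p <- ct$p.value
  } else {
    stat <- NA_real_
    p <- stats::binom.test(n_up, n, 0.5)$p.value
  }
  list(statistic = stat, p_value = p, direction = direction,
       method = method, defined = TRUE)
}

#' Write a classification as TSV (gene_id, log2_ratio, status)
#' @param cls an `organ_class` carrying per-gene labels.
#' @param path output path.
#' @export
write_classification <- function(cls, path) {
  if (is.null(cls$status)) stop("classification carries counts only")
  write_tsv(data.frame(gene_id = names(cls$status),
                       log2_ratio = unname(cls$log2_ratio),
                       status = as.character(cls$status)), path)
}
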