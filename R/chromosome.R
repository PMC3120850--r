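#' Per-chromosome deregulation bias
#'
#' For each chromosome, tests whether its up/down/unchanged composition
#' deviates from the class proportions of all annotated genes (Pearson
#' goodness-of-fit chi-squared, df 2, or down-vs-rest with df 1 in
#' `two_class` mode). The multiple-testing column follows the uncapped
#' Bonferroni-product convention -- raw p times the number of chromosomes
#' actually tested, so values above 1 occur -- with a conventional capped
#' column alongside. Genes missing from the annotation are excluded with a
#' logged count; chromosomes with fewer than `min_genes` annotated genes
#' are skipped with a warning.
#'
#' @param cls an `organ_class` with per-gene labels.
#' @param ann a `gene_annotation`.
#' @param mode `"three_class"` or `"two_class"`.
#' @param min_genes minimum annotated genes for a chromosome to be tested.
#' @param alpha significance level applied to the capped Bonferroni value.
#' @return data.frame of class `chromosome_bias`: one row per tested
#'   chromosome with observed counts, expected counts, chi2, raw p,
#'   `bonferroni` (uncapped product), `bonferroni_capped`, `significant`;
#'   attributes `n_tests`, `n_unannotated`, `organ`.
#' @export
per_chromosome_bias <- function(cls, ann, mode = c("three_class", "two_class"),
                                min_genes = 5, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(cls, "organ_class"), inherits(ann, "gene_annotation"))
  if (is.null(cls$status)) stop("classification carries counts only")
  shared <- intersect(names(cls$status), ann$gene_id)
  n_unannotated <- length(cls$status) - length(shared)
  if (n_unannotated > 0) {
    message(cls$organ, ": ", n_unannotated,
            " gene(s) absent from annotation excluded from chromosome scan")
  }
  status <- cls$status[shared]
  chrom <- ann$chromosome[match(shared, ann$gene_id)]
  genome <- table(status)[c("up", "down", "unchanged")]
  if (mode == "two_class") {
    genome <- c(down = unname(genome["down"]),
                rest = unname(genome["up"] + genome["unchanged"]))
  }
  props <- as.numeric(genome) / sum(genome)
  tab <- table(chrom, status)
  chroms <- rownames(tab)
  sizes <- rowSums(tab)
  small <- sizes < min_genes
  if (any(small)) {
    warning("skipped chromosome(s) with < ", min_genes, " genes: ",
            paste(chroms[small], collapse = ", "))
  }
  chroms <- chroms[!small]
  rows <- lapply(chroms, function(ch) {
    o3 <- as.integer(tab[ch, c("up", "down", "unchanged")])
    o <- if (mode == "two_class") c(o3[2], o3[1] + o3[3]) else o3
    e <- sum(o) * props
    keep <- e > 0
    chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
    p <- stats::pchisq(chi2, df = length(o) - 1L, lower.tail = FALSE)
    data.frame(chromosome = ch, n_genes = sum(o3), n_up = o3[1], n_down = o3[2],
               n_unchanged = o3[3], chi2 = chi2, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_tests <- nrow(out)
  out$bonferroni <- out$p_raw * n_tests
  out$bonferroni_capped <- pmin(out$bonferroni, 1)
  out$significant <- out$bonferroni_capped < alpha
  attr(out, "n_tests") <- n_tests
  attr(out, "n_unannotated") <- n_unannotated
  attr(out, "organ") <- cls$organ
  attr(out, "mode") <- mode
  class(out) <- c("chromosome_bias", "data.frame")
  out
}

#' Sliding-window deregulation profile along chromosomes
#'
#' Orders genes by (chromosome, start) and computes the mean log2 ratio
#' over every run of `k` consecutive genes (step 1 gene). Windows never
#' span chromosomes; a chromosome with fewer than `k` annotated genes
#' yields no windows and is logged. Window order is positional, not
#' base-pair: this is the "k consecutive genes" smoothing used for
#' chromosome deregulation-cluster plots.
#'
#' @param table an [expression_table()].
#' @param ann a `gene_annotation`.
#' @param k window size in genes (>= 1); default 10.
#' @return data.frame of class `chromosome_profile`: one row per window
#'   with `chromosome`, `first_gene`, `last_gene`, `span_start`,
#'   `span_end` (bp, 0-based half-open union of member genes), `mean`
#'   (arithmetic mean of the k member log2 ratios); attributes `k`,
#'   `organ`.
#' @export
window_profile <- function(table, ann, k = 10) {
  stopifnot(inherits(table, "expression_table"),
            inherits(ann, "gene_annotation"))
  if (k < 1) stop("k must be >= 1")
  idx <- match(table$gene_id, ann$gene_id)
  keep <- !is.na(idx)
  if (any(!keep)) {
    message(sum(!keep), " gene(s) absent from annotation excluded from profile")
  }
  g <- data.frame(gene_id = table$gene_id[keep],
                  log2_ratio = table$log2_ratio[keep],
                  chromosome = ann$chromosome[idx[keep]],
                  start = ann$start[idx[keep]], end = ann$end[idx[keep]],
                  stringsAsFactors = FALSE)
  g <- g[order(g$chromosome, g$start, g$gene_id), ]
  out <- lapply(split(g, g$chromosome), function(gc) {
    n <- nrow(gc)
    if (n < k) {
      message("chromosome ", gc$chromosome[1], ": ", n,
              " gene(s) < window size ", k, ", no windows")
      return(NULL)
    }
    nw <- n - k + 1L
    cs <- cumsum(c(0, gc$log2_ratio))
    means <- (cs[(k + 1):(n + 1)] - cs[1:nw]) / k
    i <- seq_len(nw)
    data.frame(chromosome = gc$chromosome[1],
               first_gene = gc$gene_id[i], last_gene = gc$gene_id[i + k - 1L],
               span_start = gc$start[i],
               span_end = vapply(i, function(j) max(gc$end[j:(j + k - 1L)]),
                                 numeric(1)),
               mean = means, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(), first_gene = character(),
                      last_gene = character(), span_start = numeric(),
                      span_end = numeric(), mean = numeric())
  }
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "organ") <- attr(table, "organ")
  class(out) <- c("chromosome_profile", "data.frame")
  out
}

#' Call deregulated regions from a window profile
#'
#' A region is a maximal run of at least `min_windows` consecutive windows
#' (on one chromosome) whose mean log2 ratios all satisfy
#' `|mean| >= threshold` with a consistent sign. Region bounds are the
#' union of the member windows' genomic spans.
#'
#' @param profile a `chromosome_profile`.
#' @param threshold minimum absolute window mean (> 0).
#' @param min_windows minimum run length in windows; default 3.
#' @return data.frame of class `deg_regions`: `chromosome`, `start`,
#'   `end` (bp), `direction` (`up`/`down`), `n_windows`, `mean` (mean of
#'   member window means); attributes `threshold`, `min_windows`.
#' @export
call_regions <- function(profile, threshold, min_windows = 3) {
  stopifnot(inherits(profile, "chromosome_profile"), threshold > 0)
  regions <- lapply(split(seq_len(nrow(profile)), profile$chromosome),
                    function(ix) {
    m <- profile$mean[ix]
    state <- ifelse(m >= threshold, 1L, ifelse(m <= -threshold, -1L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    qual <- which(r$values != 0L & r$lengths >= min_windows)
    if (!length(qual)) return(NULL)
    do.call(rbind, lapply(qual, function(q) {
      w <- ix[starts[q]:ends[q]]
      data.frame(chromosome = profile$chromosome[w[1]],
                 start = min(profile$span_start[w]),
                 end = max(profile$span_end[w]),
                 direction = if (r$values[q] > 0) "up" else "down",
                 n_windows = length(w), mean = mean(profile$mean[w]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, regions)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_windows = integer(), mean = numeric())
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "min_windows") <- min_windows
  class(out) <- c("deg_regions", "data.frame")
  out
}

#' Write called regions as BED
#' @param regions a `deg_regions` data.frame.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bed <- data.frame(regions$chromosome, format(regions$start, scientific = FALSE, trim = TRUE),
                    format(regions$end, scientific = FALSE, trim = TRUE),
                    paste0(regions$direction, "_", seq_len(nrow(regions))),
                    round(1000 * pmin(abs(regions$mean), 1)),
                    ifelse(regions$direction == "up", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
plot.chromosome_profile <- function(x, chromosome = NULL, ...) {
  if (!is.null(chromosome)) x <- x[x$chromosome == chromosome, ]
  pos <- (x$span_start + x$span_end) / 2 / 1e6
  graphics::plot(pos, x$mean, type = "l",
                 xlab = "position (Mb)", ylab = "mean log2 ratio", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
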