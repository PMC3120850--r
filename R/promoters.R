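#' Select the most induced and most repressed genes
#'
#' @param table an [expression_table()] with at least `2 * n` genes.
#' @param n genes per extreme; default 20.
#' @return list with `induced` (top n by descending log2 ratio) and
#'   `repressed` (top n ascending); ties at the cut are broken by
#'   lexicographic gene id.
#' @export
select_extremes <- function(table, n = 20) {
  stopifnot(inherits(table, "expression_table"))
  if (n == 0) return(list(induced = character(), repressed = character()))
  if (nrow(table) < 2 * n) stop("fewer than 2n genes")
  ind <- table$gene_id[order(-table$log2_ratio, table$gene_id)][seq_len(n)]
  rep_ <- table$gene_id[order(table$log2_ratio, table$gene_id)][seq_len(n)]
  list(induced = ind, repressed = rep_)
}

# Log-odds score matrix from a count (or probability) PWM:
# columns normalized with a pseudocount, scored against a uniform
# background; an extra 'N' row carries the column's expected
# background score so ambiguous bases are background-neutral.
pwm_logodds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(nrow(pwm) == 4)
  probs <- sweep(pwm + pseudocount / 4, 2, colSums(pwm) + pseudocount, "/")
  lo <- log2(probs / background)
  rbind(lo, N = colSums(lo * background))
}

#' Count PWM matches in a promoter sequence
#'
#' Scans both strands of a sequence with a position weight matrix and
#' counts the start positions whose log-odds score reaches
#' `score_threshold` times the maximum attainable score. Column
#' probabilities are formed from the count matrix with a pseudocount and
#' scored against a uniform background; `N` bases score as background.
#' The reverse strand is scanned by scoring the forward sequence with the
#' reverse-complemented matrix, so palindromic hits count once per strand.
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param pwm 4 x L count matrix (rows A, C, G, T), as from
#'   [read_jaspar()].
#' @param score_threshold fraction of the maximum score in (0, 1];
#'   default 0.85.
#' @param background base frequencies; default uniform 0.25.
#' @param pseudocount total pseudocount per column; default 0.8.
#' @return integer site count (0 when the sequence is shorter than the
#'   matrix).
#' @export
scan_promoter <- function(seq, pwm, score_threshold = 0.85,
                          background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(is.character(seq), length(seq) == 1)
  lo <- pwm_logodds(pwm, background, pseudocount)
  L <- ncol(lo)
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T", "N"))
  if (anyNA(code)) stop("sequence contains characters outside A/C/G/T/N")
  n <- length(code)
  if (n < L) return(0L)
  cutoff <- score_threshold * sum(apply(lo[1:4, , drop = FALSE], 2, max))
  lo_rc <- lo[c(4:1, 5), L:1, drop = FALSE]  # reverse complement strand
  nw <- n - L + 1L
  count <- 0L
  for (m in list(lo, lo_rc)) {
    scores <- numeric(nw)
    for (j in seq_len(L)) {
      scores <- scores + m[cbind(code[j:(j + nw - 1L)], j)]
    }
    count <- count + sum(scores >= cutoff)
  }
  as.integer(count)
}

#' Build a per-promoter site-count table by scanning sequences
#'
#' @param seqs named character vector of promoter sequences; names are
#'   promoter ids.
#' @param pwms named list of PWMs (see [read_jaspar()]).
#' @param promoter_genes named character vector mapping promoter id to
#'   gene id (every promoter maps to exactly one gene).
#' @inheritParams scan_promoter
#' @return data.frame with `promoter_id`, `gene_id` and one count column
#'   per matrix family.
#' @export
count_sites <- function(seqs, pwms, promoter_genes, score_threshold = 0.85,
                        background = rep(0.25, 4), pseudocount = 0.8) {
  if (!all(names(seqs) %in% names(promoter_genes))) {
    stop("every promoter needs a gene mapping")
  }
  counts <- vapply(pwms, function(p) {
    vapply(seqs, scan_promoter, integer(1), pwm = p,
           score_threshold = score_threshold, background = background,
           pseudocount = pseudocount)
  }, integer(length(seqs)))
  out <- data.frame(promoter_id = names(seqs),
                    gene_id = unname(promoter_genes[names(seqs)]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts))
}

#' Compare site counts between induced and repressed genes
#'
#' Two-sample two-sided Student t test per matrix family on per-promoter
#' site counts, induced vs repressed; every promoter of a selected gene is
#' one observation. Bonferroni correction is over the number of families
#' tested. Families with zero variance in both groups are flagged and
#' given p = 1.
#'
#' @param counts site-count data.frame (`promoter_id`, `gene_id`, one
#'   column per family), e.g. from [count_sites()] or read from TSV.
#' @param induced,repressed character vectors of gene ids.
#' @param var_equal pooled-variance Student t (default TRUE); FALSE gives
#'   Welch.
#' @return data.frame of class `occurrence_test`: one row per family with
#'   `family`, `mean_induced`, `mean_repressed`, `t` (positive when
#'   induced > repressed), `p`, `p_bonferroni` (capped at 1),
#'   `degenerate`.
#' @export
occurrence_test <- function(counts, induced, repressed, var_equal = TRUE) {
  fam <- setdiff(names(counts), c("promoter_id", "gene_id"))
  if (!length(fam)) stop("no count columns")
  gi <- counts$gene_id %in% induced
  gr <- counts$gene_id %in% repressed
  if (!any(gi) || !any(gr)) stop("both groups must be non-empty")
  rows <- lapply(fam, function(f) {
    a <- counts[[f]][gi]
    b <- counts[[f]][gr]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(data.frame(family = f, mean_induced = mean(a),
                        mean_repressed = mean(b), t = 0, p = 1,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(family = f, mean_induced = mean(a), mean_repressed = mean(b),
               t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * length(fam), 1)
  attr(out, "n_families") <- length(fam)
  attr(out, "var_equal") <- var_equal
  class(out) <- c("occurrence_test", "data.frame")
  out
}
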