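#' Cross-organ concordance against an independence model
#'
#' For a pair of organ classifications sharing a gene universe, tabulates
#' the observed 3 x 3 joint counts over up/down/unchanged and the counts
#' expected if the two organs' classifications were statistically
#' independent: `expected[i, j] = marginalA[i] * marginalB[j] / N`, where
#' N is the size of the shared universe. Cells where the observed count
#' exceeds (falls short of) the expectation are flagged `+` (`-`).
#'
#' When both classifications carry per-gene labels, the universe is their
#' intersection and the observed matrix is the joint cross-tabulation.
#' Count-only classifications (see [organ_class_counts()]) must share the
#' same total; they yield the expected matrix with `observed = NULL`, which
#' is how published marginal totals are fed to the independence model.
#'
#' @param clsA,clsB `organ_class` objects.
#' @return object of class `concordance`: list with `organs`, `observed`
#'   (3 x 3 integer matrix or NULL), `expected` (3 x 3 real, sums to N
#'   exactly), `flags` (character matrix or NULL), `N`.
#' @examples
#' pla <- organ_class_counts(2844, 2978, 17634, "placenta")
#' lun <- organ_class_counts(3642, 4418, 15396, "lung")
#' expected_counts(pla, lun)
#' @export
expected_counts <- function(clsA, clsB) {
  stopifnot(inherits(clsA, "organ_class"), inherits(clsB, "organ_class"))
  lv <- c("up", "down", "unchanged")
  if (!is.null(clsA$status) && !is.null(clsB$status)) {
    shared <- intersect(names(clsA$status), names(clsB$status))
    if (!length(shared)) stop("empty gene-universe intersection")
    a <- clsA$status[shared]
    b <- clsB$status[shared]
    observed <- as.matrix(table(a, b))
    margA <- table(a)[lv]
    margB <- table(b)[lv]
    N <- length(shared)
    observed <- matrix(as.integer(observed[lv, lv]), 3, 3,
                       dimnames = list(A = lv, B = lv))
  } else {
    if (clsA$total != clsB$total) {
      stop("count-only classifications must share the same gene universe size")
    }
    N <- clsA$total
    margA <- clsA$counts[lv]
    margB <- clsB$counts[lv]
    observed <- NULL
  }
  expected <- outer(as.numeric(margA), as.numeric(margB)) / N
  dimnames(expected) <- list(A = lv, B = lv)
  flags <- if (!is.null(observed)) {
    matrix(ifelse(observed > expected, "+",
                  ifelse(observed < expected, "-", "=")), 3, 3,
           dimnames = dimnames(expected))
  }
  out <- list(organs = c(clsA$organ, clsB$organ), observed = observed,
              expected = expected, flags = flags, N = N)
  class(out) <- "concordance"
  out
}

#' @export
print.concordance <- function(x, digits = 1, ...) {
  cat(sprintf("Concordance %s x %s (N = %d genes)\n", x$organs[1],
              x$organs[2], x$N))
  cat("Expected under independence (rounded):\n")
  print(round(x$expected))
  if (!is.null(x$observed)) {
    cat("Observed:\n")
    print(x$observed)
    cat("Excess(+)/deficit(-):\n")
    print(x$flags, quote = FALSE)
  }
  invisible(x)
}

#' Pearson correlation matrix between organ log2-ratio profiles
#'
#' Merges the tables on gene id and computes pairwise-complete Pearson
#' correlations of the per-gene log2 ratios.
#'
#' @param tables list of [expression_table()] objects (>= 2 organs).
#' @return symmetric correlation matrix with unit diagonal, one
#'   row/column per organ.
#' @export
organ_correlation_matrix <- function(tables) {
  if (length(tables) < 2) stop("need at least two organs")
  organs <- vapply(tables, function(t) attr(t, "organ"), character(1))
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"))))
  m <- matrix(NA_real_, length(genes), length(tables),
              dimnames = list(genes, organs))
  for (i in seq_along(tables)) {
    m[tables[[i]]$gene_id, i] <- tables[[i]]$log2_ratio
  }
  for (i in seq_along(tables)) {
    v <- stats::var(m[, i], na.rm = TRUE)
    if (!is.finite(v) || v == 0) {
      stop("zero-variance log2 ratios for organ: ", organs[i])
    }
  }
  n_shared <- crossprod(!is.na(m))
  if (any(n_shared < 3)) stop("pairwise-complete gene intersection < 3")
  r <- stats::cor(m, use = "pairwise.complete.obs")
  r[cbind(seq_along(organs), seq_along(organs))] <- 1
  r
}

#' Agglomerative clustering of organs from a correlation matrix
#'
#' Converts correlations to distances d = 1 - r and clusters with
#' [stats::hclust()]. Rows are ordered by label before clustering so tied
#' merges resolve deterministically.
#'
#' @param corr symmetric correlation matrix with organ dimnames.
#' @param method linkage: `"average"` (default), `"complete"` or
#'   `"single"`.
#' @return an object of classes `organ_dendrogram` and `hclust`;
#'   attributes `distance` ("1 - pearson r") and `dist_matrix` (the
#'   distance object used).
#' @export
cluster_organs <- function(corr, method = c("average", "complete", "single")) {
  method <- match.arg(method)
  if (!isSymmetric(unname(corr), tol = 1e-8)) {
    stop("correlation matrix must be symmetric")
  }
  ord <- order(rownames(corr))
  corr <- corr[ord, ord]
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = method)
  attr(hc, "distance") <- "1 - pearson r"
  attr(hc, "dist_matrix") <- d
  class(hc) <- c("organ_dendrogram", "hclust")
  hc
}

#' Members of the two top-level clusters of a dendrogram
#' @param dend an `organ_dendrogram` (or any hclust).
#' @return list of two character vectors of leaf labels, the bipartition
#'   produced by the final merge.
#' @export
top_split <- function(dend) {
  k2 <- stats::cutree(dend, k = 2)
  split(names(k2), unname(k2))
}

#' Export a dendrogram with heights as Newick
#' @param dend an `organ_dendrogram`.
#' @param path output file.
#' @export
write_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Cophenetic robustness of an organ dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances implied by the tree, a standard measure of how
#' faithfully the dendrogram represents the distance matrix. Significance
#' is either a two-sided t test on the n(n-1)/2 pair distances with
#' n_pairs - 2 degrees of freedom (`method = "ttest"`, an approximation:
#' pair distances are not independent) or a label-permutation test
#' (`method = "permutation"`).
#'
#' @param dend an `organ_dendrogram`/hclust.
#' @param original_distances `dist` or symmetric matrix of the distances
#'   the tree was built from; defaults to the matrix stored on the tree.
#' @param method `"ttest"` or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list with `r_cophenetic`, `p_value`, `statistic` (t, or NA),
#'   `df`, `method`, `defined` (FALSE when the distance vector is
#'   constant, in which case r is NA).
#' @export
cophenetic_test <- function(dend, original_distances = attr(dend, "dist_matrix"),
                            method = c("ttest", "permutation"), n_perm = 999) {
  method <- match.arg(method)
  if (is.null(original_distances)) stop("no original distance matrix supplied")
  d0 <- stats::as.dist(original_distances)
  dc <- stats::cophenetic(dend)
  # align pair order by labels
  lab <- attr(d0, "Labels")
  dcm <- as.matrix(dc)[lab, lab]
  v0 <- as.vector(d0)
  vc <- as.vector(stats::as.dist(dcm))
  m <- length(v0)
  if (stats::var(v0) == 0 || stats::var(vc) == 0) {
    return(list(r_cophenetic = NA_real_, p_value = NA_real_,
                statistic = NA_real_, df = m - 2L, method = method,
                defined = FALSE))
  }
  r <- stats::cor(v0, vc)
  if (method == "ttest") {
    if (m - 2 <= 0) stop("need >= 4 leaves for a defined p-value")
    if (1 - r^2 < .Machine$double.eps) {
      tt <- Inf
      p <- 0
    } else {
      tt <- r * sqrt((m - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tt), df = m - 2)
    }
    list(r_cophenetic = r, p_value = p, statistic = tt, df = m - 2L,
         method = "ttest", defined = TRUE)
  } else {
    n <- length(lab)
    d0m <- as.matrix(d0)
    rs <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      stats::cor(as.vector(stats::as.dist(d0m[idx, idx])), vc)
    }, numeric(1))
    p <- (1 + sum(rs >= r)) / (n_perm + 1)
    list(r_cophenetic = r, p_value = p, statistic = NA_real_, df = NA_integer_,
         method = "permutation", defined = TRUE)
  }
}

#' @export
plot.organ_dendrogram <- function(x, ...) {
  y <- x
  class(y) <- "hclust"
  graphics::plot(y, ylab = attr(x, "distance"), sub = "", xlab = "", ...)
  invisible(x)
}
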