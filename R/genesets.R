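#' Deviation of a gene panel from the genome background
#'
#' Pearson goodness-of-fit chi-squared test of a panel's up/down/unchanged
#' composition in one organ against the proportions of the whole genome
#' (no continuity correction). In `two_class` mode the categories are
#' collapsed to down vs rest (genes reduced beyond the threshold against
#' everything else). The background defaults to the whole-genome class
#' proportions including the panel itself; `background = "complement"`
#' removes the panel's own counts first.
#'
#' @param cls an `organ_class`. If it carries per-gene labels the panel's
#'   observed counts are tabulated from them; otherwise supply `observed`.
#' @param set character vector of panel member gene ids (ignored when
#'   `observed` is given).
#' @param mode `"three_class"` (up/down/unchanged, df 2) or `"two_class"`
#'   (down vs rest, df 1).
#' @param background `"whole_genome"` (default) or `"complement"`.
#' @param observed optional integer vector `c(up, down, unchanged)` of the
#'   panel's counts, e.g. as printed in a publication table.
#' @param set_name label carried into the result.
#' @return object of class `set_deviation`: list with `set_name`, `organ`,
#'   `observed`, `expected` (sums to set size), `chi2`, `df` (classes with
#'   positive expectation minus 1, so a structurally empty class does not
#'   consume a degree of freedom), `p`, `mode`. An expected cell of 0 with
#'   a positive observed count gives `chi2 = Inf`, `p = 0`, flagged via
#'   `degenerate = TRUE`.
#' @examples
#' liver <- organ_class_counts(2950, 2607, 17899, "liver")
#' set_deviation_test(liver, observed = c(1, 5, 3), set_name = "DNMTs")
#' @export
set_deviation_test <- function(cls, set = NULL,
                               mode = c("three_class", "two_class"),
                               background = c("whole_genome", "complement"),
                               observed = NULL, set_name = "set") {
  mode <- match.arg(mode)
  background <- match.arg(background)
  stopifnot(inherits(cls, "organ_class"))
  if (is.null(observed)) {
    if (is.null(set)) stop("supply a member set or observed counts")
    members <- intersect(set, names(cls$status))
    if (!length(members)) stop("set size 0 after intersection with universe")
    tab <- table(cls$status[members])
    observed <- as.integer(tab[c("up", "down", "unchanged")])
  } else {
    observed <- as.integer(observed)
    if (length(observed) != 3) stop("observed must be c(up, down, unchanged)")
  }
  size <- sum(observed)
  if (size == 0) stop("set size 0")
  genome <- as.numeric(cls$counts[c("up", "down", "unchanged")])
  if (background == "complement") genome <- genome - observed
  if (mode == "two_class") {
    observed <- c(down = observed[2], rest = observed[1] + observed[3])
    genome <- c(genome[2], genome[1] + genome[3])
  } else {
    names(observed) <- c("up", "down", "unchanged")
  }
  props <- genome / sum(genome)
  expected <- size * props
  degenerate <- any(expected == 0 & observed > 0)
  if (degenerate) {
    chi2 <- Inf
    p <- 0
  } else {
    keep <- expected > 0  # empty class with observed 0 contributes nothing
    if (any(expected[keep] < 1)) {
      warning("expected cell(s) below 1; chi-squared approximation is rough")
    }
    chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
    df <- sum(keep) - 1L  # classes with positive expectation carry the df
    p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  }
  if (degenerate) df <- length(observed) - 1L
  out <- list(set_name = set_name, organ = cls$organ, observed = observed,
              expected = expected, chi2 = chi2, df = df,
              p = p, mode = mode, background = background,
              degenerate = degenerate)
  class(out) <- "set_deviation"
  out
}

#' @export
print.set_deviation <- function(x, ...) {
  cat(sprintf("Panel deviation: %s in %s (%s, background = %s)\n", x$set_name,
              x$organ, x$mode, x$background))
  print(rbind(observed = x$observed, expected = round(x$expected, 2)))
  cat(sprintf("  chi2 = %.4g, df = %d, p = %.4g%s\n", x$chi2, x$df, x$p,
              if (x$degenerate) " [degenerate: empty expected cell]" else ""))
  invisible(x)
}

#' Panel-by-organ deviation table
#'
#' Runs [set_deviation_test()] for every panel of a collection against
#' every organ classification and assembles the counts and p-values in one
#' data.frame (one row per panel x organ).
#'
#' @param cls_list list of `organ_class` objects with per-gene labels.
#' @param sets a `gene_set_collection`.
#' @inheritParams set_deviation_test
#' @return data.frame with columns set_name, organ, n_up, n_down,
#'   n_unchanged, chi2, df, p.
#' @export
set_deviation_table <- function(cls_list, sets,
                                mode = c("three_class", "two_class"),
                                background = c("whole_genome", "complement")) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  rows <- list()
  for (nm in names(sets)) {
    for (cls in cls_list) {
      r <- set_deviation_test(cls, sets[[nm]], mode = mode,
                              background = background, set_name = nm)
      o <- if (mode == "three_class") r$observed else
        c(NA_integer_, r$observed[["down"]], NA_integer_)
      rows[[length(rows) + 1L]] <- data.frame(
        set_name = nm, organ = cls$organ, n_up = o[[1]], n_down = o[[2]],
        n_unchanged = o[[3]], chi2 = r$chi2, df = r$df, p = r$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Over-representation of modified genes in a pathway
#'
#' Compares the observed number of modified genes in a pathway with the
#' count expected from the genome-wide modification rate:
#' `expected = set_total * n_modified / universe`. The p-value is the
#' upper tail P(X >= n_observed) under a binomial draw of `set_total`
#' genes at rate `n_modified / universe` (default), or under the
#' hypergeometric model of sampling without replacement.
#'
#' @param n_observed modified genes observed in the pathway.
#' @param set_total genes of the pathway present on the platform.
#' @param n_modified modified genes genome-wide.
#' @param universe genes on the platform.
#' @param model `"binomial"` (default) or `"hypergeometric"`.
#' @return list with `expected`, `p`, `model`.
#' @export
overrepresentation_test <- function(n_observed, set_total, n_modified,
                                    universe,
                                    model = c("binomial", "hypergeometric")) {
  model <- match.arg(model)
  if (n_observed > set_total || set_total > universe || n_modified > universe ||
      any(c(n_observed, set_total, n_modified, universe) < 0)) {
    stop("inconsistent counts")
  }
  expected <- set_total * n_modified / universe
  p <- if (model == "binomial") {
    stats::pbinom(n_observed - 1, size = set_total,
                  prob = n_modified / universe, lower.tail = FALSE)
  } else {
    stats::phyper(n_observed - 1, m = n_modified, n = universe - n_modified,
                  k = set_total, lower.tail = FALSE)
  }
  list(expected = expected, p = p, model = model)
}
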