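#' Read a per-organ expression ratio table
#'
#' Reads a tab-delimited table of per-gene expression ratios for one organ.
#' The file must have a header and a `gene_id` column (or the first column
#' is taken as the gene id), plus either one or more log2-ratio columns
#' (names starting with `log2_ratio`) or paired intensity columns (names
#' starting with `treated` and `control`, matched in order). When several
#' ratio columns (replicate hybridizations) are present their log2 ratios
#' are averaged. Genes whose ratio is not finite -- e.g. a zero control
#' intensity -- are dropped, and the number dropped is reported.
#'
#' @param path path to a TSV file; lines starting with `#` are comments.
#' @param organ organ label attached to the table.
#' @return An `expression_table`: a data.frame with columns `gene_id` and
#'   `log2_ratio`, attributes `organ` and `n_dropped`.
#' @seealso [expression_table()], [write_ratio_table()]
#' @export
read_ratio_table <- function(path, organ) {
  x <- read_tsv(path)
  idcol <- if ("gene_id" %in% names(x)) "gene_id" else names(x)[1L]
  ratio_cols <- grep("^log2_ratio", names(x), value = TRUE)
  if (length(ratio_cols)) {
    lr <- rowMeans(as.matrix(x[ratio_cols]), na.rm = FALSE)
  } else {
    tr <- grep("^treated", names(x), value = TRUE)
    ct <- grep("^control", names(x), value = TRUE)
    if (!length(tr) || length(tr) != length(ct)) {
      stop("format error: need a 'log2_ratio' column or matched ",
           "'treated'/'control' intensity columns in ", path)
    }
    lr <- rowMeans(log2(as.matrix(x[tr]) / as.matrix(x[ct])))
  }
  expression_table(as.character(x[[idcol]]), lr, organ = organ)
}

#' Construct an expression table
#'
#' @param gene_id character vector of gene identifiers, unique.
#' @param log2_ratio numeric log2(treated/control) ratios; non-finite
#'   entries are dropped with a message.
#' @param organ organ label.
#' @return data.frame of class `expression_table` with attributes `organ`
#'   and `n_dropped`.
#' @export
expression_table <- function(gene_id, log2_ratio, organ) {
  gene_id <- as.character(gene_id)
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop("validation error: duplicated gene id(s): ",
         paste(unique(dup)[seq_len(min(5, length(unique(dup))))], collapse = ", "))
  }
  keep <- is.finite(log2_ratio)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(organ, ": dropped ", n_dropped, " gene(s) with non-finite log2 ratio")
  }
  out <- data.frame(gene_id = gene_id[keep], log2_ratio = log2_ratio[keep],
                    stringsAsFactors = FALSE)
  attr(out, "organ") <- organ
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("expression_table", "data.frame")
  out
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", attr(x, "organ"), "--", nrow(x), "genes",
      sprintf("(%d dropped on read)\n", attr(x, "n_dropped")))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write an expression ratio table
#' @param x an `expression_table`.
#' @param path output TSV path.
#' @export
write_ratio_table <- function(x, path) {
  utils::write.table(as.data.frame(x)[c("gene_id", "log2_ratio")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (BED or 1-based TSV)
#'
#' Coordinates are held internally 0-based half-open (BED convention).
#' A TSV with 1-based inclusive coordinates (columns `gene_id`,
#' `chromosome`, `start`, `end` and optionally `strand`) is converted on
#' read when `format = "tsv"`.
#'
#' @param path input file.
#' @param format `"bed"` (BED4+, 0-based half-open; optional column 6 is
#'   the strand) or `"tsv"` (header, 1-based inclusive).
#' @return data.frame of class `gene_annotation` with columns `gene_id`,
#'   `chromosome`, `start`, `end`, `strand`; attribute `dialect` records
#'   the input convention.
#' @export
read_annotation <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(x) < 4) stop("format error: BED needs at least 4 columns")
    ann <- data.frame(gene_id = as.character(x[[4]]),
                      chromosome = as.character(x[[1]]),
                      start = as.integer(x[[2]]), end = as.integer(x[[3]]),
                      strand = if (ncol(x) >= 6) as.character(x[[6]]) else "unknown",
                      stringsAsFactors = FALSE)
  } else {
    x <- read_tsv(path)
    need <- c("gene_id", "chromosome", "start", "end")
    if (!all(need %in% names(x))) {
      stop("format error: TSV annotation needs columns ",
           paste(need, collapse = ", "))
    }
    ann <- data.frame(gene_id = as.character(x$gene_id),
                      chromosome = as.character(x$chromosome),
                      start = as.integer(x$start) - 1L,  # 1-based -> 0-based
                      end = as.integer(x$end),
                      strand = if ("strand" %in% names(x)) as.character(x$strand) else "unknown",
                      stringsAsFactors = FALSE)
  }
  gene_annotation(ann, dialect = format)
}

#' Construct/validate a gene annotation
#' @param ann data.frame with gene_id, chromosome, start, end (0-based
#'   half-open) and optionally strand.
#' @param dialect provenance of the source coordinates.
#' @export
gene_annotation <- function(ann, dialect = "internal") {
  if (is.null(ann$strand)) ann$strand <- "unknown"
  ann$strand[!ann$strand %in% c("+", "-")] <- "unknown"
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) {
    stop("validation error: duplicated gene id(s) in annotation: ",
         paste(unique(dup)[seq_len(min(5, length(unique(dup))))], collapse = ", "))
  }
  bad <- ann$end <= ann$start | ann$start < 0
  if (any(bad)) {
    stop("validation error: end <= start (or negative start) for gene(s): ",
         paste(ann$gene_id[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  ann <- ann[c("gene_id", "chromosome", "start", "end", "strand")]
  attr(ann, "dialect") <- dialect
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write an annotation as BED4+2
#' @param ann a `gene_annotation`.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  bed <- data.frame(ann$chromosome, ann$start, ann$end, ann$gene_id,
                    0L, ann$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT lines are `name <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a set are collapsed with a warning; empty sets
#' are retained (size 0) with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors, class `gene_set_collection`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    nm <- f[1]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set '", nm, "': duplicate members collapsed")
      members <- unique(members)
    }
    if (!length(members)) warning("set '", nm, "' is empty")
    sets[[nm]] <- members
  }
  class(sets) <- "gene_set_collection"
  sets
}

#' Write gene sets as GMT
#' @param sets named list of member vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to a gene universe
#'
#' Drops members absent from `universe` and reports how many ids were
#' removed per set.
#'
#' @param sets a `gene_set_collection` (or named list).
#' @param universe character vector of valid gene ids.
#' @return the reconciled collection; attribute `n_dropped` is a named
#'   integer vector of removed-member counts.
#' @export
reconcile_gene_sets <- function(sets, universe) {
  dropped <- integer(length(sets))
  names(dropped) <- names(sets)
  out <- lapply(names(sets), function(nm) {
    keep <- sets[[nm]] %in% universe
    dropped[nm] <<- sum(!keep)
    sets[[nm]][keep]
  })
  names(out) <- names(sets)
  if (any(dropped > 0)) {
    message("reconciliation dropped ", sum(dropped),
            " member id(s) absent from the universe")
  }
  attr(out, "n_dropped") <- dropped
  class(out) <- "gene_set_collection"
  out
}

#' Read position weight matrices in JASPAR text format
#'
#' Accepts the JASPAR flat format: a `>identifier name` header line
#' followed by four rows `A [ 4 17 0 ... ]` (brackets optional) for
#' A, C, G, T counts.
#'
#' @param path JASPAR-format text file.
#' @return named list of 4 x L numeric count matrices with rownames ACGT.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("format error: no '>' header in ", path)
  pwms <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    nm <- strsplit(trimws(hdr), "\\s+")[[1]]
    nm <- nm[length(nm)]  # prefer matrix name over accession when both given
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4) stop("format error: matrix '", nm, "' needs 4 base rows")
    rows <- lapply(body, function(b) {
      b <- gsub("\\[|\\]", " ", b)
      v <- strsplit(trimws(b), "\\s+")[[1]]
      list(base = v[1], counts = as.numeric(v[-1]))
    })
    bases <- toupper(vapply(rows, `[[`, character(1), "base"))
    m <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    pwms[[nm]] <- m
  }
  pwms
}

#' Write position weight matrices in JASPAR text format
#' @param pwms named list of 4 x L count matrices (rows A, C, G, T).
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(names(pwms), function(nm) {
    m <- pwms[[nm]]
    c(paste0(">", nm, " ", nm),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, "  [ ", paste(format(m[b, ]), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA file of promoter sequences; names are promoter ids.
#' @return named character vector of uppercase sequences.
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write promoter sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_promoter_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Columns: `gene_id`, `condition` (treated/control), `replicate`,
#' `ct_target`, `ct_reference`. Ct values outside (0, 45) cycles are
#' flagged with a warning but retained.
#'
#' @param path TSV file.
#' @return data.frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  x <- read_tsv(path)
  need <- c("gene_id", "condition", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(x))) {
    stop("format error: Ct table needs columns ", paste(need, collapse = ", "))
  }
  ct <- c(x$ct_target, x$ct_reference)
  if (any(ct <= 0 | ct >= 45)) {
    warning(sum(ct <= 0 | ct >= 45), " Ct value(s) outside the plausible (0, 45) range")
  }
  x
}

# shared plain-TSV reader: header, '#' comments, no factor coercion
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
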