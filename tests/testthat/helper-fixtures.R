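# fixtures are built in code at test time; nothing is stored on disk

write_lines_tmp <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# expression table with an injected up/down fraction at |log2| >= cut
make_signal_table <- function(n = 1000, frac_up = 0.1, frac_down = 0.1,
                              organ = "organ", noise_sd = 0.2) {
  n_up <- round(n * frac_up)
  n_down <- round(n * frac_down)
  lr <- rnorm(n, 0, noise_sd)
  lr[seq_len(n_up)] <- 1 + rexp(n_up, 2)
  lr[n_up + seq_len(n_down)] <- -(1 + rexp(n_down, 2))
  expression_table(sprintf("g%04d", sample(n)), lr, organ = organ)
}

# annotation with one chromosome of n genes, evenly spaced
make_annotation <- function(n, chromosome = "chr1", spacing = 10000,
                            len = 2000, prefix = "g") {
  gene_annotation(data.frame(
    gene_id = sprintf("%s%04d", prefix, seq_len(n)),
    chromosome = chromosome, start = (seq_len(n) - 1) * spacing,
    end = (seq_len(n) - 1) * spacing + len, strand = "+",
    stringsAsFactors = FALSE))
}

# a strongly-peaked count PWM for a given consensus
make_pwm <- function(consensus, peak = 17) {
  m <- matrix(1, 4, length(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(consensus, rownames(m)), seq_along(consensus))] <- peak
  m
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent naive PWM scan: explicit per-position loop on both strands,
# the oracle for the vectorized scanner
oracle_scan <- function(seq, pwm, score_threshold = 0.85,
                        background = rep(0.25, 4), pseudocount = 0.8) {
  probs <- sweep(pwm + pseudocount / 4, 2, colSums(pwm) + pseudocount, "/")
  lo <- log2(probs / background)
  lo <- rbind(lo, colSums(lo * background))  # row 5: N scores as background
  L <- ncol(lo)
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (length(code) < L) return(0L)
  cutoff <- score_threshold * sum(apply(lo[1:4, , drop = FALSE], 2, max))
  lo_rc <- lo[c(4, 3, 2, 1, 5), L:1, drop = FALSE]
  hits <- 0L
  for (m in list(lo, lo_rc)) {
    for (s in 1:(length(code) - L + 1)) {
      sc <- 0
      for (j in 1:L) sc <- sc + m[code[s + j - 1], j]
      if (sc >= cutoff) hits <- hits + 1L
    }
  }
  hits
}
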