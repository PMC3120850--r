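test_that("extreme selection takes the top and bottom n with lexicographic ties", {
  ids <- sprintf("g%03d", 1:100)
  tab <- expression_table(ids, 1:100, "x")
  ext <- select_extremes(tab, 20)
  expect_setequal(ext$induced, ids[81:100])
  expect_setequal(ext$repressed, ids[1:20])

  # tie at the cut: two candidates share the rank-2 value, lexicographic wins
  tab2 <- expression_table(c("mm", "zz", "aa", sprintf("m%02d", 1:37)),
                           c(3, 5, 5, 6:42), "x")
  ext2 <- select_extremes(tab2, 2)
  expect_equal(ext2$repressed, c("mm", "aa"))
  expect_false("zz" %in% ext2$repressed)

  expect_equal(select_extremes(tab, 0),
               list(induced = character(), repressed = character()))
  expect_error(select_extremes(tab, 60), "2n")
})

test_that("an embedded consensus site is detected", {
  set.seed(41)
  consensus <- c("T", "G", "A", "C", "T", "G", "G", "A")
  pwm <- make_pwm(consensus)
  s <- strsplit(random_seq(300), "")[[1]]
  s[101:108] <- consensus
  expect_gte(scan_promoter(paste(s, collapse = ""), pwm, 0.95), 1)
})

test_that("scanning is strand-symmetric", {
  set.seed(42)
  pwm <- make_pwm(c("T", "G", "A", "C", "T", "G", "G", "A"), peak = 8)
  rc <- pwm[4:1, ncol(pwm):1]
  rownames(rc) <- c("A", "C", "G", "T")
  for (i in 1:5) {
    s <- random_seq(400)
    expect_equal(scan_promoter(s, pwm, 0.8), scan_promoter(s, rc, 0.8))
  }
})

test_that("ten embedded copies are counted at a high threshold", {
  set.seed(43)
  consensus <- c("T", "G", "A", "C", "T", "G", "G", "A")
  pwm <- make_pwm(consensus)
  s <- strsplit(random_seq(900), "")[[1]]
  starts <- seq(10, 900 - 8, by = 88)[1:10]
  for (p in starts) s[p:(p + 7)] <- consensus
  seqc <- paste(s, collapse = "")
  n <- scan_promoter(seqc, pwm, 0.95)
  # brute-force oracle agrees and both see (at least) the 10 embeddings
  expect_identical(n, oracle_scan(seqc, pwm, 0.95))
  expect_gte(n, 10L)
  expect_lte(n, 12L)  # background 8-mers at 0.95 of max are rare
})

test_that("sequences shorter than the matrix and N runs are handled", {
  pwm <- make_pwm(c("T", "G", "A", "C"))
  expect_equal(scan_promoter("TG", pwm), 0L)
  # N scores as background: an all-N sequence scores far below max
  expect_equal(scan_promoter(paste(rep("N", 50), collapse = ""), pwm, 0.85), 0L)
  expect_error(scan_promoter("TGXX", pwm), "outside")
})

test_that("the vectorized scanner equals the naive oracle on random sequences", {
  set.seed(44)
  pwms <- list(make_pwm(c("T", "G", "A", "C", "T", "G", "G", "A")),
               make_pwm(c("A", "A", "T", "T", "C", "C")),
               matrix(c(4, 3, 2, 1, 1, 2, 3, 4, 5, 5, 1, 1), 4,
                      dimnames = list(c("A", "C", "G", "T"), NULL)))
  for (i in 1:25) {
    s <- random_seq(sample(50:400, 1))
    pwm <- pwms[[sample(3, 1)]]
    th <- sample(c(0.7, 0.85, 0.95), 1)
    expect_identical(scan_promoter(s, pwm, th), oracle_scan(s, pwm, th))
  }
})

test_that("count_sites builds one row per promoter, one column per family", {
  set.seed(45)
  seqs <- c(p1 = random_seq(100), p2 = random_seq(100))
  pwms <- list(TF1 = make_pwm(c("T", "G", "A", "C")),
               TF2 = make_pwm(c("A", "C", "G", "T")))
  pg <- c(p1 = "geneA", p2 = "geneB")
  ct <- count_sites(seqs, pwms, pg, score_threshold = 0.9)
  expect_equal(names(ct), c("promoter_id", "gene_id", "TF1", "TF2"))
  expect_equal(ct$gene_id, c("geneA", "geneB"))
  expect_true(all(ct$TF1 >= 0))
})

test_that("occurrence test is antisymmetric and exact in degenerate cases", {
  counts <- data.frame(promoter_id = paste0("p", 1:8),
                       gene_id = rep(c("gi1", "gi2", "gr1", "gr2"), each = 2),
                       TFA = c(5, 6, 4, 7, 1, 2, 1, 0),
                       TFB = rep(2, 8))
  res <- occurrence_test(counts, c("gi1", "gi2"), c("gr1", "gr2"))
  swapped <- occurrence_test(counts, c("gr1", "gr2"), c("gi1", "gi2"))
  expect_equal(res$t[1], -swapped$t[1])
  expect_equal(res$p[1], swapped$p[1])
  # both groups constant: flagged, p = 1
  expect_true(res$degenerate[2])
  expect_equal(res$p[2], 1)
  # bonferroni over the 2 families tested
  expect_equal(res$p_bonferroni, pmin(res$p * 2, 1))
  single <- occurrence_test(counts[c("promoter_id", "gene_id", "TFA")],
                            c("gi1", "gi2"), c("gr1", "gr2"))
  expect_equal(single$p_bonferroni, single$p)
})

test_that("identical count distributions give p = 1", {
  counts <- data.frame(promoter_id = paste0("p", 1:6),
                       gene_id = c("a", "a", "b", "c", "c", "d"),
                       TFA = c(3, 1, 2, 3, 1, 2))
  res <- occurrence_test(counts, c("a", "b"), c("c", "d"))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("a strong Poisson rate shift survives Bonferroni in most seeds", {
  found <- 0L
  for (s in 1:60) {
    set.seed(500 + s)
    n_fam <- 100
    genes <- c(paste0("gi", 1:20), paste0("gr", 1:20))
    counts <- as.data.frame(matrix(rpois(40 * n_fam, 3), 40,
                                   dimnames = list(NULL, sprintf("F%03d", 1:n_fam))))
    counts$F001 <- c(rpois(20, 2), rpois(20, 6))
    counts <- cbind(data.frame(promoter_id = paste0(genes, "_p1"),
                               gene_id = genes, stringsAsFactors = FALSE),
                    counts)
    res <- occurrence_test(counts, paste0("gi", 1:20), paste0("gr", 1:20))
    if (res$p_bonferroni[res$family == "F001"] < 0.05) found <- found + 1L
  }
  expect_gte(found / 60, 0.8)
})
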