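# two-chromosome annotation with configurable gene counts
two_chrom_ann <- function(n1, n2, spacing = 10000) {
  gene_annotation(data.frame(
    gene_id = sprintf("g%04d", seq_len(n1 + n2)),
    chromosome = rep(c("chr1", "chr2"), c(n1, n2)),
    start = c(seq_len(n1) - 1, seq_len(n2) - 1) * spacing,
    end = c(seq_len(n1) - 1, seq_len(n2) - 1) * spacing + 2000,
    strand = "+", stringsAsFactors = FALSE))
}

test_that("a chromosome matching genome proportions has raw p = 1", {
  # two identical chromosomes: each matches the pooled proportions exactly
  n <- 100
  ann <- two_chrom_ann(n, n)
  lr <- rep(c(rep(1.5, 10), rep(-1.5, 20), rep(0, 70)), 2)
  tab <- expression_table(ann$gene_id, lr, "x")
  bias <- per_chromosome_bias(classify(tab), ann)
  expect_equal(bias$p_raw, c(1, 1))
  expect_equal(bias$bonferroni, c(2, 2))  # raw p times number of tests
  expect_equal(bias$chi2[1], bias$chi2[2])
  expect_false(any(bias$significant))
})

test_that("per-class sums over chromosomes equal the annotated genome counts", {
  set.seed(17)
  sim <- sim_study(sim_config(small = TRUE), seed = 17)
  cls <- classify(sim$tables$placenta)
  bias <- per_chromosome_bias(cls, sim$annotation)
  expect_equal(sum(bias$n_up), cls$counts[["up"]])
  expect_equal(sum(bias$n_down), cls$counts[["down"]])
  expect_equal(sum(bias$n_genes), cls$total)
  expect_equal(attr(bias, "n_tests"), nrow(bias))
  expect_equal(bias$bonferroni, bias$p_raw * nrow(bias))
  expect_true(all(bias$bonferroni_capped <= 1))
})

test_that("a down-enriched chromosome is the one flagged, across seeds", {
  n_chrom <- 20
  per <- 100
  n <- n_chrom * per
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chromosome = rep(sprintf("c%02d", seq_len(n_chrom)), each = per),
    start = rep((seq_len(per) - 1) * 10000, n_chrom),
    end = rep((seq_len(per) - 1) * 10000 + 2000, n_chrom),
    strand = "+", stringsAsFactors = FALSE))
  hits <- 0L
  false_hits <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    on_c01 <- ann$chromosome == "c01"
    dereg <- rbinom(n, 1, ifelse(on_c01, 0.45, 0.15))
    dir <- ifelse(on_c01, -1, sample(c(-1, 1), n, TRUE))
    lr <- ifelse(dereg == 1, dir * (1 + rexp(n, 2)), rnorm(n, 0, 0.2))
    bias <- per_chromosome_bias(classify(expression_table(ann$gene_id, lr, "x")), ann)
    if (bias$significant[bias$chromosome == "c01"]) hits <- hits + 1L
    false_hits <- false_hits + sum(bias$significant[bias$chromosome != "c01"])
  }
  expect_gte(hits, 19)
  expect_lte(false_hits / (20 * (n_chrom - 1)), 0.05)
})

test_that("chromosomes below the gene minimum are skipped with a warning", {
  ann <- two_chrom_ann(50, 3)
  tab <- expression_table(ann$gene_id, rnorm(53), "x")
  expect_warning(bias <- per_chromosome_bias(classify(tab), ann), "chr2")
  expect_equal(bias$chromosome, "chr1")
})

test_that("window means are exact for constant and block signals", {
  ann <- make_annotation(30)
  tab <- expression_table(ann$gene_id, rep(0.7, 30), "x")
  prof <- window_profile(tab, ann, k = 10)
  expect_equal(nrow(prof), 21)  # n - k + 1
  expect_equal(prof$mean, rep(0.7, 21))

  lr <- c(rep(0, 10), rep(2, 10), rep(0, 10))
  prof2 <- window_profile(expression_table(ann$gene_id, lr, "x"), ann, k = 10)
  expect_equal(sum(prof2$mean == 2), 1)
  expect_equal(which(prof2$mean == 2), 11)  # only the aligned window
})

test_that("windows never span chromosomes and short chromosomes yield none", {
  ann <- two_chrom_ann(15, 5)
  tab <- expression_table(ann$gene_id, rnorm(20), "x")
  expect_message(prof <- window_profile(tab, ann, k = 10), "chr2")
  expect_true(all(prof$chromosome == "chr1"))
  expect_equal(nrow(prof), 6)
})

test_that("window means equal the arithmetic mean of member ratios", {
  set.seed(23)
  ann <- make_annotation(40)
  lr <- rnorm(40)
  prof <- window_profile(expression_table(ann$gene_id, lr, "x"), ann, k = 7)
  # oracle: direct mean over each window
  for (i in c(1, 10, 34)) {
    expect_equal(prof$mean[i], mean(lr[i:(i + 6)]))
  }
  expect_equal(prof$span_start[1], ann$start[1])
  expect_equal(prof$span_end[1], max(ann$end[1:7]))
})

test_that("window profiles are translation-equivariant", {
  set.seed(4)
  ann <- make_annotation(25)
  shifted <- ann
  shifted$start <- ann$start + 5e6
  shifted$end <- ann$end + 5e6
  tab <- expression_table(ann$gene_id, rnorm(25), "x")
  p1 <- window_profile(tab, ann, k = 5)
  p2 <- window_profile(tab, gene_annotation(as.data.frame(shifted)), k = 5)
  expect_equal(p1$mean, p2$mean)
  expect_equal(p2$span_start - p1$span_start, rep(5e6, nrow(p1)))
})

test_that("region calling finds qualifying runs and nothing in flat profiles", {
  ann <- make_annotation(40)
  flat <- window_profile(expression_table(ann$gene_id, rep(0, 40), "x"), ann)
  expect_equal(nrow(call_regions(flat, 0.5)), 0)

  lr <- c(rep(0, 10), rep(-1.5, 16), rep(0, 14))
  prof <- window_profile(expression_table(ann$gene_id, lr, "x"), ann, k = 10)
  reg <- call_regions(prof, 0.8, min_windows = 3)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$direction, "down")
  expect_lt(reg$mean, -0.8)
})

test_that("region calling is idempotent and monotone in the threshold", {
  set.seed(6)
  ann <- make_annotation(120)
  lr <- rnorm(120, 0, 0.3)
  lr[30:70] <- lr[30:70] - 1.2
  prof <- window_profile(expression_table(ann$gene_id, lr, "x"), ann)
  r1 <- call_regions(prof, 0.5)
  expect_identical(call_regions(prof, 0.5), r1)  # deterministic/idempotent
  r2 <- call_regions(prof, 0.9)
  # higher threshold: every called region lies within some lower-threshold one
  if (nrow(r2) > 0) {
    inside <- vapply(seq_len(nrow(r2)), function(i) {
      any(r1$chromosome == r2$chromosome[i] & r1$start <= r2$start[i] &
            r1$end >= r2$end[i] & r1$direction == r2$direction[i])
    }, logical(1))
    expect_true(all(inside))
  }
  expect_true(sum(r2$n_windows) <= sum(r1$n_windows))
})

test_that("injected clusters are recovered with the window maximum inside the span", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 200
    ann <- make_annotation(n)
    lr <- rnorm(n, 0, 0.3)
    span <- 81:110  # 30-gene cluster
    lr[span] <- rnorm(30, -1.5, 0.3)
    prof <- window_profile(expression_table(ann$gene_id, lr, "x"), ann, k = 10)
    peak <- which.max(abs(prof$mean))
    first_gene_idx <- peak  # window i starts at gene i
    if (first_gene_idx >= min(span) - 9 && first_gene_idx <= max(span)) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 19)
})

test_that("two separated clusters yield two regions with near-true boundaries", {
  set.seed(77)
  n <- 300
  ann <- make_annotation(n)
  lr <- rnorm(n, 0, 0.25)
  lr[41:70] <- rnorm(30, -1.5, 0.25)
  lr[151:180] <- rnorm(30, 1.5, 0.25)
  prof <- window_profile(expression_table(ann$gene_id, lr, "x"), ann, k = 10)
  reg <- call_regions(prof, 0.6, min_windows = 3)
  expect_equal(nrow(reg), 2)
  expect_setequal(reg$direction, c("down", "up"))
  k_bp <- 10 * 10000  # k genes of spacing
  down <- reg[reg$direction == "down", ]
  expect_lt(abs(down$start - ann$start[41]), k_bp + 2000)
  expect_lt(abs(down$end - ann$end[70]), k_bp + 2000)
})
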