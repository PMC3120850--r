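#' Configuration for the synthetic five-organ study generator
#'
#' Defaults emulate the design of a five-organ IUGR/control rat
#' transcriptome study: 23,456 transcripts; organ-specific deregulated
#' fractions of 34% (lung), 24% (liver), 7.7% (kidney), 3.3% (heart) and
#' 24% (placenta) at a two-fold threshold; excess down-regulation in
#' lung, kidney and heart, excess up in liver, near-balance in placenta;
#' and a shared latent deregulation factor that couples the organs with
#' signs making {placenta, kidney} mirror {liver, lung, heart}.
#'
#' @param n_genes transcripts on the simulated array; default 23456.
#' @param small logical; TRUE switches to a 2,000-gene preset (same
#'   structure, desk-scale) for fast runs.
#' @param organs data.frame with columns `organ`, `fraction` (deregulated
#'   fraction), `prob_down` (down-probability among independently
#'   deregulated genes; genes following the shared factor are
#'   direction-symmetric, so the realized down fraction is
#'   `coupling/2 + (1 - coupling) * prob_down`), `sign` (+1/-1 on the
#'   shared factor), `coupling` (strength in [0, 1]).
#' @param noise_sd standard deviation of null log2 ratios; default 0.25.
#' @param effect_mean mean of the exponential excess shift added to
#'   log2(threshold) for deregulated genes (heavy upper tail, so effect
#'   sizes straddle realistic fold changes up to ~10-fold); default 0.7.
#' @param threshold fold threshold the fractions refer to; default 2.
#' @param n_chrom chromosomes (named Chr1..Chr(n-1), ChrX); default 21.
#' @param gene_spacing,gene_length bp between gene starts and gene
#'   length; defaults 10000 and 2000.
#' @param clusters list of injected positional clusters, each a list with
#'   `chromosome`, `first_gene` (index in chromosome gene order),
#'   `n_genes`, `organs`, `direction` (+1/-1), `effect` (|log2 shift|).
#' @param panels named integer vector of gene-panel sizes written as GMT.
#' @param panel_enrichment list of lists (`panel`, `organ`, `direction`,
#'   `odds`): sampling odds multiplier for genes deregulated in that
#'   direction in that organ.
#' @param promoter list: `organ`, `n_extremes`, `n_families`,
#'   `effect_family`, `rate_background`, `rate_induced`,
#'   `rate_repressed` (Poisson site-count rates), `promoters_per_gene`.
#' @param qpcr list: `organ`, `n_genes`, `target_r` (population
#'   correlation between platforms), `ct_noise_sd`, `replicates`.
#' @param seed default RNG seed used by [sim_study()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = if (small) 2000L else 23456L,
                       small = FALSE,
                       organs = data.frame(
                         organ = c("lung", "liver", "kidney", "heart", "placenta"),
                         fraction = c(0.34, 0.24, 0.077, 0.033, 0.24),
                         prob_down = c(0.62, 0.42, 0.685, 0.685, 0.53),
                         sign = c(1, 1, -1, 1, -1),
                         coupling = 0.6,
                         stringsAsFactors = FALSE),
                       noise_sd = 0.25, effect_mean = 0.7, threshold = 2,
                       n_chrom = 21L, gene_spacing = 10000L,
                       gene_length = 2000L,
                       clusters = list(
                         list(chromosome = "Chr15", first_gene = 11L,
                              n_genes = 30L, organs = c("placenta", "kidney"),
                              direction = -1, effect = 1.5),
                         list(chromosome = "Chr15", first_gene = 61L,
                              n_genes = 30L, organs = c("placenta", "kidney"),
                              direction = -1, effect = 1.5)),
                       panels = c(DNMT = 9L, HDAC = 14L, CHD = 16L, BRD = 18L,
                                  HMAT = 12L, imprinted = 83L,
                                  coagulation = 24L, misc_pathway = 14L),
                       panel_enrichment = list(
                         list(panel = "DNMT", organ = "liver",
                              direction = "down", odds = 8),
                         list(panel = "HDAC", organ = "lung",
                              direction = "down", odds = 8),
                         list(panel = "imprinted", organ = "kidney",
                              direction = "up", odds = 8),
                         list(panel = "coagulation", organ = "kidney",
                              direction = "up", odds = 12)),
                       promoter = list(organ = "liver", n_extremes = 20L,
                                       n_families = 100L,
                                       effect_family = "TF001",
                                       rate_background = 3,
                                       rate_induced = 2, rate_repressed = 6,
                                       promoters_per_gene = 1:3),
                       qpcr = list(organ = "liver", n_genes = 12L,
                                   target_r = 0.97, ct_noise_sd = 0.15,
                                   replicates = 4L),
                       seed = 20110601L) {
  cfg <- list(n_genes = as.integer(n_genes), organs = organs,
              noise_sd = noise_sd, effect_mean = effect_mean,
              threshold = threshold, n_chrom = as.integer(n_chrom),
              gene_spacing = gene_spacing, gene_length = gene_length,
              clusters = clusters, panels = panels,
              panel_enrichment = panel_enrichment, promoter = promoter,
              qpcr = qpcr, seed = seed)
  stopifnot(all(cfg$organs$fraction >= 0 & cfg$organs$fraction <= 1),
            all(cfg$organs$coupling >= 0 & cfg$organs$coupling <= 1),
            all(cfg$organs$prob_down >= 0 & cfg$organs$prob_down <= 1),
            all(is.finite(vapply(cfg$clusters, `[[`, numeric(1), "effect"))))
  class(cfg) <- "sim_config"
  cfg
}

# even split of genes over chromosomes; remainder goes to the first ones
sim_chrom_sizes <- function(n_genes, n_chrom) {
  base <- n_genes %/% n_chrom
  extra <- n_genes %% n_chrom
  sizes <- rep(base, n_chrom) + c(rep(1L, extra), rep(0L, n_chrom - extra))
  names(sizes) <- c(paste0("Chr", seq_len(n_chrom - 1)), "ChrX")
  sizes
}

#' Generate a synthetic multi-organ study bundle
#'
#' Draws, under a fixed seed, everything the pipeline consumes: per-organ
#' expression tables, a gene annotation, gene-panel GMT content, a
#' promoter site-count table (plus promoter sequences and a PWM for the
#' effect family, with sites embedded at the drawn counts), a qPCR Ct
#' table, and a `truth` record of every injected signal for
#' parameter-recovery testing.
#'
#' Deregulated genes are selected per organ at the exact configured count
#' via a shared latent score (coupling), and receive log2 shifts of
#' `sign * (log2(threshold) + Exp(effect_mean))`; null genes get
#' N(0, noise_sd) ratios. Injected positional clusters replace an equal
#' number of randomly chosen deregulated genes of the same direction so
#' marginal counts are preserved.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to the config's.
#' @return list of class `sim_bundle` with elements `tables` (named list
#'   of [expression_table()]), `annotation`, `sets`, `promoter` (list:
#'   `counts`, `sequences`, `pwms`, `promoter_genes`, `extremes`), `qpcr`
#'   (list: `ct`, `array_log2`), `truth`, `config`.
#' @export
sim_study <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  # annotation
  sizes <- sim_chrom_sizes(n, config$n_chrom)
  chrom <- rep(names(sizes), sizes)
  idx_in_chrom <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  start <- (idx_in_chrom - 1L) * config$gene_spacing
  ann <- gene_annotation(data.frame(
    gene_id = gene_id, chromosome = chrom, start = start,
    end = start + config$gene_length,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE), dialect = "simulated")

  # cluster membership -> gene indices
  cluster_truth <- lapply(config$clusters, function(cl) {
    in_chr <- which(chrom == cl$chromosome)
    if (cl$first_gene + cl$n_genes - 1L > length(in_chr)) {
      stop("config error: cluster span exceeds gene count of ", cl$chromosome)
    }
    g <- in_chr[cl$first_gene:(cl$first_gene + cl$n_genes - 1L)]
    list(chromosome = cl$chromosome, gene_ids = gene_id[g], idx = g,
         span_start = min(start[g]),
         span_end = max(start[g]) + config$gene_length,
         direction = cl$direction, organs = cl$organs, effect = cl$effect)
  })

  # shared latent structure for cross-organ coupling
  u <- stats::runif(n)
  d <- sample(c(1, -1), n, replace = TRUE)

  tables <- list()
  truth_organs <- list()
  for (i in seq_len(nrow(config$organs))) {
    o <- config$organs[i, ]
    n_d <- round(o$fraction * n)
    follow <- stats::runif(n) < o$coupling
    score <- ifelse(follow, u, stats::runif(n))
    dereg <- logical(n)
    dereg[order(score)[seq_len(n_d)]] <- TRUE
    dir <- ifelse(follow, o$sign * d,
                  ifelse(stats::runif(n) < o$prob_down, -1, 1))
    lr <- stats::rnorm(n, 0, config$noise_sd)
    shift <- log2(config$threshold) + stats::rexp(n, rate = 1 / config$effect_mean)
    lr[dereg] <- (dir * shift)[dereg]
    # injected clusters: force, then retire matched deregulated genes
    for (cl in cluster_truth) {
      if (!(o$organ %in% cl$organs)) next
      newly <- cl$idx[!dereg[cl$idx]]
      lr[cl$idx] <- cl$direction * cl$effect +
        stats::rnorm(length(cl$idx), 0, config$noise_sd)
      dereg[cl$idx] <- TRUE
      dir[cl$idx] <- cl$direction
      pool <- setdiff(which(dereg & dir == cl$direction), cl$idx)
      retire <- sample(pool, min(length(newly), length(pool)))
      dereg[retire] <- FALSE
      lr[retire] <- stats::rnorm(length(retire), 0, config$noise_sd)
    }
    tables[[o$organ]] <- expression_table(gene_id, lr, organ = o$organ)
    truth_organs[[o$organ]] <- list(
      fraction = o$fraction, n_deregulated = sum(dereg),
      up = gene_id[dereg & dir > 0], down = gene_id[dereg & dir < 0])
  }

  # gene panels with enrichment odds
  sets <- list()
  for (nm in names(config$panels)) {
    w <- rep(1, n)
    for (en in config$panel_enrichment) {
      if (en$panel != nm) next
      tr <- truth_organs[[en$organ]]
      hit <- gene_id %in% tr[[en$direction]]
      w[hit] <- w[hit] * en$odds
    }
    sets[[nm]] <- sort(sample(gene_id, config$panels[[nm]], prob = w))
  }
  class(sets) <- "gene_set_collection"

  promoter <- sim_promoters(config, tables)
  qpcr <- sim_qpcr(config, tables)

  truth <- list(seed = seed, organs = truth_organs,
                clusters = lapply(cluster_truth, function(cl) {
                  cl[c("chromosome", "gene_ids", "span_start", "span_end",
                       "direction", "organs", "effect")]
                }),
                panel_enrichment = config$panel_enrichment,
                promoter = promoter$truth, qpcr = qpcr$truth)
  out <- list(tables = tables, annotation = ann, sets = sets,
              promoter = promoter[c("counts", "sequences", "pwms",
                                    "promoter_genes", "extremes")],
              qpcr = qpcr[c("ct", "array_log2")],
              truth = truth, config = config)
  class(out) <- "sim_bundle"
  out
}

# promoter site-count model + sequences carrying the effect family's sites
sim_promoters <- function(config, tables) {
  pm <- config$promoter
  tab <- tables[[pm$organ]]
  ext <- select_extremes(tab, pm$n_extremes)
  genes <- c(ext$induced, ext$repressed)
  n_prom <- sample(pm$promoters_per_gene, length(genes), replace = TRUE)
  promoter_genes <- rep(genes, n_prom)
  promoter_id <- paste0(promoter_genes, "_p",
                        unlist(lapply(n_prom, seq_len), use.names = FALSE))
  names(promoter_genes) <- promoter_id
  fam <- sprintf("TF%03d", seq_len(pm$n_families))
  group <- ifelse(promoter_genes %in% ext$induced, "induced", "repressed")
  counts <- matrix(stats::rpois(length(promoter_id) * pm$n_families,
                                pm$rate_background),
                   nrow = length(promoter_id), dimnames = list(NULL, fam))
  eff_rate <- ifelse(group == "induced", pm$rate_induced, pm$rate_repressed)
  counts[, pm$effect_family] <- stats::rpois(length(promoter_id), eff_rate)
  count_df <- cbind(data.frame(promoter_id = promoter_id,
                               gene_id = unname(promoter_genes),
                               stringsAsFactors = FALSE),
                    as.data.frame(counts))

  # effect-family PWM (strong consensus) and sequences embedding its sites
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A")
  m <- matrix(1, 4, length(consensus), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(consensus, rownames(m)), seq_along(consensus))] <- 17
  pwms <- stats::setNames(list(m), pm$effect_family)
  L <- length(consensus)
  seqs <- vapply(seq_along(promoter_id), function(i) {
    s <- sample(c("A", "C", "G", "T"), 800, replace = TRUE)
    k <- count_df[[pm$effect_family]][i]
    if (k > 0) {
      slots <- seq(1, 800 - L, by = L + 4)
      at <- sample(slots, min(k, length(slots)))
      for (p in at) s[p:(p + L - 1)] <- consensus
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- promoter_id

  list(counts = count_df, sequences = seqs, pwms = pwms,
       promoter_genes = promoter_genes, extremes = ext,
       truth = list(effect_family = pm$effect_family,
                    rate_background = pm$rate_background,
                    rate_induced = pm$rate_induced,
                    rate_repressed = pm$rate_repressed,
                    induced = ext$induced, repressed = ext$repressed))
}

# qPCR panel: platform noise calibrated to the target cross-platform r
sim_qpcr <- function(config, tables) {
  qc <- config$qpcr
  tab <- tables[[qc$organ]]
  # spread panel across the ratio range: quantile-ranked picks
  ord <- order(tab$log2_ratio)
  pick <- ord[round(seq(1, nrow(tab), length.out = qc$n_genes))]
  genes <- tab$gene_id[pick]
  array_lr <- tab$log2_ratio[pick]
  names(array_lr) <- genes
  sigma <- stats::sd(array_lr) * sqrt(1 / qc$target_r^2 - 1)
  qpcr_lr <- array_lr + stats::rnorm(qc$n_genes, 0, sigma)
  rows <- list()
  for (i in seq_along(genes)) {
    base <- stats::runif(1, 8, 14)  # gene-specific dCt in the control
    for (cond in c("treated", "control")) {
      dct <- if (cond == "treated") base - qpcr_lr[i] else base
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes[i], condition = cond, replicate = seq_len(qc$replicates),
        ct_target = 12 + dct + stats::rnorm(qc$replicates, 0, qc$ct_noise_sd),
        ct_reference = 12 + stats::rnorm(qc$replicates, 0, qc$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(ct = do.call(rbind, rows), array_log2 = array_lr,
       truth = list(genes = genes, array_log2 = unname(array_lr),
                    qpcr_log2 = unname(qpcr_lr), noise_sd = sigma,
                    target_r = qc$target_r))
}

#' Write a simulated bundle to disk
#'
#' Emits the pipeline's external formats: one ratio TSV per organ
#' (`<organ>_ratios.tsv`), `annotation.bed`, `panels.gmt`,
#' `promoter_counts.tsv`, `promoters.fa`, `pwms.jaspar`, `qpcr_ct.tsv`,
#' and `truth.json`.
#'
#' @param sim a `sim_bundle` from [sim_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (organ in names(sim$tables)) {
    p <- file.path(dir, paste0(organ, "_ratios.tsv"))
    write_ratio_table(sim$tables[[organ]], p)
    paths[paste0("ratios_", organ)] <- p
  }
  paths["annotation"] <- write_annotation(sim$annotation,
                                          file.path(dir, "annotation.bed"))
  paths["panels"] <- write_gene_sets(sim$sets, file.path(dir, "panels.gmt"))
  paths["promoter_counts"] <- write_tsv(sim$promoter$counts,
                                        file.path(dir, "promoter_counts.tsv"))
  paths["promoters"] <- write_promoter_fasta(sim$promoter$sequences,
                                             file.path(dir, "promoters.fa"))
  paths["pwms"] <- write_jaspar(sim$promoter$pwms,
                                file.path(dir, "pwms.jaspar"))
  paths["qpcr_ct"] <- write_tsv(sim$qpcr$ct, file.path(dir, "qpcr_ct.tsv"))
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
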