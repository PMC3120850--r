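#' Load a study bundle from a directory
#'
#' Reads the file layout written by [write_sim_bundle()] (or assembled by
#' hand in the same formats): `<organ>_ratios.tsv` per organ, optional
#' `annotation.bed`, `panels.gmt`, `promoter_counts.tsv`, `promoters.fa`,
#' `pwms.jaspar`, `qpcr_ct.tsv`. Missing optional inputs yield NULL
#' elements, which the pipeline treats as stages to skip.
#'
#' @param dir bundle directory.
#' @return list with `tables`, `annotation`, `sets`, `promoter_counts`,
#'   `promoter_seqs`, `pwms`, `qpcr_ct`, `paths`.
#' @export
load_bundle <- function(dir) {
  ratio_files <- list.files(dir, pattern = "_ratios\\.tsv$", full.names = TRUE)
  if (!length(ratio_files)) stop("no *_ratios.tsv files in ", dir)
  organs <- sub("_ratios\\.tsv$", "", basename(ratio_files))
  tables <- Map(read_ratio_table, ratio_files, organs)
  names(tables) <- organs
  opt <- function(fname, reader) {
    p <- file.path(dir, fname)
    if (file.exists(p)) reader(p) else NULL
  }
  list(tables = tables,
       annotation = opt("annotation.bed", read_annotation),
       sets = opt("panels.gmt", read_gene_sets),
       promoter_counts = opt("promoter_counts.tsv", read_tsv),
       promoter_seqs = opt("promoters.fa", read_promoter_fasta),
       pwms = opt("pwms.jaspar", read_jaspar),
       qpcr_ct = opt("qpcr_ct.tsv", read_ct_table),
       paths = c(stats::setNames(ratio_files, paste0("ratios_", organs)),
                 annotation = file.path(dir, "annotation.bed"),
                 panels = file.path(dir, "panels.gmt")))
}

#' Run the full multi-organ analysis
#'
#' Orchestrates classification, cross-organ concordance and clustering,
#' gene-panel deviation tests, chromosome bias and window scans, the
#' promoter occurrence comparison and qPCR concordance over a study
#' bundle, writing one TSV per result plus a JSON run manifest recording
#' parameters, input digests and per-stage outputs. Stages whose inputs
#' are absent are skipped with a notice in the manifest.
#'
#' @param bundle a `sim_bundle`, a bundle directory path, or a list as
#'   returned by [load_bundle()].
#' @param out_dir output directory.
#' @param threshold fold threshold; default 2.
#' @param k sliding-window size in genes; default 10.
#' @param region_threshold minimum |window mean| for region calling;
#'   default 0.5.
#' @param min_windows minimum windows per called region; default 3.
#' @param n_extremes genes per extreme for the promoter stage; default 20.
#' @param mode class mode for deviation tests; default `"three_class"`.
#' @param figures write PDF figures for the dendrogram and chromosome
#'   profiles; default FALSE.
#' @return invisibly, the manifest list; component `report` is a
#'   data.frame of per-stage status.
#' @export
run_pipeline <- function(bundle, out_dir, threshold = 2, k = 10,
                         region_threshold = 0.5, min_windows = 3,
                         n_extremes = 20, mode = "three_class",
                         figures = FALSE) {
  if (is.character(bundle)) bundle <- load_bundle(bundle)
  if (inherits(bundle, "sim_bundle")) {
    bundle <- list(tables = bundle$tables, annotation = bundle$annotation,
                   sets = bundle$sets,
                   promoter_counts = bundle$promoter$counts,
                   promoter_seqs = bundle$promoter$sequences,
                   pwms = bundle$promoter$pwms, qpcr_ct = bundle$qpcr$ct,
                   paths = character())
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = paste0("modeg ", as.character(utils::packageVersion("modeg"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(threshold = threshold, k = k,
                      region_threshold = region_threshold,
                      min_windows = min_windows, n_extremes = n_extremes,
                      mode = mode),
    inputs = as.list(tools::md5sum(bundle$paths[file.exists(bundle$paths)])),
    stages = list())
  status <- list()
  nwarn <- 0L
  run_stage <- function(name, expr) {
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        msg <- conditionMessage(e)
        verb <- if (startsWith(msg, "no ")) "skipped:" else "failed:"
        status[[name]] <<- paste(verb, msg)
        NULL
      }),
      warning = function(w) {
        nwarn <<- nwarn + 1L
        invokeRestart("muffleWarning")
      })
    if (is.null(status[[name]])) status[[name]] <<- "ok"
    res
  }

  # 1. classification
  cls <- run_stage("classify", {
    out <- lapply(bundle$tables, classify, threshold = threshold)
    for (organ in names(out)) {
      write_classification(out[[organ]],
                           file.path(out_dir, paste0(organ, "_class.tsv")))
    }
    fractions <- vapply(out, modified_fraction, numeric(1))
    bias <- lapply(out, directional_bias_test)
    write_tsv(data.frame(
      organ = names(out),
      n_up = vapply(out, function(x) x$counts[["up"]], integer(1)),
      n_down = vapply(out, function(x) x$counts[["down"]], integer(1)),
      n_unchanged = vapply(out, function(x) x$counts[["unchanged"]], integer(1)),
      modified_pct = fractions,
      bias_direction = vapply(bias, `[[`, character(1), "direction"),
      bias_p = vapply(bias, `[[`, numeric(1), "p_value")),
      file.path(out_dir, "classification_summary.tsv"))
    out
  })

  # 2. cross-organ concordance + clustering
  cross <- run_stage("concordance", {
    if (length(bundle$tables) < 2) stop("need >= 2 organs")
    organs <- names(cls)
    pairs <- utils::combn(organs, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      cc <- expected_counts(cls[[pr[1]]], cls[[pr[2]]])
      lv <- rownames(cc$expected)
      grid <- expand.grid(A = lv, B = lv, stringsAsFactors = FALSE)
      data.frame(organ_a = pr[1], organ_b = pr[2], class_a = grid$A,
                 class_b = grid$B,
                 observed = as.vector(cc$observed),
                 expected = as.vector(cc$expected),
                 flag = as.vector(cc$flags), stringsAsFactors = FALSE)
    })
    write_tsv(do.call(rbind, rows), file.path(out_dir, "concordance.tsv"))
    corr <- organ_correlation_matrix(bundle$tables)
    dend <- cluster_organs(corr)
    write_newick(dend, file.path(out_dir, "organ_dendrogram.nwk"))
    coph <- cophenetic_test(dend)
    write_tsv(data.frame(r_cophenetic = coph$r_cophenetic,
                         p_value = coph$p_value, method = coph$method),
              file.path(out_dir, "cophenetic.tsv"))
    if (figures) {
      grDevices::pdf(file.path(out_dir, "organ_dendrogram.pdf"))
      plot(dend, main = "Organ clustering (1 - r, average linkage)")
      grDevices::dev.off()
    }
    list(corr = corr, dend = dend, coph = coph)
  })

  # 3. gene-panel deviation
  run_stage("geneset", {
    if (is.null(bundle$sets)) stop("no gene sets supplied")
    universe <- unique(unlist(lapply(bundle$tables, `[[`, "gene_id")))
    sets <- reconcile_gene_sets(bundle$sets, universe)
    write_tsv(set_deviation_table(cls, sets, mode = mode),
              file.path(out_dir, "geneset_deviation.tsv"))
  })

  # 4. chromosome scan
  run_stage("chromosome", {
    if (is.null(bundle$annotation)) stop("no annotation supplied")
    for (organ in names(cls)) {
      bias <- per_chromosome_bias(cls[[organ]], bundle$annotation)
      write_tsv(as.data.frame(bias),
                file.path(out_dir, paste0(organ, "_chromosome_bias.tsv")))
      prof <- window_profile(bundle$tables[[organ]], bundle$annotation, k = k)
      write_tsv(as.data.frame(prof),
                file.path(out_dir, paste0(organ, "_window_profile.tsv")))
      regions <- call_regions(prof, threshold = region_threshold,
                              min_windows = min_windows)
      write_regions_bed(regions,
                        file.path(out_dir, paste0(organ, "_regions.bed")))
      if (figures && nrow(prof)) {
        grDevices::pdf(file.path(out_dir, paste0(organ, "_profile.pdf")))
        plot(prof, chromosome = prof$chromosome[1], main = organ)
        grDevices::dev.off()
      }
    }
  })

  # 5. promoter occurrence comparison
  run_stage("promoter", {
    counts <- bundle$promoter_counts
    if (is.null(counts)) {
      if (is.null(bundle$promoter_seqs) || is.null(bundle$pwms)) {
        stop("no promoter counts, and no sequences + PWMs to scan")
      }
      pg <- vapply(strsplit(names(bundle$promoter_seqs), "_p"), `[[`,
                   character(1), 1)
      names(pg) <- names(bundle$promoter_seqs)
      counts <- count_sites(bundle$promoter_seqs, bundle$pwms, pg)
    }
    ext <- select_extremes(bundle$tables[[pick_promoter_organ(bundle, counts)]],
                           n_extremes)
    write_tsv(as.data.frame(occurrence_test(counts, ext$induced,
                                            ext$repressed)),
              file.path(out_dir, "promoter_occurrence.tsv"))
  })

  # 6. qPCR concordance
  run_stage("qpcr", {
    if (is.null(bundle$qpcr_ct)) stop("no qPCR Ct table supplied")
    fc <- qpcr_fold_changes(bundle$qpcr_ct)
    write_tsv(fc, file.path(out_dir, "qpcr_fold_changes.tsv"))
    organ <- pick_qpcr_organ(bundle, fc$gene_id)
    arr <- bundle$tables[[organ]]
    arr_lr <- stats::setNames(arr$log2_ratio, arr$gene_id)
    conc <- platform_concordance(stats::setNames(fc$log2_ratio, fc$gene_id),
                                 arr_lr)
    write_tsv(data.frame(organ = organ, r = conc$r,
                         r_squared = conc$r_squared, slope = conc$slope,
                         intercept = conc$intercept, n = conc$n),
              file.path(out_dir, "qpcr_concordance.tsv"))
  })

  manifest$stages <- status
  manifest$n_warnings <- nwarn
  manifest$outputs <- list.files(out_dir, recursive = TRUE)
  manifest$report <- data.frame(stage = names(status),
                                status = unlist(status),
                                stringsAsFactors = FALSE)
  jsonlite::write_json(manifest[setdiff(names(manifest), "report")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- all(manifest$report$status == "ok")
  message("pipeline ", if (ok) "complete" else "finished with skipped/failed stages")
  invisible(manifest)
}

# promoter stage compares extremes of the organ whose extreme genes the
# count table actually covers (falls back to the first organ)
pick_promoter_organ <- function(bundle, counts) {
  hits <- vapply(names(bundle$tables), function(o) {
    sum(counts$gene_id %in% bundle$tables[[o]]$gene_id)
  }, numeric(1))
  best <- names(bundle$tables)[which.max(hits)]
  cover <- vapply(names(bundle$tables), function(o) {
    ext <- tryCatch(select_extremes(bundle$tables[[o]], 1), error = function(e) NULL)
    if (is.null(ext)) return(0)
    sum(counts$gene_id %in% unlist(ext))
  }, numeric(1))
  if (any(cover > 0)) names(bundle$tables)[which.max(cover)] else best
}

pick_qpcr_organ <- function(bundle, genes) {
  hits <- vapply(names(bundle$tables), function(o) {
    sum(genes %in% bundle$tables[[o]]$gene_id)
  }, numeric(1))
  names(bundle$tables)[which.max(hits)]
}

#' Run the pipeline from a YAML configuration
#'
#' The YAML maps directly onto [run_pipeline()] arguments, e.g.
#' `bundle: sim_out/`, `out_dir: results/`, `threshold: 2`, `k: 10`.
#'
#' @param config_path path to a YAML file.
#' @return invisibly, the run manifest.
#' @export
run_pipeline_yaml <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  do.call(run_pipeline, cfg)
}
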