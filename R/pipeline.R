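#' Pipeline configuration
#'
#' Bundles the five input paths, the per-module configurations and the
#' global seed. Every threshold used by the stages (FDR alpha, annotation
#' window, bootstrap/permutation counts, group cutoffs) is carried here;
#' stage code never hard-codes them. The configuration round-trips
#' losslessly through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param samples,counts,gtf,dmrs Paths to the sample table, transcript
#'   count matrix, gene-model GTF and DMR BED.
#' @param cov_files Character vector of per-sample Bismark-style coverage
#'   files (or a single directory containing `<sample>.cov` files).
#' @param outdir Output directory for result tables.
#' @param annotation An [annotation_config()].
#' @param eqtm An [eqtm_config()].
#' @param alpha Gene-level GDE FDR threshold.
#' @param tx_alpha Per-transcript FDR threshold (concordance voting).
#' @param weight_floor Lancaster weight floor (base expression units).
#' @param allosomes Chromosomes removed from both modalities.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, counts, gtf, dmrs, cov_files,
                            outdir = "eqtmpipe_out",
                            annotation = annotation_config(),
                            eqtm = eqtm_config(),
                            alpha = 0.05, tx_alpha = 0.05,
                            weight_floor = 1,
                            allosomes = c("chrX", "chrY", "X", "Y"),
                            seed = 1) {
  structure(
    list(samples = samples, counts = counts, gtf = gtf, dmrs = dmrs,
         cov_files = cov_files, outdir = outdir, annotation = annotation,
         eqtm = eqtm, alpha = alpha, tx_alpha = tx_alpha,
         weight_floor = weight_floor, allosomes = allosomes,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ann <- do.call(annotation_config, y$annotation %||% list())
  eq <- do.call(eqtm_config, y$eqtm %||% list())
  y$annotation <- NULL
  y$eqtm <- NULL
  do.call(pipeline_config, c(y, list(annotation = ann, eqtm = eq)))
}

#' @rdname read_pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$annotation <- unclass(cfg$annotation)
  y$eqtm <- unclass(cfg$eqtm)
  yaml::write_yaml(y, path)
  invisible(path)
}

resolve_cov_files <- function(cov_files) {
  if (length(cov_files) == 1L && dir.exists(cov_files)) {
    cov_files <- sort(list.files(cov_files, pattern = "\\.cov$",
                                 full.names = TRUE))
  }
  cov_files
}

#' Run the full integration pipeline
#'
#' Stages, in order: stratify the cohort by SJC66 and build the covariate
#' design; normalize transcript counts, drop allosome genes, test each
#' transcript and aggregate to gene-level GDE calls (expression-weighted
#' Lancaster + BH); annotate DMRs to genes through the strand-aware
#' promoter window; intersect GDE genes with DMR-linked genes into GDEMs
#' and classify transcript concordance; and score every
#' GDEM x DMR x significant-transcript pair for eQTM (Pearson r,
#' percentile bootstrap CI, consecutive-CpG permutation p). Result tables
#' are written with a provenance header (version, seed, config hash; no
#' timestamps), so identical config + seed gives byte-identical outputs.
#' Any stage error aborts with a stage-tagged message and removes partial
#' outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with every intermediate result and the paths
#'   of the written tables.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  log_line <- function(stage, fmt, ...) {
    if (!quiet) {
      message(sprintf("[%s] %s (%.1fs)", stage, sprintf(fmt, ...),
                      proc.time()[["elapsed"]] - t0))
    }
  }

  # -- config stage: validate inputs before any computation
  cov_files <- resolve_cov_files(cfg$cov_files)
  for (p in c(cfg$samples, cfg$counts, cfg$gtf, cfg$dmrs, cov_files)) {
    if (!file.exists(p)) stage_stop("config", "input path not found: %s", p)
  }
  if (length(cov_files) == 0L) {
    stage_stop("config", "no coverage files found under %s", cfg$cov_files)
  }
  # outdir does not influence any computed value, so it is excluded from
  # the provenance hash
  chash <- config_hash(unclass(cfg)[setdiff(names(cfg), "outdir")])

  written <- character(0)
  on.exit({
    if (!is.null(attr(written, "failed"))) unlink(written)
  })

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      attr(written, "failed") <<- TRUE
      stage_stop(stage, "%s", conditionMessage(e))
    })
  }

  # -- stratify
  res <- list()
  run_stage("stratify", {
    samples <- read_samples_tsv(cfg$samples)
    samples <- dichotomize_sjc66(samples)
    res$samples <- samples
    res$design <- build_design(samples)
    log_line("stratify", "%d samples: %d high, %d low, %d excluded",
             nrow(samples), sum(samples$group == "high"),
             sum(samples$group == "low"), sum(samples$group == "excluded"))
  })

  # -- gde
  run_stage("gde", {
    cm <- read_counts_tsv(cfg$counts)
    models <- read_gtf(cfg$gtf)
    gene_chrom <- stats::setNames(models$genes$chrom, models$genes$gene_id)
    tx2gene <- filter_allosomes(cm$tx2gene, gene_chrom,
                                allosomes = cfg$allosomes)
    counts <- cm$counts[tx2gene$transcript_id, , drop = FALSE]
    norm <- normalize_counts(counts)
    tx_res <- test_transcripts(norm$normalized, res$design,
                               base_expression = NULL)
    tx_res$gene_id <- tx2gene$gene_id[match(tx_res$transcript_id,
                                            tx2gene$transcript_id)]
    tx_res$q_value <- bh_adjust(tx_res$p_value)
    gene_res <- aggregate_genes(tx_res, alpha = cfg$alpha,
                                weight_floor = cfg$weight_floor)
    res$models <- models
    res$normalized <- norm$normalized
    res$tx_results <- tx_res
    res$gene_results <- gene_res
    log_line("gde", paste0(
      "%d transcripts tested (%d allosomal removed), %d genes aggregated, ",
      "%d GDE at FDR<%g"),
      nrow(tx_res), attr(tx2gene, "n_removed"), nrow(gene_res),
      sum(gene_res$is_gde), cfg$alpha)
  })

  # -- annotate
  run_stage("annotate", {
    dmrs <- read_bed_dmrs(cfg$dmrs)
    n0 <- nrow(dmrs)
    dmrs <- dmrs[!(dmrs$chrom %in% cfg$allosomes), , drop = FALSE]
    genes <- res$models$genes[!(res$models$genes$chrom %in% cfg$allosomes), ,
                              drop = FALSE]
    links <- annotate_dmrs(dmrs, genes, cfg$annotation)
    res$dmrs <- dmrs
    res$links <- links
    log_line("annotate", "%d DMRs (%d allosomal removed) -> %d gene links",
             nrow(dmrs), n0 - nrow(dmrs), nrow(links))
  })

  # -- integrate
  run_stage("integrate", {
    gde_genes <- res$gene_results$gene_id[res$gene_results$is_gde]
    gdem <- intersect_gdem(gde_genes, res$links)
    tbl <- gdem_table(gdem, res$gene_results, res$tx_results, res$dmrs,
                      alpha = cfg$tx_alpha)
    res$gdem <- gdem
    res$gdem_tbl <- tbl
    log_line("integrate", "%d GDEM genes, %d unique DMRs, %d table rows",
             attr(gdem, "n_unique_genes"), attr(gdem, "n_unique_dmrs"),
             nrow(tbl))
  })

  # -- eqtm
  run_stage("eqtm", {
    eq_cfg <- cfg$eqtm
    eq_cfg$seed <- eq_cfg$seed %||% stage_seed(cfg$seed, "eqtm")
    eq_cfg$allosomes <- cfg$allosomes
    meth <- read_bismark_cov(cov_files)
    res$meth <- meth
    res$eqtm <- eqtm_analysis(res$gdem_tbl, res$dmrs, meth,
                               res$normalized, eq_cfg)
    log_line("eqtm", "%d pairs scored, %d skipped", nrow(res$eqtm),
             attr(res$eqtm, "n_skipped"))
  })

  # -- write outputs last so failures leave no partial tables
  run_stage("write", {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(df, name) {
      p <- file.path(cfg$outdir, name)
      write_result_table(df, p, seed = cfg$seed, config_hash = chash)
      written <<- c(written, p)
      p
    }
    res$paths <- list(
      transcript_results = out(res$tx_results, "transcript_results.tsv"),
      gde_results = out(res$gene_results, "gde_results.tsv"),
      dmr_gene_links = out(res$links, "dmr_gene_links.tsv"),
      gdem_table = out(res$gdem_tbl, "gdem_table.tsv"),
      eqtm_results = out(res$eqtm, "eqtm_results.tsv")
    )
    log_line("write", "5 tables written to %s", cfg$outdir)
  })

  invisible(res)
}
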