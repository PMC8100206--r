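#' Intersect GDE genes with DMR-linked genes into GDEM records
#'
#' A GDEM ("gene displaying both differential expression and methylation")
#' is a gene that passes the gene-level expression FDR call and has at
#' least one annotated DMR. One record is returned per gene in the
#' intersection, carrying the ids of its linked DMRs; the counts of unique
#' genes and unique DMRs are attached as attributes for the run log.
#'
#' @param gde_genes Character vector of GDE gene ids.
#' @param links Link data frame from [annotate_dmrs()] (needs `gene_id` and
#'   `dmr_id`).
#' @return Data frame with `gene_id` and list-column `dmr_ids`; attributes
#'   `"n_unique_genes"` and `"n_unique_dmrs"`.
#' @export
intersect_gdem <- function(gde_genes, links) {
  stopifnot(is.character(gde_genes) || length(gde_genes) == 0L,
            is.data.frame(links))
  genes <- intersect(unique(gde_genes), unique(links$gene_id))
  dmr_ids <- lapply(genes, function(g) unique(links$dmr_id[links$gene_id == g]))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out$dmr_ids <- dmr_ids
  attr(out, "n_unique_genes") <- length(genes)
  attr(out, "n_unique_dmrs") <- length(unique(unlist(dmr_ids)))
  out
}

#' Classify transcript-direction concordance of a GDEM
#'
#' Only transcripts that are individually significant (per-transcript BH
#' q < alpha across all tested transcripts) vote: if the significant
#' transcripts' effect signs include both + and -, the gene's transcripts
#' run in opposite directions (`"opposite"`); otherwise they are
#' `"concordant"`. A gene with no significant transcript is classified
#' concordant with `voted = FALSE`. Setting `voters = "all"` lets every
#' transcript vote regardless of significance.
#'
#' @param effect_stats Numeric vector of signed per-transcript statistics.
#' @param q_values Per-transcript BH q-values (same order).
#' @param alpha Per-transcript significance threshold.
#' @param voters `"significant"` (default) or `"all"`.
#' @return List with `concordance` (`"concordant"`/`"opposite"`) and
#'   `voted` (TRUE if at least one transcript voted).
#' @export
classify_concordance <- function(effect_stats, q_values, alpha = 0.05,
                                 voters = c("significant", "all")) {
  voters <- match.arg(voters)
  stopifnot(length(effect_stats) == length(q_values))
  vote <- if (voters == "all") rep(TRUE, length(effect_stats)) else q_values < alpha
  signs <- unique(sign(effect_stats[vote & effect_stats != 0]))
  list(
    concordance = if (all(c(-1, 1) %in% signs)) "opposite" else "concordant",
    voted = any(vote)
  )
}

#' Build the per-gene GDEM table
#'
#' Combines the GDEM intersection, gene-level aggregation results,
#' transcript statistics and DMR records into one row per
#' gene x DMR x significant transcript, mirroring the published summary
#' table layout (gene, gene-level p, DMR coordinates/statistic/p,
#' transcript id, transcript p, concordance). Exact duplicate rows are
#' removed with a logged count.
#'
#' @param gdem Data frame from [intersect_gdem()].
#' @param gene_results Data frame from [aggregate_genes()].
#' @param tx_results Transcript results with `gene_id`, `transcript_id`,
#'   `effect_stat`, `p_value` and a `q_value` column (BH across
#'   transcripts).
#' @param dmrs DMR record data frame with `dmr_id`, `chrom`, `start`,
#'   `end`, `stat`, `p_value`.
#' @param alpha Per-transcript significance threshold used for concordance
#'   voting and row selection.
#' @param voters Passed to [classify_concordance()].
#' @return Data frame, one row per gene x DMR x significant transcript;
#'   attribute `"concordance"` holds the per-gene classification.
#' @export
gdem_table <- function(gdem, gene_results, tx_results, dmrs, alpha = 0.05,
                       voters = "significant") {
  stopifnot("q_value" %in% names(tx_results))
  conc <- vapply(gdem$gene_id, function(g) {
    sub <- tx_results[tx_results$gene_id == g, , drop = FALSE]
    classify_concordance(sub$effect_stat, sub$q_value, alpha = alpha,
                         voters = voters)$concordance
  }, character(1))
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(gdem))) {
    g <- gdem$gene_id[i]
    gres <- gene_results[gene_results$gene_id == g, , drop = FALSE]
    tx <- tx_results[tx_results$gene_id == g & tx_results$q_value < alpha, ,
                     drop = FALSE]
    if (nrow(tx) == 0L) next
    for (d in gdem$dmr_ids[[i]]) {
      drec <- dmrs[dmrs$dmr_id == d, , drop = FALSE]
      for (t in seq_len(nrow(tx))) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene_id = g,
          gde_p = gres$p_value[1],
          gde_q = gres$q_value[1],
          dmr_id = d,
          dmr = fmt_interval(drec$chrom[1], drec$start[1], drec$end[1]),
          dmr_stat = drec$stat[1],
          dmr_p = drec$p_value[1],
          transcript_id = tx$transcript_id[t],
          dte_stat = tx$effect_stat[t],
          dte_p = tx$p_value[t],
          dte_q = tx$q_value[t],
          concordance = conc[[g]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (k == 0L) {
    data.frame(gene_id = character(0), gde_p = numeric(0), gde_q = numeric(0),
               dmr_id = character(0), dmr = character(0),
               dmr_stat = numeric(0), dmr_p = numeric(0),
               transcript_id = character(0), dte_stat = numeric(0),
               dte_p = numeric(0), dte_q = numeric(0),
               concordance = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  n_before <- nrow(out)
  out <- unique(out)
  rownames(out) <- NULL
  attr(out, "n_duplicates_removed") <- n_before - nrow(out)
  attr(out, "concordance") <- conc
  out
}
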