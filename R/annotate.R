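#' Annotation window configuration
#'
#' Controls how DMRs are linked to genes. The default rule extends the gene
#' body by `upstream_bp` on the promoter side and `downstream_bp` past the
#' gene end (strand-aware: upstream of a minus-strand gene is rightward)
#' and links a DMR when it overlaps the window by at least 1 bp.
#'
#' @param upstream_bp Bases upstream of the gene (default 5000).
#' @param downstream_bp Bases downstream of the gene (default 1000).
#' @param anchor `"body"` (default) anchors the window on the full gene
#'   body; `"tss"` anchors it on the transcription start site only.
#' @param mode `"overlap"` (default) links on any 1-bp overlap;
#'   `"midpoint"` requires the DMR midpoint to fall inside the window.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(upstream_bp = 5000, downstream_bp = 1000,
                              anchor = c("body", "tss"),
                              mode = c("overlap", "midpoint")) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  structure(
    list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
         anchor = match.arg(anchor), mode = match.arg(mode)),
    class = "annotation_config"
  )
}

# Strand-aware eligible window per gene, 1-based inclusive.
gene_windows <- function(genes, cfg) {
  plus <- genes$strand != "-"
  anchor_start <- if (cfg$anchor == "body") genes$gene_start else {
    ifelse(plus, genes$gene_start, genes$gene_end)
  }
  anchor_end <- if (cfg$anchor == "body") genes$gene_end else {
    ifelse(plus, genes$gene_start, genes$gene_end)
  }
  win_start <- ifelse(plus, anchor_start - cfg$upstream_bp,
                      anchor_start - cfg$downstream_bp)
  win_end <- ifelse(plus, anchor_end + cfg$downstream_bp,
                    anchor_end + cfg$upstream_bp)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             win_start = pmax(1, win_start), win_end = win_end,
             stringsAsFactors = FALSE)
}

#' Annotate DMRs to genes by promoter-window overlap
#'
#' Links each differentially methylated region to every gene whose
#' strand-aware eligible window (gene body extended 5 kb upstream and 1 kb
#' downstream by default) it overlaps. A DMR may link to several genes and
#' a gene to several DMRs; no nearest-gene collapsing is performed.
#' Interval arithmetic is delegated to [GenomicRanges::findOverlaps()].
#'
#' @param dmrs Data frame of DMR records with 1-based inclusive `chrom`,
#'   `start`, `end` and (passed through) `dmr_id`, `stat`, `p_value`,
#'   `direction` columns.
#' @param genes Data frame of gene models with `gene_id`, `chrom`, `strand`,
#'   `gene_start`, `gene_end` (1-based inclusive).
#' @param cfg An [annotation_config()].
#' @return Data frame of links: one row per (dmr, gene) pair, carrying the
#'   DMR columns plus `gene_id`. DMRs on chromosomes absent from the gene
#'   models trigger a warning and stay unannotated.
#' @export
annotate_dmrs <- function(dmrs, genes, cfg = annotation_config()) {
  stopifnot(inherits(cfg, "annotation_config"))
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) {
    return(empty_links(dmrs))
  }
  if (any(dmrs$start > dmrs$end)) stop("DMR with start > end")
  unknown <- setdiff(unique(dmrs$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning("DMR chromosome(s) absent from gene models (left unannotated): ",
            paste(unknown, collapse = ", "))
  }
  win <- gene_windows(genes, cfg)
  if (cfg$mode == "midpoint") {
    mid <- floor((as.numeric(dmrs$start) + as.numeric(dmrs$end)) / 2)
    q <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(mid, mid))
  } else {
    q <- GenomicRanges::GRanges(dmrs$chrom,
                                IRanges::IRanges(dmrs$start, dmrs$end))
  }
  s <- GenomicRanges::GRanges(win$chrom,
                              IRanges::IRanges(win$win_start, win$win_end))
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
  out <- cbind(
    dmrs[S4Vectors::queryHits(hits), , drop = FALSE],
    gene_id = win$gene_id[S4Vectors::subjectHits(hits)]
  )
  rownames(out) <- NULL
  out
}

#' Brute-force DMR annotation oracle
#'
#' Pairwise O(n*m) re-implementation of [annotate_dmrs()] with identical
#' window and overlap semantics, written without interval libraries. Used
#' as the independent oracle in tests; not intended for large inputs.
#'
#' @inheritParams annotate_dmrs
#' @return Same shape as [annotate_dmrs()].
#' @export
brute_force_annotate <- function(dmrs, genes, cfg = annotation_config()) {
  stopifnot(inherits(cfg, "annotation_config"))
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) return(empty_links(dmrs))
  win <- gene_windows(genes, cfg)
  if (cfg$mode == "midpoint") {
    qs <- floor((as.numeric(dmrs$start) + as.numeric(dmrs$end)) / 2)
    qe <- qs
  } else {
    qs <- dmrs$start
    qe <- dmrs$end
  }
  # exhaustive comparison of every (dmr, gene) pair
  qi <- rep(seq_len(nrow(dmrs)), times = nrow(win))
  sj <- rep(seq_len(nrow(win)), each = nrow(dmrs))
  hit <- dmrs$chrom[qi] == win$chrom[sj] &
    qs[qi] <= win$win_end[sj] & qe[qi] >= win$win_start[sj]
  if (!any(hit)) return(empty_links(dmrs))
  out <- cbind(dmrs[qi[hit], , drop = FALSE], gene_id = win$gene_id[sj[hit]])
  out <- out[order(qi[hit], sj[hit]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_links <- function(dmrs) {
  out <- cbind(dmrs[integer(0), , drop = FALSE],
               gene_id = character(0))
  rownames(out) <- NULL
  out
}
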