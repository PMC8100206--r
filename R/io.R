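#' Read a sample metadata table
#'
#' Tab-separated, UTF-8, header required; columns `sample_id`, `sjc66`,
#' `sex`, `age`, `dmard_use` (logical), optionally `joint_source` and
#' `cohort_label`.
#'
#' @param path Path to samples.tsv.
#' @return Data frame of sample records.
#' @export
read_samples_tsv <- function(path) {
  if (!file.exists(path)) stop("samples file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "sjc66", "sex", "age", "dmard_use")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("samples.tsv missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$dmard_use <- as.logical(df$dmard_use)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  df
}

#' Write a sample metadata table
#' @param samples Data frame of sample records.
#' @param path Output path.
#' @export
write_samples_tsv <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read Bismark-style coverage files into a methylation matrix
#'
#' Each file holds one sample: tab-separated `chrom`, `start` (1-based),
#' `end` (= start), `%methylation`, `count_methylated`,
#' `count_unmethylated`, no header. CpG positions absent from a sample get
#' zero coverage.
#'
#' @param files Character vector of file paths.
#' @param sample_names Sample names (default: file base names without
#'   `.cov`).
#' @return A [meth_matrix()].
#' @export
read_bismark_cov <- function(files, sample_names = NULL) {
  if (is.null(sample_names)) {
    sample_names <- sub("\\.cov$", "", basename(files))
  }
  stopifnot(length(files) == length(sample_names))
  per <- lapply(seq_along(files), function(i) {
    f <- files[i]
    if (!file.exists(f)) stop("coverage file not found: ", f)
    df <- as.data.frame(data.table::fread(
      f, header = FALSE, sep = "\t",
      col.names = c("chrom", "start", "end", "pct", "meth", "unmeth")))
    if (nrow(df) > 0 && any(df$start != df$end)) {
      bad <- which(df$start != df$end)[1]
      stop("malformed coverage record at ", f, ":", bad,
           " (start != end for a CpG)")
    }
    df
  })
  all <- data.table::rbindlist(per, idcol = "sample_i")
  key <- unique(all[, c("chrom", "start")])
  data.table::setorder(key, chrom, start)
  key$row <- seq_len(nrow(key))
  all <- key[all, on = c("chrom", "start")]
  meth <- matrix(0L, nrow(key), length(files),
                 dimnames = list(NULL, sample_names))
  total <- meth
  meth[cbind(all$row, all$sample_i)] <- as.integer(all$meth)
  total[cbind(all$row, all$sample_i)] <- as.integer(all$meth + all$unmeth)
  meth_matrix(key$chrom, key$start, meth, total)
}

#' Write Bismark-style coverage files, one per sample
#'
#' @param meth A [meth_matrix()].
#' @param dir Output directory; files are named `<sample>.cov`.
#' @return Invisibly, the written paths.
#' @export
write_bismark_cov <- function(meth, dir) {
  stopifnot(inherits(meth, "meth_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(meth$samples), function(i) {
    covered <- meth$total[, i] > 0
    m <- meth$meth[covered, i]
    t <- meth$total[covered, i]
    df <- data.frame(
      chrom = meth$chrom[covered],
      start = meth$pos[covered],
      end = meth$pos[covered],
      pct = round(100 * m / t, 6),
      meth = m,
      unmeth = t - m
    )
    p <- file.path(dir, paste0(meth$samples[i], ".cov"))
    data.table::fwrite(df, p, sep = "\t", col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read gene models from a GENCODE-dialect GTF
#'
#' Parses `gene` and `transcript` features (via [rtracklayer::import()])
#' into the package's gene-model tables.
#'
#' @param path GTF path.
#' @return List of class `gene_models` with data frames `genes`
#'   (`gene_id`, `chrom`, `strand`, `gene_start`, `gene_end`) and
#'   `transcripts` (`transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`), both sorted by id.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  g <- gr[type == "gene"]
  t <- gr[type == "transcript"]
  genes <- data.frame(
    gene_id = g$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    strand = as.character(BiocGenerics::strand(g)),
    gene_start = BiocGenerics::start(g),
    gene_end = BiocGenerics::end(g),
    stringsAsFactors = FALSE
  )
  transcripts <- data.frame(
    transcript_id = t$transcript_id,
    gene_id = t$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(t)),
    strand = as.character(BiocGenerics::strand(t)),
    tx_start = BiocGenerics::start(t),
    tx_end = BiocGenerics::end(t),
    stringsAsFactors = FALSE
  )
  gene_models(genes, transcripts)
}

#' Construct a gene-model set
#'
#' @param genes,transcripts Data frames as documented in [read_gtf()].
#' @return List of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts) {
  stopifnot(all(c("gene_id", "chrom", "strand", "gene_start",
                  "gene_end") %in% names(genes)),
            all(c("transcript_id", "gene_id", "chrom", "strand", "tx_start",
                  "tx_end") %in% names(transcripts)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript_id")
  gs <- genes$gene_start[match(transcripts$gene_id, genes$gene_id)]
  ge <- genes$gene_end[match(transcripts$gene_id, genes$gene_id)]
  if (any(transcripts$tx_start < gs | transcripts$tx_end > ge)) {
    stop("transcript outside its gene bounds")
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  transcripts <- transcripts[order(transcripts$transcript_id), , drop = FALSE]
  rownames(genes) <- rownames(transcripts) <- NULL
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write gene models to a GENCODE-dialect GTF
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  t <- models$transcripts
  lines <- c(
    sprintf('%s\teqtmpipe\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
            g$chrom, g$gene_start, g$gene_end, g$strand, g$gene_id),
    sprintf(paste0('%s\teqtmpipe\ttranscript\t%d\t%d\t.\t%s\t.\t',
                   'gene_id "%s"; transcript_id "%s";'),
            t$chrom, t$tx_start, t$tx_end, t$strand, t$gene_id,
            t$transcript_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read DMR calls from a BED6+2 file
#'
#' Columns: chrom, start (0-based), end, name, score (region statistic),
#' strand, p_value, direction. Coordinates are converted to 1-based
#' inclusive on read.
#'
#' @param path BED path.
#' @return Data frame with `dmr_id`, `chrom`, `start`, `end`, `stat`,
#'   `p_value`, `direction`.
#' @export
read_bed_dmrs <- function(path) {
  if (!file.exists(path)) stop("DMR BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(p_value = "numeric",
                                          direction = "character"))
  df <- data.frame(
    dmr_id = gr$name,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),   # rtracklayer converts to 1-based
    end = BiocGenerics::end(gr),
    stat = gr$score,
    p_value = gr$p_value,
    direction = gr$direction,
    stringsAsFactors = FALSE
  )
  bad <- df$direction != ifelse(df$stat >= 0, "hyper", "hypo")
  if (any(bad)) {
    stop("DMR direction inconsistent with statistic sign at ", path,
         " row(s): ", paste(which(bad), collapse = ", "))
  }
  df
}

#' Write DMR calls to a BED6+2 file
#'
#' @param dmrs Data frame as returned by [read_bed_dmrs()] (1-based
#'   inclusive coordinates; converted to BED on write).
#' @param path Output path.
#' @export
write_bed_dmrs <- function(dmrs, path) {
  df <- data.frame(
    chrom = dmrs$chrom,
    start0 = as.integer(dmrs$start) - 1L,
    end = as.integer(dmrs$end),
    name = dmrs$dmr_id,
    score = dmrs$stat,
    strand = ".",
    p_value = dmrs$p_value,
    direction = dmrs$direction
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transcript x sample count matrix
#'
#' Tab-separated with header: `transcript_id`, `gene_id`, then one column
#' per sample.
#'
#' @param path counts.tsv path.
#' @return List with integer matrix `counts` (rownames = transcript ids)
#'   and data frame `tx2gene`.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(df))) {
    stop("counts.tsv must start with transcript_id and gene_id columns")
  }
  m <- as.matrix(df[, setdiff(names(df), c("transcript_id", "gene_id")),
                    drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$transcript_id
  if (any(m < 0)) stop("negative counts in ", path)
  list(counts = m,
       tx2gene = df[, c("transcript_id", "gene_id"), drop = FALSE])
}

#' Write a transcript x sample count matrix
#'
#' @param counts Integer matrix with transcript rownames.
#' @param tx2gene Data frame with `transcript_id`, `gene_id`.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, tx2gene, path) {
  stopifnot(identical(rownames(counts), tx2gene$transcript_id))
  df <- cbind(tx2gene, as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table with a provenance header
#'
#' Prepends a single comment line with the package version, seed and
#' config hash (no timestamp, so identical runs are byte-identical).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the provenance line.
#' @param config_hash Config hash recorded in the provenance line.
#' @export
write_result_table <- function(df, path, seed = NA, config_hash = "") {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eqtmpipe %s seed=%s config=%s",
                     as.character(utils::packageVersion("eqtmpipe")),
                     seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic short hash of a configuration object (md5 of its
# serialized YAML form).
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 10)
}
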