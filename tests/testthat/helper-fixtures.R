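# Shared fixtures, built in code at test time.

# A balanced mini-cohort with both sexes in each group.
make_cohort_df <- function(n_high = 5, n_low = 5, n_zero = 0) {
  n <- n_high + n_low + n_zero
  data.frame(
    sample_id = sprintf("T%02d", seq_len(n)),
    sjc66 = c(rep(12, n_high), rep(4, n_low), rep(0, n_zero)),
    sex = rep(c("male", "female"), length.out = n),
    age = seq(30, 60, length.out = n),
    dmard_use = rep(c(TRUE, TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE
  )
}

# A small, fast simulation configuration used across tests where the full
# default study would be wasteful.
small_sim_cfg <- function(seed = 7, ...) {
  sim_config(n_genes = 40, n_cpgs = 20000, n_gde = 12, n_dmr = 14,
             n_gdem = 8, n_discordant = 2, transcripts_per_gene = c(1, 3),
             seed = seed, ...)
}

# Random annotation instance generator for oracle-equivalence checks;
# includes exact boundary-touching intervals by construction.
random_annotation_instance <- function(n_dmr, n_gene, seed) {
  set.seed(seed)
  chroms <- c("c1", "c2", "c3")
  gs <- sample(1e4:5e5, n_gene)
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n_gene)),
    chrom = sample(chroms, n_gene, replace = TRUE),
    strand = sample(c("+", "-"), n_gene, replace = TRUE),
    gene_start = gs,
    gene_end = gs + sample(100:50000, n_gene),
    stringsAsFactors = FALSE
  )
  ds <- sample(1e4:6e5, n_dmr)
  dmrs <- data.frame(
    dmr_id = sprintf("D%03d", seq_len(n_dmr)),
    chrom = sample(chroms, n_dmr, replace = TRUE),
    start = ds,
    end = ds + sample(50:20000, n_dmr),
    stat = round(rnorm(n_dmr, 0, 10), 2),
    p_value = runif(n_dmr),
    stringsAsFactors = FALSE
  )
  dmrs$direction <- ifelse(dmrs$stat >= 0, "hyper", "hypo")
  # force a few exact boundary cases: DMR end == window start, etc.
  if (n_dmr >= 4 && n_gene >= 2) {
    g <- genes[1, ]
    up <- if (g$strand == "+") 5000 else 1000
    dmrs$chrom[1] <- g$chrom
    dmrs$start[1] <- g$gene_start - up - 200
    dmrs$end[1] <- g$gene_start - up          # touches window edge
    dmrs$chrom[2] <- g$chrom
    dmrs$start[2] <- g$gene_start - up - 200
    dmrs$end[2] <- g$gene_start - up - 1      # one bp outside
  }
  list(dmrs = dmrs, genes = genes)
}

links_key <- function(links) {
  sort(paste(links$dmr_id, links$gene_id))
}

hash_file <- function(p) unname(tools::md5sum(p))
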