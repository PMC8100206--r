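test_that("cohort generation respects strata, sizes and determinism", {
  cfg <- sim_config(n_high = 5, n_low = 5, n_zero = 2, seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 12)
  expect_equal(sum(co$sjc66 >= 9), 5)
  expect_equal(sum(co$sjc66 >= 1 & co$sjc66 <= 8), 5)
  expect_equal(sum(co$sjc66 == 0), 2)

  co17 <- simulate_cohort(sim_config(n_high = 9, n_low = 8, n_zero = 0,
                                     seed = 7))
  expect_equal(nrow(co17), 17)

  # determinism: same config, same seed, called twice
  expect_identical(co, simulate_cohort(cfg))
  expect_error(sim_config(n_high = 0, n_low = 5), "positive")
  expect_error(sim_config(n_high = 2, n_low = 1), "at least 4")
})

test_that("config validation guards ranges", {
  expect_error(sim_config(eqtm_rho = 1.5), "eqtm_rho")
  expect_error(sim_config(dmr_effect = 120), "dmr_effect")
  expect_error(sim_config(n_gdem = 50, n_gde = 30, n_dmr = 40), "n_gdem")
})

test_that("gene models are well-formed and GTF round-trips", {
  cfg <- sim_config(n_genes = 10, n_gde = 3, n_dmr = 4, n_gdem = 2,
                    n_discordant = 1, seed = 3)
  gm <- simulate_gene_models(cfg)
  expect_equal(nrow(gm$genes), 10)
  expect_true(all(table(gm$transcripts$gene_id) >= 1))
  # transcripts inside gene bounds (also enforced by the constructor)
  gs <- gm$genes[match(gm$transcripts$gene_id, gm$genes$gene_id), ]
  expect_true(all(gm$transcripts$tx_start >= gs$gene_start))
  expect_true(all(gm$transcripts$tx_end <= gs$gene_end))
  expect_true(all(gm$genes$gene_end - gm$genes$gene_start + 1 <= 50000))

  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm, p)
  expect_identical(read_gtf(p)$genes, gm$genes)
  expect_identical(read_gtf(p)$transcripts, gm$transcripts)
})

test_that("methylome counts are consistent and null effects vanish", {
  cfg <- small_sim_cfg(seed = 5, dmr_effect = 0)
  co <- simulate_cohort(cfg)
  gm <- simulate_gene_models(cfg)
  my <- simulate_methylome(co, gm, cfg)
  expect_true(all(my$meth$meth <= my$meth$total))
  expect_true(all(my$meth$meth >= 0))

  # with zero planted effect the group difference over planted regions is
  # within binomial noise of zero
  high <- co$sample_id[co$sjc66 >= 9]
  low <- co$sample_id[co$sjc66 >= 1 & co$sjc66 <= 8]
  diffs <- vapply(seq_len(nrow(my$dmrs)), function(i) {
    d <- my$dmrs[i, ]
    m <- median_methylation(d$chrom, d$start, d$end, my$meth)
    mean(m[high]) - mean(m[low])
  }, numeric(1))
  expect_lt(max(abs(diffs)), 6)
  expect_lt(abs(mean(diffs)), 2)
})

test_that("planted methylation shifts are recovered at the configured size", {
  cfg <- small_sim_cfg(seed = 6, dmr_effect = 30, coverage_mean = 30,
                       dmr_len = c(20, 20))
  co <- simulate_cohort(cfg)
  gm <- simulate_gene_models(cfg)
  my <- simulate_methylome(co, gm, cfg)
  high <- co$sample_id[co$sjc66 >= 9]
  low <- co$sample_id[co$sjc66 >= 1 & co$sjc66 <= 8]
  diffs <- vapply(seq_len(nrow(my$dmrs)), function(i) {
    d <- my$dmrs[i, ]
    m <- median_methylation(d$chrom, d$start, d$end, my$meth)
    (mean(m[high]) - mean(m[low])) * d$sign
  }, numeric(1))
  expect_true(all(abs(diffs - 30) < 5))
  # direction field is consistent with the planted sign
  expect_equal(my$dmrs$direction, ifelse(my$dmrs$sign > 0, "hyper", "hypo"))
})

test_that("planted truth is internally consistent and recoverable", {
  cfg <- small_sim_cfg(seed = 9)
  co <- simulate_cohort(cfg)
  gm <- simulate_gene_models(cfg)
  my <- simulate_methylome(co, gm, cfg)
  ex <- simulate_transcript_counts(co, gm, my, cfg)
  truth <- ex$truth

  expect_true(all(!truth$is_gdem | (truth$is_gde & truth$has_dmr)))
  expect_equal(sum(truth$is_gdem), cfg$n_gdem)
  expect_equal(sum(truth$is_gde), cfg$n_gde)
  expect_equal(nrow(my$dmrs), cfg$n_dmr)

  # every planted DMR maps to >= 1 gene under the annotation rule
  links <- brute_force_annotate(my$dmrs, gm$genes, annotation_config())
  expect_true(all(my$dmrs$dmr_id %in% links$dmr_id))
  # and in particular to its own target gene
  own <- paste(my$dmrs$dmr_id, my$dmrs$gene_id) %in%
    paste(links$dmr_id, links$gene_id)
  expect_true(all(own))

  # counts are non-negative integers
  expect_true(all(ex$counts >= 0))
  expect_true(is.integer(ex$counts) || all(ex$counts == round(ex$counts)))

  # discordant genes carry planted effects of both signs; concordant GDEMs
  # do not
  for (g in truth$gene_id[truth$is_gdem]) {
    s <- ex$truth_tx$lfc[ex$truth_tx$gene_id == g]
    signs <- unique(sign(s[!is.na(s) & s != 0]))
    if (truth$discordant[truth$gene_id == g]) {
      expect_true(all(c(-1, 1) %in% signs))
    } else {
      expect_lte(length(signs), 1)
    }
  }
  # every eQTM pair points at a gene with a planted DMR
  expect_true(all(ex$truth_pairs$gene_id %in%
                    truth$gene_id[truth$has_dmr]))
})

test_that("a full synthetic study is byte-identical under a fixed seed", {
  cfg <- small_sim_cfg(seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(hash_file(file.path(d1, f)), hash_file(file.path(d2, f)),
                     info = f)
  }
  # different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_study(small_sim_cfg(seed = 5), d3)
  expect_false(identical(hash_file(file.path(d1, "counts.tsv")),
                         hash_file(file.path(d3, "counts.tsv"))))
})
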