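#' Simulation configuration for a synthetic methylation-expression study
#'
#' Defines the miniature study emulated by the generator: a 17-sample
#' cohort in two SJC66 strata (with a deliberate sex confound), gene models
#' on synthetic chromosomes, a CpG methylome with planted differentially
#' methylated regions (runs of consecutive CpGs shifted between groups),
#' negative-binomial transcript counts with planted fold changes (including
#' genes whose transcripts move in opposite directions), and planted
#' monotone methylation-expression coupling for a subset of gene/DMR pairs.
#'
#' @param n_high,n_low,n_zero Samples per SJC66 stratum (high >= 9,
#'   low 1-8, zero exactly 0).
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Length-2 range of transcripts per gene.
#' @param n_cpgs Number of background CpGs genome-wide (promoter CpG
#'   clusters of ~60 CpGs per gene are added on top).
#' @param cpg_spacing_bp Mean inter-CpG distance of the background CpGs.
#' @param dmr_effect Planted between-group methylation difference in
#'   percentage points (0-100).
#' @param expr_lfc Planted absolute log2 fold change for differentially
#'   expressed transcripts.
#' @param eqtm_rho Target magnitude of the planted methylation-expression
#'   correlation (0-1).
#' @param coverage_mean Mean WGBS read depth per CpG (Poisson).
#' @param dispersion Negative-binomial dispersion of the counts.
#' @param n_gde Genes planted as differentially expressed.
#' @param n_dmr Planted DMRs (one per target gene).
#' @param n_gdem Genes planted as both (subset of the GDE and DMR targets).
#' @param n_discordant GDEM genes whose transcripts get opposite planted
#'   directions.
#' @param sex_confound Fraction of high-group samples assigned male (and of
#'   low-group samples assigned female); 0.5 removes the confound.
#' @param dmr_len Length-2 range of planted DMR lengths in consecutive
#'   CpGs.
#' @param coupling_sd Log2-scale SD of the latent expression component
#'   driven by regional methylation for eQTM-linked transcripts.
#' @param seed Integer seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_high = 9, n_low = 8, n_zero = 0,
                       n_genes = 100, transcripts_per_gene = c(1, 5),
                       n_cpgs = 100000, cpg_spacing_bp = 300,
                       dmr_effect = 30, expr_lfc = 2, eqtm_rho = 0.9,
                       coverage_mean = 30, dispersion = 0.05,
                       n_gde = 30, n_dmr = 40, n_gdem = 20,
                       n_discordant = 4, sex_confound = 0.75,
                       dmr_len = c(10, 50), coupling_sd = 1.5, seed = 1) {
  cfg <- list(
    n_high = n_high, n_low = n_low, n_zero = n_zero, n_genes = n_genes,
    transcripts_per_gene = transcripts_per_gene, n_cpgs = n_cpgs,
    cpg_spacing_bp = cpg_spacing_bp, dmr_effect = dmr_effect,
    expr_lfc = expr_lfc, eqtm_rho = eqtm_rho,
    coverage_mean = coverage_mean, dispersion = dispersion,
    n_gde = n_gde, n_dmr = n_dmr, n_gdem = n_gdem,
    n_discordant = n_discordant, sex_confound = sex_confound,
    dmr_len = dmr_len, coupling_sd = coupling_sd, seed = seed
  )
  counts <- c("n_high", "n_low", "n_zero", "n_genes", "n_cpgs", "n_gde",
              "n_dmr", "n_gdem", "n_discordant")
  for (f in counts) {
    if (cfg[[f]] < 0) stop(f, " must be non-negative")
  }
  if (n_high <= 0 || n_low <= 0) stop("group sizes n_high and n_low must be positive")
  if (n_high + n_low < 4) stop("need at least 4 samples across the two SJC66 groups")
  if (eqtm_rho < 0 || eqtm_rho > 1) stop("eqtm_rho must lie in [0, 1]")
  if (dmr_effect < 0 || dmr_effect > 100) {
    stop("dmr_effect must lie in [0, 100] percentage points")
  }
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_gdem > min(n_gde, n_dmr)) stop("n_gdem cannot exceed min(n_gde, n_dmr)")
  if (n_discordant > n_gdem) stop("n_discordant cannot exceed n_gdem")
  if (n_gde + (n_dmr - n_gdem) > n_genes) {
    stop("not enough genes for the requested GDE/DMR targets")
  }
  if (length(transcripts_per_gene) != 2L ||
      transcripts_per_gene[1] < 1 ||
      transcripts_per_gene[1] > transcripts_per_gene[2]) {
    stop("transcripts_per_gene must be an increasing range of length 2")
  }
  if (length(dmr_len) != 2L || dmr_len[1] < 2 || dmr_len[1] > dmr_len[2]) {
    stop("dmr_len must be an increasing range of length 2 with minimum >= 2")
  }
  structure(cfg, class = "sim_config")
}

#' Generate the synthetic cohort metadata
#'
#' SJC66 is drawn in 9-20 for the high stratum, 1-8 for the low stratum and
#' set to 0 for the zero stratum. Sex is assigned with a configurable
#' confounding rate (by default 75% of high-group samples are male and 75%
#' of low-group samples female), mirroring a sex-confounded clinical
#' cohort so that covariate-adjustment code paths are exercised. Age is
#' uniform in 25-70 years and DMARD use Bernoulli(0.5).
#'
#' @param cfg A [sim_config()].
#' @return Data frame of sample records (`sample_id`, `sjc66`, `sex`,
#'   `age`, `dmard_use`, `joint_source`, `cohort_label`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg$seed, "cohort"), {
    n <- cfg$n_high + cfg$n_low + cfg$n_zero
    stratum <- rep(c("high", "low", "zero"),
                   c(cfg$n_high, cfg$n_low, cfg$n_zero))
    sjc66 <- integer(n)
    sjc66[stratum == "high"] <- sample(9:20, cfg$n_high, replace = TRUE)
    sjc66[stratum == "low"] <- sample(1:8, cfg$n_low, replace = TRUE)
    sex <- character(n)
    sex[stratum == "high"] <- ifelse(
      stats::runif(cfg$n_high) < cfg$sex_confound, "male", "female")
    sex[stratum == "low"] <- ifelse(
      stats::runif(cfg$n_low) < cfg$sex_confound, "female", "male")
    sex[stratum == "zero"] <- sample(c("male", "female"), cfg$n_zero,
                                     replace = TRUE)
    data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      sjc66 = sjc66,
      sex = sex,
      age = round(stats::runif(n, 25, 70), 1),
      dmard_use = stats::rbinom(n, 1, 0.5) == 1,
      joint_source = sample(c("knee", "ankle"), n, replace = TRUE,
                            prob = c(0.85, 0.15)),
      cohort_label = sample(c("pre-synoviomics", "synoviomics",
                              "synoviomics-II"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic gene models
#'
#' Places genes sequentially on synthetic chromosomes (`chrS1`, `chrS2`,
#' ..., one per ~100 genes; synthetic names avoid collision with real
#' genomes), with lengths 1-50 kb, random strand and 1-5 transcripts each
#' sharing the gene's TSS region.
#'
#' @param cfg A [sim_config()].
#' @return A [gene_models()] object.
#' @export
simulate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg$seed, "genes"), {
    n <- cfg$n_genes
    n_chrom <- ceiling(n / 100)
    chrom_of <- sprintf("chrS%d", ((seq_len(n) - 1L) %% n_chrom) + 1L)
    glist <- vector("list", n)
    tlist <- vector("list", n)
    cursor <- stats::setNames(rep(20000L, n_chrom),
                              sprintf("chrS%d", seq_len(n_chrom)))
    for (i in seq_len(n)) {
      chr <- chrom_of[i]
      len <- as.integer(round(stats::runif(1, 1000, 50000)))
      gstart <- cursor[[chr]]
      gend <- gstart + len - 1L
      cursor[[chr]] <- gend + as.integer(round(stats::runif(1, 8000, 20000)))
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("SGENE%04d", i)
      k <- sample(cfg$transcripts_per_gene[1]:cfg$transcripts_per_gene[2], 1)
      # transcripts anchored near the TSS end of the gene
      if (strand == "+") {
        ts <- gstart + as.integer(round(stats::runif(k, 0, min(200, len / 10))))
        te <- pmin(gend, ts + as.integer(round(stats::runif(k, 0.4, 1) * len)))
      } else {
        te <- gend - as.integer(round(stats::runif(k, 0, min(200, len / 10))))
        ts <- pmax(gstart, te - as.integer(round(stats::runif(k, 0.4, 1) * len)))
      }
      glist[[i]] <- data.frame(
        gene_id = gid, chrom = chr, strand = strand,
        gene_start = gstart, gene_end = gend, stringsAsFactors = FALSE
      )
      tlist[[i]] <- data.frame(
        transcript_id = sprintf("%s.t%d", gid, seq_len(k)),
        gene_id = gid, chrom = chr, strand = strand,
        tx_start = ts, tx_end = pmax(ts, te), stringsAsFactors = FALSE
      )
    }
    gene_models(do.call(rbind, glist), do.call(rbind, tlist))
  })
}

# Assign planted roles to genes: which are GDE, which carry a DMR, which
# are both (GDEM), and which GDEMs get discordant transcript directions.
# Discordant genes need >= 2 transcripts.
plan_truth <- function(cfg, models) {
  with_seed(stage_seed(cfg$seed, "plan"), {
    genes <- models$genes$gene_id
    n_tx <- table(models$transcripts$gene_id)[genes]
    multi <- genes[n_tx >= 2]
    if (length(multi) < cfg$n_discordant) {
      stop("not enough multi-transcript genes for the requested discordant set")
    }
    discordant <- sample(multi, cfg$n_discordant)
    gdem_rest <- sample(setdiff(genes, discordant),
                        cfg$n_gdem - cfg$n_discordant)
    gdem <- c(discordant, gdem_rest)
    gde_only <- sample(setdiff(genes, gdem), cfg$n_gde - cfg$n_gdem)
    dmr_only <- sample(setdiff(genes, c(gdem, gde_only)),
                       cfg$n_dmr - cfg$n_gdem)
    truth <- data.frame(
      gene_id = genes,
      is_gde = genes %in% c(gdem, gde_only),
      has_dmr = genes %in% c(gdem, dmr_only),
      is_gdem = genes %in% gdem,
      discordant = genes %in% discordant,
      stringsAsFactors = FALSE
    )
    stopifnot(all(!truth$is_gdem | (truth$is_gde & truth$has_dmr)))
    truth
  })
}

#' Generate the synthetic methylome with planted DMRs
#'
#' Every gene gets a promoter CpG cluster (~60 CpGs spanning TSS +/- 1 kb)
#' on top of `n_cpgs` background CpGs with exponential spacing. Baseline
#' per-CpG methylation comes from a bimodal beta mixture (background) or a
#' low-methylation beta (promoter clusters). For each planted DMR, a run
#' of consecutive CpGs in the target gene's promoter cluster is shifted by
#' +/- `dmr_effect` percentage points in the high-SJC66 group (both
#' directions planted, hypomethylation more frequent). Read counts are
#' binomial given a Poisson depth per CpG. Every planted DMR is verified
#' to overlap its gene's annotation window so the truth is recoverable.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param models A [gene_models()] object.
#' @param cfg A [sim_config()].
#' @return List with `meth` (a [meth_matrix()]), `dmrs` (DMR records:
#'   `dmr_id`, `chrom`, `start`, `end`, `stat`, `p_value`, `direction`,
#'   `gene_id`, `sign`, `L`) and `truth` (per-gene role flags from the
#'   planner).
#' @export
simulate_methylome <- function(cohort, models, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(models, "gene_models"))
  truth <- plan_truth(cfg, models)
  with_seed(stage_seed(cfg$seed, "methylome"), {
    g <- models$genes
    tss <- ifelse(g$strand == "+", g$gene_start, g$gene_end)
    # promoter clusters
    clus <- lapply(seq_len(nrow(g)), function(i) {
      p <- as.integer(round(seq(tss[i] - 1000, tss[i] + 1000,
                                length.out = 60) +
                              stats::runif(60, -10, 10)))
      data.frame(chrom = g$chrom[i], pos = pmax(1L, p), promoter = TRUE,
                 stringsAsFactors = FALSE)
    })
    # background CpGs per chromosome, exponential gaps
    spans <- tapply(g$gene_end, g$chrom, max) + 10000
    n_bg <- round(cfg$n_cpgs * spans / sum(spans))
    bg <- lapply(names(spans), function(chr) {
      k <- n_bg[[chr]]
      if (k < 1) return(NULL)
      gaps <- 1 + stats::rexp(k, 1 / cfg$cpg_spacing_bp)
      data.frame(chrom = chr, pos = as.integer(cumsum(gaps)),
                 promoter = FALSE, stringsAsFactors = FALSE)
    })
    cpgs <- rbind(do.call(rbind, clus), do.call(rbind, bg))
    cpgs <- cpgs[!duplicated(cpgs[, c("chrom", "pos")]), , drop = FALSE]
    cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
    n_cpg <- nrow(cpgs)

    # baseline methylation: bimodal background, hypomethylated promoters
    lowcomp <- stats::runif(n_cpg) < 0.4
    baseline <- ifelse(lowcomp, stats::rbeta(n_cpg, 1.5, 6),
                       stats::rbeta(n_cpg, 6, 1.5))
    baseline[cpgs$promoter] <- stats::rbeta(sum(cpgs$promoter), 1.5, 8)

    # plant DMRs in promoter clusters of the target genes
    target_genes <- truth$gene_id[truth$has_dmr]
    shift <- numeric(n_cpg)
    dmr_rows <- vector("list", length(target_genes))
    for (j in seq_along(target_genes)) {
      gid <- target_genes[j]
      gi <- which(g$gene_id == gid)
      in_clus <- which(cpgs$chrom == g$chrom[gi] & cpgs$promoter &
                         abs(cpgs$pos - tss[gi]) <= 1100)
      L_want <- sample(cfg$dmr_len[1]:cfg$dmr_len[2], 1)
      L_want <- min(L_want, length(in_clus))
      s0 <- sample(seq_len(length(in_clus) - L_want + 1L), 1)
      run <- in_clus[s0:(s0 + L_want - 1L)]
      start <- min(cpgs$pos[run])
      end <- max(cpgs$pos[run])
      # the region covers every CpG inside the interval, incl. background
      region <- which(cpgs$chrom == g$chrom[gi] & cpgs$pos >= start &
                        cpgs$pos <= end)
      sgn <- if (stats::runif(1) < 0.6) -1 else 1   # hypo more frequent
      baseline[region] <- pmin(0.97, pmax(0.03,
        stats::runif(1, 0.35, 0.6) + stats::rnorm(length(region), 0, 0.02)))
      shift[region] <- sgn * cfg$dmr_effect / 100
      dmr_rows[[j]] <- data.frame(
        dmr_id = sprintf("DMR%03d", j),
        chrom = g$chrom[gi], start = start, end = end,
        stat = round(sgn * stats::runif(1, 8, 15), 2),
        p_value = signif(stats::runif(1, 1e-5, 1e-3), 3),
        direction = if (sgn > 0) "hyper" else "hypo",
        gene_id = gid, sign = sgn, L = length(region),
        stringsAsFactors = FALSE
      )
    }
    dmrs <- if (length(dmr_rows)) do.call(rbind, dmr_rows) else
      data.frame(dmr_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), stat = numeric(0),
                 p_value = numeric(0), direction = character(0),
                 gene_id = character(0), sign = numeric(0), L = integer(0),
                 stringsAsFactors = FALSE)

    # recoverability: each planted DMR must overlap its gene's window
    if (nrow(dmrs)) {
      links <- brute_force_annotate(dmrs, g, annotation_config())
      ok <- mapply(function(d, gid) {
        any(links$dmr_id == d & links$gene_id == gid)
      }, dmrs$dmr_id, dmrs$gene_id)
      if (!all(ok)) {
        stop("planted DMR outside every annotation window: ",
             paste(dmrs$dmr_id[!ok], collapse = ", "))
      }
    }

    # per-sample methylation probabilities and binomial counts
    n_s <- nrow(cohort)
    high <- cohort$sjc66 >= 9
    meth <- matrix(0L, n_cpg, n_s, dimnames = list(NULL, cohort$sample_id))
    total <- meth
    for (s in seq_len(n_s)) {
      p <- baseline + if (high[s]) shift else 0
      p <- pmin(0.99, pmax(0.01, p + stats::rnorm(n_cpg, 0, 0.02)))
      depth <- stats::rpois(n_cpg, cfg$coverage_mean)
      total[, s] <- depth
      meth[, s] <- stats::rbinom(n_cpg, depth, p)
    }
    list(meth = meth_matrix(cpgs$chrom, cpgs$pos, meth, total),
         dmrs = dmrs, truth = truth)
  })
}

#' Generate synthetic transcript counts with planted effects
#'
#' Negative-binomial counts with gene-level baselines and per-sample
#' library-size factors. Planted GDE transcripts receive +/- `expr_lfc`;
#' discordant GDEM genes get transcripts of both signs. For each GDEM
#' gene, one designated transcript is coupled to the sample's median
#' planted-DMR methylation through a Gaussian-copula-style latent link, so
#' that the realized Pearson correlation has magnitude ~ `eqtm_rho` with
#' sign opposite to promoter methylation (the default repressive
#' direction).
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param models A [gene_models()] object.
#' @param methylome List from [simulate_methylome()].
#' @param cfg A [sim_config()].
#' @return List with `counts` (integer matrix), `tx2gene`, `truth_tx`
#'   (per-transcript planted lfc), `truth_pairs` (planted eQTM links:
#'   `gene_id`, `dmr_id`, `transcript_id`, `rho`, `sign`) and `truth`
#'   (gene roles).
#' @export
simulate_transcript_counts <- function(cohort, models, methylome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- methylome$truth
  dmrs <- methylome$dmrs
  with_seed(stage_seed(cfg$seed, "counts"), {
    tx <- models$transcripts
    n_s <- nrow(cohort)
    high <- as.numeric(cohort$sjc66 >= 9)
    base_g <- stats::setNames(stats::runif(nrow(models$genes), 3, 9),
                              models$genes$gene_id)
    b_t <- base_g[tx$gene_id] + stats::runif(nrow(tx), -1, 1)
    libfac <- exp(stats::rnorm(n_s, 0, 0.15))

    lfc <- numeric(nrow(tx))          # directly planted group lfc
    implied <- rep(NA_real_, nrow(tx))  # lfc implied by the coupling
    log2mu <- matrix(rep(b_t, n_s), nrow(tx), n_s)
    pairs <- list()
    couple_sign <- -1   # repressive: expression anti-correlates with methylation

    for (gid in truth$gene_id[truth$is_gde]) {
      idx <- which(tx$gene_id == gid)
      rec <- truth[truth$gene_id == gid, ]
      if (rec$is_gdem) {
        d <- dmrs[dmrs$gene_id == gid, ][1, ]
        if (is.na(d$dmr_id)) {
          stop("eQTM link requested for gene without a planted DMR: ", gid)
        }
        # designated transcript: methylation-coupled latent expression
        des <- idx[1]
        sel <- methylome$meth$chrom == d$chrom &
          methylome$meth$pos >= d$start & methylome$meth$pos <= d$end
        m <- vapply(seq_len(n_s), function(s) {
          tt <- methylome$meth$total[sel, s]
          mm <- methylome$meth$meth[sel, s]
          stats::median(100 * mm[tt > 0] / tt[tt > 0])
        }, numeric(1))
        z_m <- if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else
          rep(0, n_s)
        z <- cfg$eqtm_rho * z_m + sqrt(1 - cfg$eqtm_rho^2) *
          stats::rnorm(n_s)
        log2mu[des, ] <- log2mu[des, ] + couple_sign * z * cfg$coupling_sd
        # record the planted link; r has the coupling sign by construction
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_id = gid, dmr_id = d$dmr_id,
          transcript_id = tx$transcript_id[des],
          rho = cfg$eqtm_rho, sign = couple_sign,
          stringsAsFactors = FALSE
        )
        # group direction implied by coupling: methylation moves by d$sign
        # in the high group, expression by couple_sign * d$sign
        expr_dir <- couple_sign * d$sign
        lfc[des] <- NA  # group effect carried implicitly by the coupling
        implied[des] <- expr_dir * cfg$expr_lfc
        others <- setdiff(idx, des)
        if (rec$discordant && length(others) >= 1) {
          # at least one transcript against the coupled direction
          half <- ceiling(length(others) / 2)
          lfc[others[seq_len(half)]] <- -expr_dir * cfg$expr_lfc
          if (half < length(others)) {
            lfc[others[(half + 1):length(others)]] <- expr_dir * cfg$expr_lfc
          }
        } else if (length(others) >= 1) {
          lfc[others] <- expr_dir * cfg$expr_lfc
        }
      } else {
        sgn <- sample(c(-1, 1), 1)
        lfc[idx] <- sgn * cfg$expr_lfc
      }
    }

    planted <- !is.na(lfc) & lfc != 0
    log2mu[planted, ] <- log2mu[planted, , drop = FALSE] +
      outer(lfc[planted], high)
    mu <- sweep(2^log2mu, 2, libfac, "*")
    counts <- matrix(
      if (cfg$dispersion > 1e-8) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
      } else {
        stats::rpois(length(mu), mu)
      },
      nrow(tx), n_s, dimnames = list(tx$transcript_id, cohort$sample_id)
    )
    truth_pairs <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(gene_id = character(0), dmr_id = character(0),
                 transcript_id = character(0), rho = numeric(0),
                 sign = numeric(0), stringsAsFactors = FALSE)
    list(
      counts = counts,
      tx2gene = tx[, c("transcript_id", "gene_id")],
      truth_tx = data.frame(transcript_id = tx$transcript_id,
                            gene_id = tx$gene_id,
                            lfc = ifelse(is.na(lfc), implied, lfc),
                            coupled = is.na(lfc) & !is.na(implied),
                            stringsAsFactors = FALSE),
      truth_pairs = truth_pairs,
      truth = truth
    )
  })
}

#' Generate a complete synthetic study on disk
#'
#' Runs the four generators and writes the study inputs in the pipeline's
#' external formats: `samples.tsv`, `genes.gtf` (GENCODE dialect),
#' per-sample Bismark-style `<sample>.cov` files under `methylation/`,
#' `counts.tsv`, `dmrs.bed` (BED6+2) and the planted-truth tables
#' `truth_genes.tsv`, `truth_dmrs.tsv`, `truth_pairs.tsv`,
#' `truth_transcripts.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory pieces plus `paths`.
#' @export
simulate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(cfg)
  models <- simulate_gene_models(cfg)
  methylome <- simulate_methylome(cohort, models, cfg)
  expr <- simulate_transcript_counts(cohort, models, methylome, cfg)

  paths <- list(
    samples = file.path(dir, "samples.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    cov_dir = file.path(dir, "methylation"),
    counts = file.path(dir, "counts.tsv"),
    dmrs = file.path(dir, "dmrs.bed"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_dmrs = file.path(dir, "truth_dmrs.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_tx = file.path(dir, "truth_transcripts.tsv")
  )
  write_samples_tsv(cohort, paths$samples)
  write_gtf(models, paths$gtf)
  write_bismark_cov(methylome$meth, paths$cov_dir)
  write_counts_tsv(expr$counts, expr$tx2gene, paths$counts)
  write_bed_dmrs(methylome$dmrs, paths$dmrs)
  utils::write.table(expr$truth, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(methylome$dmrs, paths$truth_dmrs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$truth_pairs, paths$truth_pairs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$truth_tx, paths$truth_tx, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(cohort = cohort, models = models, methylome = methylome,
                 expr = expr, paths = paths, cfg = cfg))
}
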