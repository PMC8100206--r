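#' Construct a CpG methylation matrix
#'
#' Container for per-CpG, per-sample methylated/total read counts with
#' 1-based genomic positions, sorted by chromosome then position.
#'
#' @param chrom Character vector of chromosome names, one per CpG.
#' @param pos Integer vector of 1-based CpG positions.
#' @param meth Integer matrix CpG x sample of methylated read counts.
#' @param total Integer matrix CpG x sample of total read counts.
#' @return Object of class `meth_matrix` (list with the four fields plus
#'   `samples`).
#' @export
meth_matrix <- function(chrom, pos, meth, total) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  stopifnot(length(chrom) == length(pos),
            nrow(meth) == length(pos),
            all(dim(meth) == dim(total)))
  if (any(meth > total)) stop("methylated counts exceed total counts")
  if (any(meth < 0) || any(total < 0)) stop("counts must be non-negative")
  ord <- order(chrom, pos)
  structure(
    list(chrom = as.character(chrom)[ord], pos = as.integer(pos)[ord],
         meth = meth[ord, , drop = FALSE], total = total[ord, , drop = FALSE],
         samples = colnames(meth)),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpGs x %d samples on %d chromosome(s)\n",
              length(x$pos), ncol(x$meth), length(unique(x$chrom))))
  invisible(x)
}

# Percentage-methylation matrix (CpG x sample); CpGs below the coverage
# threshold are NA.
meth_percent <- function(meth, min_cov = 1) {
  pct <- 100 * meth$meth / meth$total
  pct[meth$total < min_cov] <- NA_real_
  pct
}

#' eQTM configuration
#'
#' @param n_bootstrap Bootstrap resamples for the correlation CI.
#' @param n_permutation Consecutive-CpG null windows for the permutation p.
#' @param ci_level Confidence level of the percentile bootstrap interval.
#' @param log2_pseudocount Pseudocount added before log2 of expression.
#' @param min_cpg_coverage Minimum reads for a CpG to contribute.
#' @param tail `"two.sided"` (default) compares |r|; `"greater"` applies the
#'   literal one-sided rule (proportion of null r above the observed r).
#' @param allosomes Chromosomes excluded from the permutation window
#'   universe.
#' @param seed Optional integer seed for bootstrap/permutation draws.
#' @return List of class `eqtm_config`.
#' @export
eqtm_config <- function(n_bootstrap = 1000, n_permutation = 1000,
                        ci_level = 0.95, log2_pseudocount = 1,
                        min_cpg_coverage = 1,
                        tail = c("two.sided", "greater"),
                        allosomes = c("chrX", "chrY", "X", "Y"),
                        seed = NULL) {
  stopifnot(n_bootstrap >= 1, n_permutation >= 1,
            ci_level > 0, ci_level < 1, min_cpg_coverage >= 0)
  structure(
    list(n_bootstrap = as.integer(n_bootstrap),
         n_permutation = as.integer(n_permutation),
         ci_level = ci_level, log2_pseudocount = log2_pseudocount,
         min_cpg_coverage = min_cpg_coverage, tail = match.arg(tail),
         allosomes = allosomes, seed = seed),
    class = "eqtm_config"
  )
}

#' Median regional methylation per sample
#'
#' For one region, computes per sample the percentage methylation of every
#' covered constituent CpG (100 * methylated / total over CpGs with
#' coverage >= `min_cov`) and returns the median. Samples with no covered
#' CpG in the region get NA (dropped downstream with a logged count).
#'
#' @param chrom,start,end Region coordinates, 1-based inclusive.
#' @param meth A [meth_matrix()].
#' @param min_cov Minimum per-CpG read coverage.
#' @return Named numeric vector (one value per sample) with attribute
#'   `"L"`, the number of constituent CpG positions.
#' @export
median_methylation <- function(chrom, start, end, meth, min_cov = 1) {
  stopifnot(inherits(meth, "meth_matrix"))
  idx <- which(meth$chrom == chrom & meth$pos >= start & meth$pos <= end)
  if (length(idx) == 0L) {
    stop("no CpGs in region ", fmt_interval(chrom, start, end))
  }
  pct <- 100 * meth$meth[idx, , drop = FALSE] / meth$total[idx, , drop = FALSE]
  pct[meth$total[idx, , drop = FALSE] < min_cov] <- NA_real_
  med <- apply(pct, 2, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  names(med) <- meth$samples
  attr(med, "L") <- length(idx)
  med
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: requires paired vectors of
#' length >= 3 and errors on constant input (callers log the failure and
#' emit a missing record).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Pearson correlation undefined")
  }
  stats::cor(x, y)
}

#' eQTM point estimate for one DMR x transcript pair
#'
#' Correlates the per-sample median methylation of the region with
#' log2(normalized expression + pseudocount).
#'
#' @param chrom,start,end DMR coordinates (1-based inclusive).
#' @param expr Named numeric vector of normalized expression counts.
#' @param meth A [meth_matrix()].
#' @param cfg An [eqtm_config()].
#' @return List with `r`, `meth_vector`, `expr_vector` (aligned, complete
#'   pairs only), `L`, and `n_dropped` (samples lost to missing coverage).
#' @export
eqtm_pair <- function(chrom, start, end, expr, meth, cfg = eqtm_config()) {
  m <- median_methylation(chrom, start, end, meth,
                          min_cov = cfg$min_cpg_coverage)
  common <- intersect(names(m), names(expr))
  if (length(common) < 3L) stop("fewer than 3 samples shared between inputs")
  mv <- m[common]
  ev <- log2(expr[common] + cfg$log2_pseudocount)
  ok <- stats::complete.cases(mv, ev)
  list(
    r = pearson_r(mv[ok], ev[ok]),
    meth_vector = mv[ok],
    expr_vector = ev[ok],
    L = attr(m, "L"),
    n_dropped = sum(!ok)
  )
}

#' CpG universe for the permutation null
#'
#' Precomputes, once per methylome, the autosomal CpG coordinates and the
#' coverage-filtered percentage-methylation matrix over which null windows
#' of consecutive CpGs are drawn.
#'
#' @param meth A [meth_matrix()].
#' @param cfg An [eqtm_config()]; uses `allosomes` and `min_cpg_coverage`.
#' @return List of class `null_universe` with `chrom`, `pos`, `pct`.
#' @export
null_universe <- function(meth, cfg = eqtm_config()) {
  stopifnot(inherits(meth, "meth_matrix"))
  keep <- !(meth$chrom %in% cfg$allosomes)
  pct <- meth_percent(meth, cfg$min_cpg_coverage)
  structure(
    list(chrom = meth$chrom[keep], pos = meth$pos[keep],
         pct = pct[keep, , drop = FALSE]),
    class = "null_universe"
  )
}

# Column medians of a small matrix; single sort over the flattened matrix
# (fast path without NAs, which dominate the permutation loop).
col_medians <- function(m) {
  if (anyNA(m)) return(apply(m, 2, stats::median, na.rm = TRUE))
  n <- nrow(m)
  s <- matrix(m[order(col(m), m)], n, ncol(m))
  if (n %% 2L == 1L) s[(n + 1L) / 2L, ] else (s[n / 2L, ] + s[n / 2L + 1L, ]) / 2
}

# Row-wise Pearson r of resampled pairs; rows with a constant vector
# return NA.
.rowwise_r <- function(X, Y) {
  xc <- X - rowMeans(X)
  yc <- Y - rowMeans(Y)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  num <- rowSums(xc * yc)
  ifelse(den > 0, num / den, NA_real_)
}

#' Percentile bootstrap CI for a Pearson correlation
#'
#' Resamples the n samples with replacement `n_bootstrap` times,
#' recomputes r on each resample, and returns the percentile interval of
#' the empirical distribution. Degenerate resamples (either vector
#' constant) are discarded and redrawn; if more than half of all draws are
#' degenerate the data are deemed pathological and an error is raised.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @param cfg An [eqtm_config()]; uses `n_bootstrap`, `ci_level`, `seed`.
#' @return Numeric vector `c(ci_low, ci_high)` with the bootstrap
#'   replicates in attribute `"replicates"`.
#' @export
bootstrap_ci <- function(x, y, cfg = eqtm_config()) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  with_seed(cfg$seed, {
    B <- cfg$n_bootstrap
    reps <- rep(NA_real_, B)
    filled <- 0L
    degenerate <- 0L
    while (filled < B) {
      need <- B - filled
      idx <- matrix(sample.int(n, need * n, replace = TRUE), nrow = need)
      r <- .rowwise_r(matrix(x[idx], nrow = need), matrix(y[idx], nrow = need))
      ok <- !is.na(r)
      degenerate <- degenerate + sum(!ok)
      if (degenerate > cfg$n_bootstrap) {
        stop("more than 50% of bootstrap resamples degenerate; ",
             "data pathological")
      }
      take <- which(ok)
      if (length(take)) {
        reps[filled + seq_along(take)] <- r[take]
        filled <- filled + length(take)
      }
    }
    alpha <- (1 - cfg$ci_level) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
    structure(ci, replicates = reps)
  })
}

#' Consecutive-CpG-window permutation p-value
#'
#' Null model for an observed eQTM correlation: windows of `L` consecutive
#' CpGs (the observed DMR's CpG count) are drawn uniformly over the
#' autosomal CpG universe, wholly on one chromosome and not overlapping
#' the observed DMR; each window's per-sample median methylation is
#' correlated with the same expression vector. The p-value is the
#' proportion of null windows whose correlation is at least as extreme as
#' the observed one — by default two-sided on |r| (the literal one-sided
#' "higher than observed" rule is available via `tail = "greater"` in the
#' config). If fewer valid window positions exist than requested, windows
#' are drawn with replacement with a warning.
#'
#' @param observed_r Observed Pearson correlation.
#' @param L Window length in consecutive CpGs (>= 2).
#' @param expr_log2 Named log2-expression vector (as used for
#'   `observed_r`).
#' @param meth A [meth_matrix()].
#' @param cfg An [eqtm_config()].
#' @param exclude Optional list `(chrom, start, end)` of the observed DMR,
#'   whose windows are excluded from the null.
#' @param universe Optional precomputed [null_universe()] (fast path for
#'   batched calls over the same methylome).
#' @return Permutation p-value in \[0, 1\]; `perm_p * n_permutation` is an
#'   integer. Attribute `"display"` renders exact zeros as
#'   `"< 1/n_permutation"`.
#' @export
permutation_p <- function(observed_r, L, expr_log2, meth,
                          cfg = eqtm_config(), exclude = NULL,
                          universe = NULL) {
  stopifnot(L >= 2)
  if (is.null(universe)) universe <- null_universe(meth, cfg)
  chrom <- universe$chrom
  pos <- universe$pos
  pct <- universe$pct
  n_cpg <- length(pos)
  if (n_cpg < L) stop("CpG universe smaller than window length")

  last <- n_cpg - L + 1L
  starts <- seq_len(last)
  same_chrom <- chrom[starts] == chrom[starts + L - 1L]
  valid <- starts[same_chrom]
  if (!is.null(exclude)) {
    ws <- pos[valid]
    we <- pos[valid + L - 1L]
    hit <- chrom[valid] == exclude$chrom &
      ws <= exclude$end & we >= exclude$start
    valid <- valid[!hit]
  }
  if (length(valid) == 0L) stop("no valid null window positions")

  expr_log2 <- expr_log2[colnames(pct) %||% seq_len(ncol(pct))]
  with_seed(cfg$seed, {
    n_perm <- cfg$n_permutation
    if (length(valid) < n_perm) {
      warning("only ", length(valid), " valid window positions for ",
              n_perm, " permutations; sampling with replacement")
      draws <- sample(valid, n_perm, replace = TRUE)
    } else {
      draws <- sample(valid, n_perm, replace = FALSE)
    }
    r_null <- rep(NA_real_, n_perm)
    attempts <- 0L
    i <- 1L
    while (i <= n_perm) {
      s <- draws[i]
      block <- pct[s:(s + L - 1L), , drop = FALSE]
      med <- col_medians(block)
      ok <- !is.nan(med) & !is.na(med) & !is.na(expr_log2)
      r <- if (sum(ok) >= 3 && stats::sd(med[ok]) > 0 &&
               stats::sd(expr_log2[ok]) > 0) {
        stats::cor(med[ok], expr_log2[ok])
      } else NA_real_
      if (is.na(r)) {
        # degenerate window: redraw so the p-value granularity is preserved
        attempts <- attempts + 1L
        if (attempts > 10L * n_perm) stop("too many degenerate null windows")
        draws[i] <- sample(valid, 1L)
        next
      }
      r_null[i] <- r
      i <- i + 1L
    }
    exceed <- if (cfg$tail == "two.sided") {
      sum(abs(r_null) >= abs(observed_r))
    } else {
      sum(r_null >= observed_r)
    }
    p <- exceed / n_perm
    structure(p, display = if (exceed == 0L) {
      sprintf("< %g", 1 / n_perm)
    } else {
      format(p)
    })
  })
}

#' Full eQTM analysis over a GDEM table
#'
#' For every gene x DMR x significant-transcript row of a GDEM table,
#' computes the methylation-expression Pearson correlation, its percentile
#' bootstrap CI and the consecutive-CpG-window permutation p-value.
#'
#' @param gdem_tbl Data frame from [gdem_table()].
#' @param dmrs DMR records (`dmr_id`, `chrom`, `start`, `end`).
#' @param meth A [meth_matrix()].
#' @param normalized Normalized transcript x sample expression matrix.
#' @param cfg An [eqtm_config()]; per-pair bootstrap/permutation seeds are
#'   derived deterministically from `cfg$seed`.
#' @return Data frame with one row per pair: `gene_id`, `dmr`,
#'   `transcript_id`, `L`, `r`, `ci_low`, `ci_high`, `perm_p`,
#'   `perm_p_display`. Pairs whose correlation is undefined are skipped;
#'   attribute `"n_skipped"` counts them.
#' @export
eqtm_analysis <- function(gdem_tbl, dmrs, meth, normalized,
                          cfg = eqtm_config()) {
  pairs <- unique(gdem_tbl[, c("gene_id", "dmr_id", "transcript_id")])
  universe <- null_universe(meth, cfg)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    d <- dmrs[dmrs$dmr_id == pairs$dmr_id[i], , drop = FALSE]
    tx <- pairs$transcript_id[i]
    expr <- normalized[tx, ]
    pair_cfg <- cfg
    pair_cfg$seed <- if (is.null(cfg$seed)) NULL else {
      stage_seed(cfg$seed, paste(pairs$gene_id[i], pairs$dmr_id[i], tx))
    }
    res <- tryCatch(
      eqtm_pair(d$chrom[1], d$start[1], d$end[1], expr, meth, pair_cfg),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- skipped + 1L
      next
    }
    ci <- bootstrap_ci(res$meth_vector, res$expr_vector, pair_cfg)
    pp <- permutation_p(res$r, max(2L, res$L), res$expr_vector, meth,
                        pair_cfg,
                        exclude = list(chrom = d$chrom[1], start = d$start[1],
                                       end = d$end[1]),
                        universe = universe)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = pairs$gene_id[i],
      dmr = fmt_interval(d$chrom[1], d$start[1], d$end[1]),
      dmr_id = pairs$dmr_id[i],
      transcript_id = tx,
      L = res$L,
      r = res$r,
      ci_low = ci[1],
      ci_high = ci[2],
      perm_p = as.numeric(pp),
      perm_p_display = attr(pp, "display"),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), dmr = character(0),
               dmr_id = character(0), transcript_id = character(0),
               L = integer(0), r = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), perm_p = numeric(0),
               perm_p_display = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}
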