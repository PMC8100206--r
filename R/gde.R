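#' Median-of-ratios normalization of a transcript count matrix
#'
#' Computes size factors as the per-sample median ratio to the geometric
#' mean reference, over the transcripts with strictly positive counts in
#' every sample, then divides each column by its size factor.
#'
#' @param counts Non-negative integer matrix, transcripts x samples, with
#'   rownames (transcript ids) and colnames (sample ids).
#' @return A list with `normalized` (numeric matrix), `size_factors`
#'   (named numeric vector) and `base_expression` (mean normalized count per
#'   transcript; the Lancaster weight source).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) stop("no transcript has positive counts in every sample")
  ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
  sf <- apply(counts[all_pos, , drop = FALSE] / ref, 2, stats::median)
  normalized <- sweep(counts, 2, sf, "/")
  list(
    normalized = normalized,
    size_factors = sf,
    base_expression = rowMeans(normalized)
  )
}

#' Per-transcript differential-expression test (OLS stand-in)
#'
#' Fits, for every transcript, an ordinary least-squares regression of
#' log2(normalized count + 1) on the full covariate design (sex, age, DMARD
#' use, SJC66 group) and reports the t statistic and two-sided p-value of
#' the group coefficient. This is a deliberately simple, pluggable stand-in
#' for a negative-binomial fit: downstream aggregation only consumes the
#' per-transcript (statistic, p, weight) triples. Transcripts with zero base
#' expression are dropped before testing. Transcripts with (numerically)
#' zero residual variance are flagged degenerate: the p-value is floored at
#' `p_floor` when the group effect is nonzero and set to 1 when it is zero.
#'
#' @param normalized Normalized transcript x sample matrix (see
#'   [normalize_counts()]); columns must cover the design rows.
#' @param design Design matrix from [build_design()] containing a `group`
#'   column.
#' @param base_expression Optional per-transcript weight vector (defaults to
#'   the row means of `normalized` over the design samples).
#' @param p_floor Lower bound for degenerate p-values.
#' @return A data frame with columns `transcript_id`, `base_expression`,
#'   `effect_stat`, `p_value`, `degenerate`.
#' @export
test_transcripts <- function(normalized, design, base_expression = NULL,
                             p_floor = 1e-300) {
  if (!"group" %in% colnames(design)) stop("design must contain a 'group' column")
  samp <- rownames(design)
  if (!all(samp %in% colnames(normalized))) {
    stop("normalized matrix lacks columns for design samples: ",
         paste(setdiff(samp, colnames(normalized)), collapse = ", "))
  }
  m <- normalized[, samp, drop = FALSE]
  if (is.null(base_expression)) base_expression <- rowMeans(m)
  keep <- base_expression > 0
  m <- m[keep, , drop = FALSE]
  base_expression <- base_expression[keep]
  n <- nrow(design)
  p <- ncol(design)
  df <- n - p
  if (df <= 0) stop("no residual degrees of freedom (n = ", n, ", p = ", p, ")")

  y <- t(log2(m + 1))                         # samples x transcripts
  qr_d <- qr(design)
  if (qr_d$rank < p) stop("design is rank deficient")
  beta <- qr.coef(qr_d, y)                    # p x transcripts
  res <- qr.resid(qr_d, y)
  rss <- colSums(res^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_d))[, , drop = FALSE]
  j <- match("group", colnames(design))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  b <- beta[j, ]
  tstat <- b / se
  pval <- 2 * stats::pt(-abs(tstat), df)

  tol <- 1e-10 * pmax(1, colSums(y^2))
  degenerate <- rss < tol
  if (any(degenerate)) {
    null_eff <- degenerate & abs(b) < sqrt(.Machine$double.eps)
    tstat[degenerate] <- sign(b[degenerate]) * Inf
    pval[degenerate] <- p_floor
    tstat[null_eff] <- 0
    pval[null_eff] <- 1
  }
  pval <- pmax(pval, p_floor)

  data.frame(
    transcript_id = rownames(m),
    base_expression = unname(base_expression),
    effect_stat = unname(tstat),
    p_value = unname(pval),
    degenerate = unname(degenerate),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Lancaster aggregation of p-values
#'
#' Combines p-values with the weighted Lancaster generalization of Fisher's
#' method: each p is transformed through the inverse gamma CDF with shape
#' w/2 and scale 2, the transforms are summed, and the sum is referred to a
#' gamma distribution with shape sum(w)/2 and scale 2. With all weights
#' equal to 2 this is exactly Fisher's method. Weights below `weight_floor`
#' are excluded before aggregation (near-zero weights carry no information
#' and destabilize the gamma shape). Inputs of p = 0 are clamped to the
#' smallest positive double with a warning. Tail probabilities are taken
#' directly from the gamma survival function, which is accurate far into
#' the tail.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param weights Non-negative numeric weights, same length (here: transcript
#'   base expression).
#' @param weight_floor Weights strictly below this are dropped (default 1).
#' @return Scalar combined p-value, with the aggregation statistic in
#'   attribute `"statistic"` and the number of aggregated p-values in
#'   attribute `"n_used"`.
#' @examples
#' lancaster_aggregate(c(0.05, 0.05), c(2, 2)) # Fisher's method
#' @export
lancaster_aggregate <- function(p_values, weights, weight_floor = 1) {
  if (length(p_values) != length(weights)) {
    stop("p_values and weights must have equal length")
  }
  if (length(p_values) == 0L) stop("no p-values to aggregate")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-value(s) of 0 clamped to smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  keep <- weights >= weight_floor
  if (!any(keep)) {
    stop("all weights fall below the weight floor (", weight_floor,
         "); combined p undefined")
  }
  p <- p_values[keep]
  w <- weights[keep]
  t_i <- stats::qgamma(p, shape = w / 2, scale = 2, lower.tail = FALSE)
  T_stat <- sum(t_i)
  comb <- stats::pgamma(T_stat, shape = sum(w) / 2, scale = 2,
                        lower.tail = FALSE)
  structure(comb, statistic = T_stat, n_used = length(p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values via [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Aggregate transcript tests to gene-level GDE results
#'
#' Groups per-transcript results by gene, combines p-values with
#' expression-weighted Lancaster aggregation, BH-adjusts across genes and
#' flags genes with q < alpha as GDE. Genes whose transcripts all fall
#' below the weight floor are dropped with a count in attribute
#' `"n_dropped_genes"`.
#'
#' @param tx_results Data frame from [test_transcripts()] plus a `gene_id`
#'   column.
#' @param alpha FDR threshold for the GDE call (strict `<`).
#' @param weight_floor Passed to [lancaster_aggregate()].
#' @return Data frame with `gene_id`, `n_transcripts`, `lancaster_T`,
#'   `p_value`, `q_value`, `is_gde`.
#' @export
aggregate_genes <- function(tx_results, alpha = 0.05, weight_floor = 1) {
  stopifnot(all(c("gene_id", "transcript_id", "p_value",
                  "base_expression") %in% names(tx_results)))
  split_idx <- split(seq_len(nrow(tx_results)), tx_results$gene_id)
  res <- lapply(names(split_idx), function(g) {
    idx <- split_idx[[g]]
    w <- tx_results$base_expression[idx]
    if (all(w < weight_floor)) return(NULL)
    comb <- lancaster_aggregate(tx_results$p_value[idx], w,
                                weight_floor = weight_floor)
    data.frame(
      gene_id = g,
      n_transcripts = attr(comb, "n_used"),
      lancaster_T = attr(comb, "statistic"),
      p_value = as.numeric(comb),
      stringsAsFactors = FALSE
    )
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) stop("no gene survived the weight floor")
  res$q_value <- bh_adjust(res$p_value)
  res$is_gde <- call_gde(res$q_value, alpha = alpha)
  attr(res, "n_dropped_genes") <- dropped
  res
}

#' GDE call at an FDR threshold
#'
#' @param q_values BH-adjusted q-values.
#' @param alpha Threshold; the call is strict (`q < alpha`).
#' @return Logical vector.
#' @export
call_gde <- function(q_values, alpha = 0.05) {
  if (length(q_values) == 0L) return(logical(0))
  q_values < alpha
}

#' Remove allosome-associated transcripts before testing
#'
#' Drops every transcript whose gene lies on a configured allosome (sex
#' chromosome), mitigating obvious sex effects in a sex-confounded cohort.
#'
#' @param tx2gene Data frame with `transcript_id`, `gene_id`.
#' @param gene_chrom Named character vector mapping gene_id to chromosome.
#' @param allosomes Chromosome names treated as allosomes.
#' @return `tx2gene` restricted to autosomal genes; attribute `"n_removed"`
#'   counts removed transcripts.
#' @export
filter_allosomes <- function(tx2gene, gene_chrom,
                             allosomes = c("chrX", "chrY", "X", "Y")) {
  chrom <- gene_chrom[tx2gene$gene_id]
  drop <- !is.na(chrom) & chrom %in% allosomes
  out <- tx2gene[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}
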