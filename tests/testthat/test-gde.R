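test_that("median-of-ratios size factors behave on symmetric and scaled toys", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("t", 1:3), c("a", "b")))
  nr <- normalize_counts(m)
  expect_equal(unname(nr$size_factors), c(1, 1))

  # doubling one column doubles its size factor relative to the other
  m2 <- m
  m2[, 2] <- m[, 2] * 2
  nr2 <- normalize_counts(m2)
  expect_equal(unname(nr2$size_factors[2] / nr2$size_factors[1]), 2)

  # hand computation on a 3-transcript, 2-sample toy:
  # counts a=(4,9,0), b=(16,36,5); geometric means over all-positive rows
  # (t1,t2) are (8, 18); ratios a=(0.5,0.5) -> sf 0.5, b=(2,2) -> sf 2
  m3 <- matrix(c(4, 9, 0, 16, 36, 5), ncol = 2,
               dimnames = list(paste0("t", 1:3), c("a", "b")))
  nr3 <- normalize_counts(m3)
  expect_equal(unname(nr3$size_factors), c(0.5, 2))
  expect_equal(unname(nr3$base_expression["t3"]), mean(c(0, 2.5)))

  expect_error(normalize_counts(cbind(a = c(0, 0), b = c(1, 2))),
               "all-zero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rnbinom(600, mu = 50, size = 5), ncol = 6)
  rownames(m) <- paste0("t", seq_len(nrow(m)))
  colnames(m) <- paste0("s", 1:6)
  ours <- normalize_counts(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # ours is the median of ratios, DESeq2 exponentiates the median log
  # ratio; they differ only in the even-count midpoint interpolation
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("transcript OLS test handles null, degenerate and planted effects", {
  s <- dichotomize_sjc66(make_cohort_df(5, 5))
  X <- build_design(s)

  # constant expression: zero group effect, p = 1
  m <- matrix(7, nrow = 2, ncol = 10,
              dimnames = list(c("t1", "t2"), rownames(X)))
  r <- test_transcripts(m, X)
  expect_equal(r$effect_stat, c(0, 0))
  expect_equal(r$p_value, c(1, 1))

  # perfect separation with zero residual variance: floored p, flag set
  grp <- X[, "group"]
  sep <- 2^(3 + 2 * grp) - 1          # log2(x+1) = 3 + 2*group exactly
  m2 <- rbind(t1 = sep)
  # (needs the other covariates to contribute nothing)
  X0 <- X[, c("intercept", "group")]
  r2 <- test_transcripts(m2, X0)
  expect_true(r2$degenerate)
  expect_lt(r2$p_value, 1e-100)
  expect_true(is.infinite(r2$effect_stat) & r2$effect_stat > 0)

  # zero-base-expression transcripts are dropped before testing
  m3 <- rbind(m, t0 = 0)
  expect_false("t0" %in% test_transcripts(m3, X)$transcript_id)
})

test_that("planted log2 fold changes are detected with high power", {
  s <- dichotomize_sjc66(make_cohort_df(8, 8))
  X <- build_design(s)
  set.seed(21)
  n_tx <- 100
  grp <- X[, "group"]
  mu <- 2^(6 + outer(rep(2, n_tx), grp))   # lfc = 2
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), nrow = n_tx,
                   dimnames = list(paste0("t", 1:n_tx), rownames(X)))
  r <- test_transcripts(counts, X)
  expect_gte(mean(r$p_value < 0.01), 0.95)
})

test_that("Lancaster aggregation reduces to the transcript p for one input", {
  set.seed(1)
  for (p in runif(20)) {
    expect_equal(as.numeric(lancaster_aggregate(p, 5)), p, tolerance = 1e-12)
  }
})

test_that("Lancaster with unit-chi-square weights equals Fisher's method", {
  # independent oracle: Fisher statistic -2*sum(log p) vs chi-square(2k)
  p <- c(0.05, 0.05)
  got <- as.numeric(lancaster_aggregate(p, c(2, 2)))
  stat <- -2 * sum(log(p))
  expect_equal(stat, 11.9829, tolerance = 1e-4)
  expect_equal(got, pchisq(stat, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:10, 1)
    p <- runif(k)
    got <- as.numeric(lancaster_aggregate(p, rep(2, k)))
    oracle <- pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
    expect_lt(abs(got - oracle), 1e-10)
  }
})

test_that("Lancaster p is permutation-invariant and monotone in inputs", {
  set.seed(9)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    p <- runif(k)
    w <- runif(k, 1, 50)
    base <- as.numeric(lancaster_aggregate(p, w))
    expect_gt(base, 0)
    expect_lt(base, 1)
    perm <- sample(k)
    expect_equal(as.numeric(lancaster_aggregate(p[perm], w[perm])), base,
                 tolerance = 1e-12)
    # raising one p cannot lower the combined p
    j <- sample(k, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_gte(as.numeric(lancaster_aggregate(p2, w)) + 1e-12, base)
  }
})

test_that("Lancaster input contracts: zero p clamped, floored weights", {
  expect_warning(r <- lancaster_aggregate(c(0, 0.5), c(10, 10)), "clamped")
  expect_gt(as.numeric(r), 0)
  expect_error(lancaster_aggregate(c(0.1, 0.2), c(0.5, 0.2)), "weight floor")
  # below-floor transcripts are excluded from the sum
  one <- as.numeric(lancaster_aggregate(c(0.03, 0.9), c(5, 0.1)))
  expect_equal(one, 0.03, tolerance = 1e-12)
})

test_that("BH adjustment matches a hand step-up oracle", {
  # literal step-up definition: q_(i) = min_{j >= i} min(1, n p_(j) / j)
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(n)
    for (i in seq_len(n)) q[i] <- min(1, n * ps[i:n] / (i:n))
    out <- numeric(n)
    out[o] <- q
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(13)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
  }
})

test_that("GDE calls use a strict FDR threshold", {
  expect_true(call_gde(0.049))
  expect_false(call_gde(0.05))
  expect_length(call_gde(numeric(0)), 0)
})

test_that("gene aggregation weights by base expression and drops weightless genes", {
  tx <- data.frame(
    transcript_id = paste0("t", 1:5),
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    p_value = c(0.01, 0.04, 0.2, 0.5, 0.6),
    base_expression = c(10, 8, 5, 0.1, 0.2),
    stringsAsFactors = FALSE
  )
  res <- aggregate_genes(tx, alpha = 0.05)
  expect_setequal(res$gene_id, c("g1", "g2"))     # g3 below weight floor
  expect_equal(attr(res, "n_dropped_genes"), 1)
  g2 <- res[res$gene_id == "g2", ]
  expect_equal(g2$p_value, 0.2, tolerance = 1e-12)  # single-transcript identity
  expect_equal(res$q_value, bh_adjust(res$p_value))
})

test_that("allosome-associated transcripts never reach testing", {
  tx2gene <- data.frame(transcript_id = paste0("t", 1:4),
                        gene_id = c("g1", "g2", "g3", "g3"),
                        stringsAsFactors = FALSE)
  chrom <- c(g1 = "chr1", g2 = "chrX", g3 = "chrY")
  kept <- filter_allosomes(tx2gene, chrom)
  expect_equal(kept$transcript_id, "t1")
  expect_equal(attr(kept, "n_removed"), 3)
})
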