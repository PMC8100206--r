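# Tiny deterministic methylome: one chromosome, evenly spaced CpGs with
# full coverage and prescribed percent methylation.
mk_meth <- function(pct_mat, pos = NULL, chrom = "c1", depth = 100L) {
  n <- nrow(pct_mat)
  if (is.null(pos)) pos <- seq(100, by = 50, length.out = n)
  total <- matrix(depth, n, ncol(pct_mat),
                  dimnames = list(NULL, colnames(pct_mat)))
  meth_matrix(rep(chrom, n), pos,
              round(pct_mat / 100 * depth), total)
}

test_that("median regional methylation follows the median contract", {
  pct <- cbind(s1 = c(10, 20, 90), s2 = c(10, 90, 90))
  meth <- mk_meth(pct)
  med <- median_methylation("c1", 100, 200, meth)
  expect_equal(as.numeric(med), c(20, 90))
  expect_equal(attr(med, "L"), 3)
  # even number of constituent CpGs: mean of the middle pair
  med2 <- median_methylation("c1", 100, 150, meth)
  expect_equal(unname(med2[1]), 15)
  expect_equal(unname(med2["s2"]), 50)
})

test_that("uncovered samples yield missing medians, empty regions error", {
  pct <- cbind(s1 = c(10, 30), s2 = c(50, 70))
  meth <- mk_meth(pct)
  meth$total[, "s2"] <- 0L
  meth$meth[, "s2"] <- 0L
  med <- median_methylation("c1", 100, 200, meth)
  expect_equal(unname(med["s1"]), 20)
  expect_true(is.na(med["s2"]))
  expect_error(median_methylation("c2", 100, 200, meth), "no CpGs")
})

test_that("pearson_r matches hand-computed values and rejects bad input", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_r(1:3, c(6, 4, 2)), -1)
  expect_equal(pearson_r(1:3, c(1, 3, 2)), 0.5)
  expect_error(pearson_r(1:3, c(2, 2, 2)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("eqtm_pair correlates regional methylation with log2 expression", {
  pct <- rbind(seq(10, 90, length.out = 9), seq(10, 90, length.out = 9))
  colnames(pct) <- paste0("s", 1:9)
  meth <- mk_meth(pct)
  expr <- stats::setNames(2^seq(1, 5, length.out = 9) - 1, paste0("s", 1:9))
  res <- eqtm_pair("c1", 100, 200, expr, meth)
  expect_equal(res$r, 1, tolerance = 1e-6)
  expect_equal(res$n_dropped, 0)
})

test_that("bootstrap CI is deterministic, bounded and degenerate-safe", {
  set.seed(8)
  x <- rnorm(17)
  y <- 0.8 * x + rnorm(17, 0, 0.6)
  cfg <- eqtm_config(n_bootstrap = 500, seed = 99)
  ci1 <- bootstrap_ci(x, y, cfg)
  ci2 <- bootstrap_ci(x, y, cfg)
  expect_equal(as.numeric(ci1), as.numeric(ci2))
  expect_true(all(ci1 >= -1 & ci1 <= 1))
  expect_lt(ci1[1], ci1[2])
  r <- pearson_r(x, y)
  expect_true(ci1[1] <= r && r <= ci1[2])

  # exactly linear data: every valid resample has r = 1
  xl <- 1:10
  ci <- bootstrap_ci(xl, 2 * xl + 3, eqtm_config(n_bootstrap = 200, seed = 1))
  expect_equal(as.numeric(ci), c(1, 1))

  # constant data can never produce a valid resample
  expect_error(bootstrap_ci(rep(1, 10), rnorm(10),
                            eqtm_config(n_bootstrap = 50, seed = 1)),
               "pathological")
})

test_that("permutation p has the documented granularity and tail behavior", {
  set.seed(31)
  n_s <- 10
  pct <- matrix(runif(400 * n_s, 0, 100), 400, n_s,
                dimnames = list(NULL, paste0("s", 1:n_s)))
  meth <- mk_meth(pct)
  expr <- stats::setNames(rnorm(n_s), paste0("s", 1:n_s))
  cfg <- eqtm_config(n_permutation = 200, seed = 4)
  p <- permutation_p(0.3, 5, expr, meth, cfg)
  expect_true(p >= 0 && p <= 1)
  expect_equal(as.numeric(p) * 200, round(as.numeric(p) * 200))
  # determinism under a fixed seed
  expect_equal(as.numeric(permutation_p(0.3, 5, expr, meth, cfg)),
               as.numeric(p))

  # no window can beat |r| = 1 on non-degenerate data
  p1 <- permutation_p(1, 5, expr, meth, cfg)
  expect_equal(as.numeric(p1), 0)
  expect_match(attr(p1, "display"), "^< ")

  # n_permutation = 1 gives p in {0, 1}
  p01 <- permutation_p(0.2, 5, expr, meth, eqtm_config(n_permutation = 1,
                                                       seed = 2))
  expect_true(as.numeric(p01) %in% c(0, 1))

  # literal one-sided rule: negative observed r is almost never exceeded
  cfg1 <- eqtm_config(n_permutation = 200, tail = "greater", seed = 4)
  expect_gt(as.numeric(permutation_p(-0.99, 5, expr, meth, cfg1)), 0.95)
})

test_that("few valid window positions trigger with-replacement sampling", {
  set.seed(2)
  pct <- matrix(runif(80, 0, 100), 8, 10,
                dimnames = list(NULL, paste0("s", 1:10)))
  meth <- mk_meth(pct)
  expr <- stats::setNames(rnorm(10), paste0("s", 1:10))
  expect_warning(
    p <- permutation_p(0.5, 5, expr, meth,
                       eqtm_config(n_permutation = 50, seed = 3)),
    "with replacement")
  expect_true(p >= 0 && p <= 1)
})

test_that("windows overlapping the observed DMR are excluded from the null", {
  # methylome where ONLY the observed region carries a huge group-like
  # signal; excluding it forces the null far from the observed r
  set.seed(5)
  n_s <- 12
  base <- matrix(runif(300 * n_s, 40, 60), 300, n_s,
                 dimnames = list(NULL, paste0("s", 1:n_s)))
  sig <- seq(0, 100, length.out = n_s)
  base[150:160, ] <- matrix(rep(sig, each = 11), 11, n_s) +
    matrix(runif(11 * n_s, -1, 1), 11, n_s)
  meth <- mk_meth(pmax(pmin(base, 100), 0))
  expr <- stats::setNames(sig + rnorm(n_s, 0, 3), paste0("s", 1:n_s))
  start <- meth$pos[150]
  end <- meth$pos[160]
  obs <- eqtm_pair("c1", start, end, 2^expr, meth)
  cfg <- eqtm_config(n_permutation = 200, seed = 11)
  p_excl <- permutation_p(obs$r, 11, obs$expr_vector, meth, cfg,
                          exclude = list(chrom = "c1", start = start,
                                         end = end))
  expect_lte(as.numeric(p_excl), 0.05)
})
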