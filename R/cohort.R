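#' Stratify samples by swollen joint count (SJC66)
#'
#' Dichotomizes the 66-joint swollen joint count into the clinical contrast
#' used throughout the pipeline: samples with SJC66 >= 9 form the `high`
#' group, samples with 1 <= SJC66 <= 8 the `low` group, and samples with
#' SJC66 = 0 are `excluded` from all comparative analyses (clinically they
#' are a heterogeneous mix of very early arthritis and treated disease
#' without residual swelling).
#'
#' @param samples A data frame with at least columns `sample_id` and `sjc66`
#'   (non-negative integers, at most 66).
#' @return The input data frame with an added factor column `group` with
#'   levels `high`, `low`, `excluded`.
#' @examples
#' s <- data.frame(sample_id = c("a", "b", "c"), sjc66 = c(9, 8, 0))
#' dichotomize_sjc66(s)$group
#' @export
dichotomize_sjc66 <- function(samples) {
  stopifnot(is.data.frame(samples), "sjc66" %in% names(samples))
  sjc <- samples$sjc66
  if (anyNA(sjc)) stop("sjc66 must be present for all samples")
  if (any(sjc < 0)) stop("sjc66 must be non-negative")
  if (any(sjc > 66)) stop("sjc66 cannot exceed 66")
  group <- ifelse(sjc >= 9, "high", ifelse(sjc >= 1, "low", "excluded"))
  samples$group <- factor(group, levels = c("high", "low", "excluded"))
  samples
}

#' Build the covariate design matrix for differential testing
#'
#' Constructs the design shared by the expression and methylation contrasts:
#' intercept, sex, age, DMARD use and the dichotomized SJC66 group indicator
#' (high = 1, low = 0). Samples in the `excluded` group are dropped. Age is
#' mean-centered (stabilizes the intercept; the group contrast is unchanged).
#' Sex is coded female = 0, male = 1. A covariate that is constant across
#' the retained samples is dropped with a warning rather than producing a
#' rank-deficient design.
#'
#' @param samples A data frame as returned by [dichotomize_sjc66()], with
#'   columns `sample_id`, `group`, `sex` (`"male"`/`"female"`), `age`
#'   (years) and `dmard_use` (logical).
#' @return A numeric matrix with one row per retained sample (rownames =
#'   `sample_id`) and columns among `intercept`, `sex`, `age`, `dmard_use`,
#'   `group`; attribute `"samples"` holds the retained sample ids in row
#'   order.
#' @export
build_design <- function(samples) {
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "group", "sex", "age", "dmard_use")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("sample_id must be unique")
  keep <- samples[samples$group %in% c("high", "low"), , drop = FALSE]
  n_high <- sum(keep$group == "high")
  n_low <- sum(keep$group == "low")
  if (n_high < 2 || n_low < 2) {
    stop("need at least 2 samples per SJC66 group after exclusion (got ",
         n_high, " high, ", n_low, " low)")
  }
  sex_num <- ifelse(as.character(keep$sex) == "male", 1, 0)
  if (!all(as.character(keep$sex) %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  X <- cbind(
    intercept = 1,
    sex = sex_num,
    age = as.numeric(keep$age) - mean(as.numeric(keep$age)),
    dmard_use = as.numeric(keep$dmard_use),
    group = as.numeric(keep$group == "high")
  )
  rownames(X) <- keep$sample_id
  constant <- apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    dropped <- names(constant)[constant]
    if ("group" %in% dropped) stop("group indicator is constant; nothing to contrast")
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient after covariate encoding")
  }
  attr(X, "samples") <- rownames(X)
  X
}
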