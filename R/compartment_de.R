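#' Compartment-specific differential expression score
#'
#' Contrasts a gene's expression change between two cohorts in the cancer
#' versus the stroma compartment:
#' `DE = log2( |e_c2 / e_c1| / |e_s2 / e_s1| )`,
#' where `e` are the deconvoluted log2 compartment expression values of
#' groups 1 and 2. Positive scores indicate a larger relative change in the
#' cancer compartment, negative scores in the stroma. A pseudocount
#' `epsilon` is added to every term before division so the score is always
#' finite.
#'
#' The alternative difference statistic
#' `DE* = (e_c2 - e_c1) - (e_s2 - e_s1)` (difference of compartment log
#' fold-changes) is available via `statistic = "difference"`.
#'
#' @param e_c1,e_c2,e_s1,e_s2 Nonnegative log2 compartment expression
#'   (group 1 and group 2; cancer and stroma). Vectorized.
#' @param epsilon Positive pseudocount, default `1e-6`.
#' @param statistic `"ratio"` (the score as defined above, default) or
#'   `"difference"`.
#' @return Numeric DE score(s).
#' @export
de_score <- function(e_c1, e_c2, e_s1, e_s2, epsilon = 1e-6,
                     statistic = c("ratio", "difference")) {
  statistic <- match.arg(statistic)
  if (epsilon <= 0) stop("epsilon must be positive")
  if (statistic == "difference")
    return((e_c2 - e_c1) - (e_s2 - e_s1))
  log2(abs((e_c2 + epsilon) / (e_c1 + epsilon)) /
         abs((e_s2 + epsilon) / (e_s1 + epsilon)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (with monotonicity enforcement)
#' of a family of p-values, as implemented by [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, elementwise `>= p`.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Permutation test of the compartment DE score
#'
#' Computes the observed DE score per gene from the true group labels, then
#' estimates its null distribution by shuffling the sample-to-group
#' assignment within the union of the two compared groups (preserving group
#' sizes) and re-running the two-compartment deconvolution at every
#' shuffle. One shared shuffle per iteration scores all genes. The
#' two-tailed empirical p-value uses the add-one rule
#' `p = (1 + #{|DE_null| >= |DE_obs|}) / (1 + n_perm)` so p is never zero.
#' When `n_perm` is at least the number of distinct label assignments the
#' test switches to exhaustive enumeration (p = exceedance fraction over
#' all assignments, message emitted).
#'
#' @param expr_log log2-scale [expression_matrix()].
#' @param purity Named purity vector.
#' @param labels Named group label vector.
#' @param groups Length-2 character vector `c(group1, group2)`; fold-changes
#'   are group2 vs group1.
#' @param n_perm Number of permutations (>= 1); the study default is 50000.
#' @param seed Integer seed.
#' @param epsilon Pseudocount forwarded to [de_score()].
#' @param statistic Forwarded to [de_score()].
#' @param mixing_scale Forwarded to [deconvolute_group()].
#' @param enumeration `"auto"` (default: enumerate exhaustively whenever
#'   `n_perm` covers all distinct assignments), `"always"`, or `"never"`
#'   (force Monte-Carlo, e.g. to study sampling convergence).
#' @return data.frame (gene, de_score, cancer_log2fc, stroma_log2fc,
#'   p_empirical, q_bh, n_permutations, direction); direction is `"cancer"`
#'   for nonnegative scores, `"stroma"` otherwise.
#' @export
permutation_de_test <- function(expr_log, purity, labels, groups,
                                n_perm = 50000L, seed = 1L,
                                epsilon = 1e-6,
                                statistic = c("ratio", "difference"),
                                mixing_scale = c("log", "linear"),
                                enumeration = c("auto", "always", "never")) {
  statistic <- match.arg(statistic)
  mixing_scale <- match.arg(mixing_scale)
  enumeration <- match.arg(enumeration)
  assert_two_groups(labels, groups)
  if (n_perm < 1L) stop("n_perm must be >= 1")

  s1 <- intersect(names(labels)[labels == groups[1]], colnames(expr_log))
  s2 <- intersect(names(labels)[labels == groups[2]], colnames(expr_log))
  if (length(s1) < 2L || length(s2) < 2L)
    stop("both groups need at least 2 samples")
  pool <- c(s1, s2)
  p <- purity[pool]
  if (anyNA(p)) {
    warning(sum(is.na(p)), " sample(s) with NA purity dropped")
    pool <- pool[!is.na(p)]
    s1 <- intersect(s1, pool); s2 <- intersect(s2, pool)
    p <- purity[pool]
  }
  n1 <- length(s1)
  vals <- unclass(expr_log)[, pool, drop = FALSE]
  if (mixing_scale == "linear") vals <- 2^vals - 1
  relog <- function(e) if (mixing_scale == "linear") log2(pmax(e, 0) + 1) else e

  score_split <- function(idx1) {
    f1 <- fit_two_compartment(vals[, idx1, drop = FALSE],
                              as.numeric(p[idx1]))
    f2 <- fit_two_compartment(vals[, -idx1, drop = FALSE],
                              as.numeric(p[-idx1]))
    list(e_c1 = relog(f1$e_c), e_s1 = relog(f1$e_s),
         e_c2 = relog(f2$e_c), e_s2 = relog(f2$e_s))
  }

  obs_idx <- seq_len(n1)   # pool is ordered c(s1, s2)
  obs <- score_split(obs_idx)
  de_obs <- de_score(obs$e_c1, obs$e_c2, obs$e_s1, obs$e_s2,
                     epsilon = epsilon, statistic = statistic)

  n_total <- length(pool)
  n_assign <- choose(n_total, n1)
  exhaustive <- switch(enumeration,
                       auto = is.finite(n_assign) && n_perm >= n_assign,
                       always = TRUE,
                       never = FALSE)
  if (exhaustive && (!is.finite(n_assign) || n_assign > 1e6))
    stop("too many distinct assignments for exhaustive enumeration")
  exceed <- integer(length(de_obs))
  if (exhaustive) {
    message("n_perm >= ", n_assign,
            " distinct assignments; using exhaustive enumeration")
    assigns <- combn(n_total, n1)
    for (k in seq_len(ncol(assigns))) {
      nul <- score_split(assigns[, k])
      de_null <- de_score(nul$e_c1, nul$e_c2, nul$e_s1, nul$e_s2,
                          epsilon = epsilon, statistic = statistic)
      # small tolerance so exact sign-flip ties count as "at least as extreme"
      exceed <- exceed + (abs(de_null) >= abs(de_obs) - 1e-9)
    }
    p_emp <- exceed / n_assign
    n_used <- as.integer(n_assign)
  } else {
    set.seed(seed)
    for (k in seq_len(n_perm)) {
      nul <- score_split(sample.int(n_total, n1))
      de_null <- de_score(nul$e_c1, nul$e_c2, nul$e_s1, nul$e_s2,
                          epsilon = epsilon, statistic = statistic)
      exceed <- exceed + (abs(de_null) >= abs(de_obs) - 1e-9)
    }
    p_emp <- (1 + exceed) / (1 + n_perm)
    n_used <- as.integer(n_perm)
  }

  data.frame(gene = rownames(vals),
             de_score = de_obs,
             cancer_log2fc = obs$e_c2 - obs$e_c1,
             stroma_log2fc = obs$e_s2 - obs$e_s1,
             p_empirical = p_emp,
             q_bh = bh_adjust(p_emp),
             n_permutations = n_used,
             direction = ifelse(de_obs >= 0, "cancer", "stroma"),
             row.names = NULL, stringsAsFactors = FALSE)
}
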