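# Shared fixtures: small synthetic cohorts and independent oracles.

small_cohort <- function(n_per = 10, n_genes = 100, noise_sd = 0,
                         frac_cancer_de = 0.1, seed = 1, ...) {
  cfg <- simulation_config(n_in = n_per, n_mm = n_per, n_sm = 2,
                           n_genes = n_genes, noise_sd = noise_sd,
                           frac_cancer_de = frac_cancer_de,
                           frac_stroma_de = 0, cna_region = NULL,
                           seed = seed, ...)
  ch <- simulate_cohort(cfg)
  ch$purity <- setNames(ch$annotation$purity, ch$annotation$sample)
  ch$labels <- setNames(ch$annotation$group, ch$annotation$sample)
  ch
}

# Hand step-up BH: sort descending, q_i = min(q_(i+1), p_i * m / i).
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  for (i in seq_along(o)) {
    rank <- m - i + 1
    prev <- min(prev, p[o[i]] * m / rank)
    q[o[i]] <- prev
  }
  q
}

# Two-sided Fisher p by exhaustive hypergeometric summation over all 2x2
# tables with the observed margins (point-probability rule).
fisher_by_enumeration <- function(k1, n1, k2, n2) {
  m1 <- k1 + k2
  lo <- max(0, m1 - n2); hi <- min(m1, n1)
  probs <- dhyper(lo:hi, n1, n2, m1)
  p_obs <- dhyper(k1, n1, n2, m1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all
# choose(n1+n2, n1) group assignments of the pooled ranks.
wilcox_by_enumeration <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Random GPR rule generator plus an independent bottom-up evaluator that
# reduces nodes iteratively with na.rm min/max (drop-missing semantics).
random_gpr <- function(depth, genes, p_leaf = 0.4) {
  if (depth <= 0 || runif(1) < p_leaf)
    return(list(gene = sample(genes, 1)))
  op <- sample(c("and", "or"), 1)
  n_args <- sample(2:3, 1)
  args <- lapply(seq_len(n_args), function(i)
    random_gpr(depth - 1, genes, p_leaf))
  # flatten same-op children so the tree is canonical
  flat <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  list(op = op, args = flat)
}

gpr_oracle_eval <- function(node, values) {
  if (!is.null(node$gene)) {
    if (!node$gene %in% names(values)) return(NA_real_)
    return(values[[node$gene]])
  }
  vals <- vapply(node$args, gpr_oracle_eval, numeric(1), values = values)
  if (all(is.na(vals))) return(NA_real_)
  if (node$op == "and") min(vals, na.rm = TRUE) else max(vals, na.rm = TRUE)
}

# k-group log-rank chi-square by direct observed-vs-expected arithmetic.
logrank_by_hand <- function(time, event, group) {
  groups <- sort(unique(group))
  times <- sort(unique(time[event == 1]))
  O <- setNames(numeric(length(groups)), groups)
  E <- O
  V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    d <- sum(event == 1 & time == tt)
    for (g in groups) {
      ng <- sum(at_risk & group == g)
      O[g] <- O[g] + sum(event == 1 & time == tt & group == g)
      E[g] <- E[g] + d * ng / n
    }
    if (n > 1) {
      ng1 <- sum(at_risk & group == groups[1])
      V <- V + d * (ng1 / n) * (1 - ng1 / n) * (n - d) / (n - 1)
    }
  }
  list(O = O, E = E, chisq_2group = (O[1] - E[1])^2 / V)
}
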