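#' Filter and log-transform a linear-scale expression matrix
#'
#' Genes with median expression strictly below `min_median` (default 2,
#' FPKM-like units) are removed; remaining values are log2(X+1)-transformed.
#'
#' @param expr Linear-scale [expression_matrix()].
#' @param min_median Median-expression threshold; a gene whose median equals
#'   the threshold is retained (strict `<` exclusion).
#' @return A log2-scale [expression_matrix()].
#' @export
prepare_expression <- function(expr, min_median = 2) {
  if (expr_scale(expr) != "linear")
    stop("input is already log-transformed; prepare_expression expects linear scale")
  med <- apply(expr, 1L, median, na.rm = TRUE)
  keep <- med >= min_median
  out <- log2(unclass(expr)[keep, , drop = FALSE] + 1)
  expression_matrix(out, scale = "log2")
}

#' Consensus tumor purity across estimation methods
#'
#' Per-sample median of the available method estimates; samples with fewer
#' than two reporting methods get `NA` (insufficient evidence for a
#' consensus).
#'
#' @param table data.frame with a `sample` column and one column per purity
#'   estimation method; estimates must lie in (0, 1] or be `NA`.
#' @return Named numeric vector of consensus purities.
#' @export
consensus_purity <- function(table) {
  if (!is.data.frame(table) || !"sample" %in% names(table))
    stop("purity table needs a `sample` column")
  methods <- setdiff(names(table), "sample")
  if (!length(methods)) stop("purity table needs at least one method column")
  est <- as.matrix(table[methods])
  if (any(est <= 0 | est > 1, na.rm = TRUE))
    stop("purity estimates must lie in (0, 1]")
  n_avail <- rowSums(!is.na(est))
  cons <- apply(est, 1L, median, na.rm = TRUE)
  cons[n_avail < 2L] <- NA_real_
  setNames(cons, table$sample)
}

# Least-squares fit of b ~ p * e_c + (1 - p) * e_s per gene with
# nonnegativity by active set (clamp the negative coefficient to zero and
# re-solve the other). vals: genes x samples, p: purity vector.
fit_two_compartment <- function(vals, p) {
  q <- 1 - p
  spp <- sum(p * p); sqq <- sum(q * q); spq <- sum(p * q)
  bp <- vals %*% p          # per-gene sum(p * b)
  bq <- vals %*% q
  det <- spp * sqq - spq * spq
  e_c <- (sqq * bp - spq * bq) / det
  e_s <- (spp * bq - spq * bp) / det
  # active-set fix-up: candidates with one coefficient pinned at zero
  neg <- which(e_c < 0 | e_s < 0)
  if (length(neg)) {
    ec0 <- pmax(bp[neg] / spp, 0)   # e_s = 0
    es0 <- pmax(bq[neg] / sqq, 0)   # e_c = 0
    ss <- rowSums(vals[neg, , drop = FALSE]^2)
    rss_c <- ss - 2 * ec0 * bp[neg] + ec0^2 * spp
    rss_s <- ss - 2 * es0 * bq[neg] + es0^2 * sqq
    use_c <- rss_c <= rss_s
    e_c[neg] <- ifelse(use_c, ec0, 0)
    e_s[neg] <- ifelse(use_c, 0, es0)
  }
  fitted_ss <- e_c^2 * spp + 2 * e_c * e_s * spq + e_s^2 * sqq
  rss <- pmax(rowSums(vals^2) - 2 * (e_c * bp + e_s * bq) + fitted_ss, 0)
  list(e_c = as.numeric(e_c), e_s = as.numeric(e_s), rss = as.numeric(rss))
}

#' Deconvolute group-level cancer and stroma expression
#'
#' For each gene, fits the two-compartment mixture
#' `b_i ~ p_i * e_c + (1 - p_i) * e_s` by least squares across the group's
#' samples, where `b_i` is the bulk log2(X+1) value and `p_i` the tumor
#' purity of sample `i`. Negative solutions are clamped to zero and the
#' remaining free parameter re-solved. With `mixing_scale = "linear"` the
#' fit is instead performed on de-logged values `2^b - 1` (the physically
#' linear mixture) and estimates are re-logged.
#'
#' @param expr_log log2-scale [expression_matrix()].
#' @param purity Named purity vector covering the group's samples; samples
#'   with `NA` purity are dropped with a warning.
#' @param group_samples Character vector of sample ids forming the group
#'   (default: all columns).
#' @param mixing_scale `"log"` (default; fit on log2 values) or `"linear"`.
#' @param group Optional group label used in messages.
#' @return data.frame (gene, e_c, e_s, rss, n) with attributes
#'   `mixing_scale` and `scale`. In the pure-tumor limit (all purities 1)
#'   `e_c` is the group mean and `e_s` is `NA`; symmetrically for purity 0.
#' @export
deconvolute_group <- function(expr_log, purity, group_samples = NULL,
                              mixing_scale = c("log", "linear"),
                              group = "group") {
  mixing_scale <- match.arg(mixing_scale)
  if (expr_scale(expr_log) != "log2")
    stop("deconvolute_group expects log2-scale expression; run prepare_expression first")
  group_samples <- group_samples %||% colnames(expr_log)
  stopifnot(all(group_samples %in% colnames(expr_log)))
  p <- purity[group_samples]
  if (anyNA(p)) {
    warning(sum(is.na(p)), " sample(s) with NA purity dropped from ", group)
    group_samples <- group_samples[!is.na(p)]
    p <- p[group_samples]
  }
  if (length(group_samples) < 2L)
    stop("fewer than 2 usable samples in ", group)
  vals <- unclass(expr_log)[, group_samples, drop = FALSE]
  genes <- rownames(vals)
  n <- length(group_samples)

  if (all(p == p[1])) {
    if (p[1] == 1)
      return(structure(data.frame(gene = genes, e_c = rowMeans(vals),
                                  e_s = NA_real_, rss = 0, n = n,
                                  row.names = NULL),
                       mixing_scale = mixing_scale))
    if (p[1] == 0)
      return(structure(data.frame(gene = genes, e_c = NA_real_,
                                  e_s = rowMeans(vals), rss = 0, n = n,
                                  row.names = NULL),
                       mixing_scale = mixing_scale))
    stop("singular design in ", group,
         ": all purities equal (", signif(p[1], 3), ")")
  }

  if (mixing_scale == "linear") {
    fit <- fit_two_compartment(2^vals - 1, as.numeric(p))
    e_c <- log2(pmax(fit$e_c, 0) + 1)
    e_s <- log2(pmax(fit$e_s, 0) + 1)
  } else {
    fit <- fit_two_compartment(vals, as.numeric(p))
    e_c <- fit$e_c
    e_s <- fit$e_s
  }
  structure(data.frame(gene = genes, e_c = e_c, e_s = e_s, rss = fit$rss,
                       n = n, row.names = NULL),
            mixing_scale = mixing_scale)
}

#' Compartment profiles for several groups
#'
#' Runs [deconvolute_group()] once per group and stacks the results into the
#' long gene-by-group compartment profile consumed by the DE score and the
#' reaction-scoring stage.
#'
#' @param expr_log log2-scale [expression_matrix()].
#' @param purity Named purity vector.
#' @param labels Named group label vector (names = sample ids).
#' @param groups Groups to deconvolute (default: all label levels).
#' @inheritParams deconvolute_group
#' @return data.frame (gene, group, e_c, e_s, rss, n).
#' @export
compartment_profile <- function(expr_log, purity, labels, groups = NULL,
                                mixing_scale = c("log", "linear")) {
  mixing_scale <- match.arg(mixing_scale)
  groups <- groups %||% unique(labels)
  out <- lapply(groups, function(g) {
    smp <- intersect(names(labels)[labels == g], colnames(expr_log))
    prof <- deconvolute_group(expr_log, purity, smp,
                              mixing_scale = mixing_scale, group = g)
    cbind(gene = prof$gene, group = g, prof[c("e_c", "e_s", "rss", "n")])
  })
  res <- do.call(rbind, out)
  attr(res, "mixing_scale") <- mixing_scale
  res
}
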