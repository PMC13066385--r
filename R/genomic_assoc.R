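#' Map copy-number segments to gene-level values
#'
#' Each gene's value is the overlap-length-weighted mean of the segment
#' means of all segments overlapping it; genes in unsegmented gaps get
#' `NA`. Coordinates are 0-based half-open throughout (use [read_seg()] to
#' convert SEG files, which are 1-based inclusive by convention).
#'
#' @param segments data.frame (sample, chrom, start, end, seg_mean),
#'   0-based half-open.
#' @param genes data.frame (gene, chrom, start, end), 0-based half-open.
#' @return Numeric gene-by-sample matrix of copy-number values.
#' @export
map_segments_to_genes <- function(segments, genes) {
  req <- c("sample", "chrom", "start", "end", "seg_mean")
  if (!all(req %in% names(segments)))
    stop("segments must have columns: ", paste(req, collapse = ", "))
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    wsum <- numeric(nrow(genes))
    wtot <- numeric(nrow(genes))
    for (k in seq_len(nrow(seg))) {
      same <- genes$chrom == seg$chrom[k]
      ov <- pmin(genes$end, seg$end[k]) - pmax(genes$start, seg$start[k])
      w <- ifelse(same & ov > 0, ov, 0)
      wsum <- wsum + w * seg$seg_mean[k]
      wtot <- wtot + w
    }
    out[wtot > 0, s] <- wsum[wtot > 0] / wtot[wtot > 0]
  }
  out
}

#' Two-group Wilcoxon rank-sum test per row
#'
#' Compares each row of a feature-by-sample matrix between two cohorts with
#' a two-tailed Wilcoxon rank-sum test (exact when both groups have at most
#' 10 non-missing values and no ties; otherwise the tie-corrected normal
#' approximation with continuity correction). Used for locus-level
#' copy-number values, bulk expression, and cell-type abundances. The
#' abundance filter drops rows without a fraction above `min_fraction` in
#' at least `min_samples` samples before testing.
#'
#' @param values Numeric feature-by-sample matrix.
#' @param labels Named group label vector.
#' @param groups Length-2 character vector `c(group1, group2)`.
#' @param abundance_filter Apply the abundance rule before testing?
#' @param min_fraction,min_samples Abundance rule: keep rows with value
#'   `> min_fraction` in at least `min_samples` samples (defaults 0.1 / 5).
#' @param q_threshold Significance threshold on the BH q-value (default
#'   0.25) used for the `significant` flag.
#' @return data.frame (feature, statistic, p, q, significant).
#' @export
two_group_locus_test <- function(values, labels, groups,
                                 abundance_filter = FALSE,
                                 min_fraction = 0.1, min_samples = 5L,
                                 q_threshold = 0.25) {
  assert_two_groups(labels, groups)
  s1 <- intersect(names(labels)[labels == groups[1]], colnames(values))
  s2 <- intersect(names(labels)[labels == groups[2]], colnames(values))
  if (abundance_filter) {
    keep <- rowSums(values > min_fraction, na.rm = TRUE) >= min_samples
    values <- values[keep, , drop = FALSE]
  }
  if (!nrow(values)) stop("no rows left to test after filtering")
  res <- t(apply(values, 1L, function(v) {
    x <- v[s1]; y <- v[s2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(c(NA_real_, NA_real_))
    ties <- anyDuplicated(c(x, y)) > 0L
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided",
                  exact = length(x) <= 10L && length(y) <= 10L && !ties,
                  correct = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }))
  p <- res[, 2L]
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  data.frame(feature = rownames(values), statistic = res[, 1L], p = p,
             q = q, significant = !is.na(q) & q < q_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene mutation-frequency Fisher test
#'
#' For each gene, builds the 2x2 carrier/non-carrier by group table and
#' applies the two-sided Fisher exact test (point-probability rule: the
#' p-value sums the probabilities of all tables, with fixed margins, no
#' more probable than the observed one).
#'
#' @param mut Binary gene-by-sample carrier matrix (1 = carries a
#'   non-silent variant).
#' @param labels Named group label vector.
#' @param groups Length-2 character vector `c(group1, group2)`.
#' @return data.frame (gene, carriers_1, n_1, carriers_2, n_2, odds_ratio,
#'   p, q).
#' @export
mutation_fisher_test <- function(mut, labels, groups) {
  assert_two_groups(labels, groups)
  if (!all(mut %in% c(0, 1))) stop("mutation matrix must be binary")
  s1 <- intersect(names(labels)[labels == groups[1]], colnames(mut))
  s2 <- intersect(names(labels)[labels == groups[2]], colnames(mut))
  res <- t(apply(mut, 1L, function(v) {
    k1 <- sum(v[s1]); k2 <- sum(v[s2])
    tab <- matrix(c(k1, length(s1) - k1, k2, length(s2) - k2), 2L)
    ft <- fisher.test(tab, alternative = "two.sided")
    c(k1, length(s1), k2, length(s2), unname(ft$estimate), ft$p.value)
  }))
  data.frame(gene = rownames(mut),
             carriers_1 = res[, 1L], n_1 = res[, 2L],
             carriers_2 = res[, 3L], n_2 = res[, 4L],
             odds_ratio = res[, 5L], p = res[, 6L],
             q = bh_adjust(res[, 6L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a binary carrier matrix from MAF-lite mutation calls
#'
#' A sample carries a gene when it has at least one variant whose class is
#' not in `silent_classes`.
#'
#' @param maf data.frame with columns sample, gene, variant_class.
#' @param samples Sample universe (columns of the output; samples without
#'   calls are non-carriers).
#' @param silent_classes Variant classes that do not count as carrier
#'   events.
#' @return Binary gene-by-sample matrix.
#' @export
build_mutation_matrix <- function(maf, samples,
                                  silent_classes = c("Silent", "Synonymous",
                                                     "Intron", "3'UTR",
                                                     "5'UTR", "IGR",
                                                     "RNA")) {
  req <- c("sample", "gene", "variant_class")
  if (!all(req %in% names(maf)))
    stop("MAF-lite table must have columns: ", paste(req, collapse = ", "))
  maf <- maf[!maf$variant_class %in% silent_classes, , drop = FALSE]
  genes <- sort(unique(maf$gene))
  out <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  hit <- maf$sample %in% samples
  out[cbind(match(maf$gene[hit], genes), match(maf$sample[hit], samples))] <- 1L
  out
}

#' Correlation between gene-level copy number and bulk expression
#'
#' Pearson correlation (with two-sided t-test p-value) per gene between
#' copy-number values and bulk expression, computed over all samples and,
#' when labels are given, within each cohort.
#'
#' @param cna Gene-by-sample copy-number matrix ([map_segments_to_genes()]).
#' @param expr [expression_matrix()] sharing gene and sample ids with `cna`.
#' @param labels Optional named group label vector for per-cohort results.
#' @param min_pairs Minimum paired non-missing observations (default 3).
#' @return data.frame (gene, cohort, r, p, n); `r` is `NA` (with one
#'   warning) for zero-variance or under-populated pairs.
#' @export
cna_expression_correlation <- function(cna, expr, labels = NULL,
                                       min_pairs = 3L) {
  genes <- intersect(rownames(cna), rownames(expr))
  samples <- intersect(colnames(cna), colnames(expr))
  if (!length(genes) || !length(samples))
    stop("cna and expr share no genes or samples")
  cohorts <- c(list(all = samples),
               if (!is.null(labels))
                 split(intersect(names(labels), samples),
                       labels[intersect(names(labels), samples)]))
  n_degenerate <- 0L
  out <- lapply(names(cohorts), function(ch) {
    smp <- cohorts[[ch]]
    res <- t(vapply(genes, function(g) {
      x <- cna[g, smp]; y <- as.numeric(unclass(expr)[g, smp])
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_pairs || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        n_degenerate <<- n_degenerate + 1L
        return(c(NA_real_, NA_real_, sum(ok)))
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      c(unname(ct$estimate), ct$p.value, sum(ok))
    }, numeric(3)))
    data.frame(gene = genes, cohort = ch, r = res[, 1L], p = res[, 2L],
               n = as.integer(res[, 3L]), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  if (n_degenerate)
    warning(n_degenerate,
            " gene/cohort pair(s) with constant or insufficient data: NA")
  do.call(rbind, out)
}

#' One-sided Fisher pathway enrichment
#'
#' Hypergeometric upper-tail (enrichment) test of a significant gene list
#' against each gene set, restricted to a background universe. Significant
#' genes outside the background are dropped (count reported via message);
#' sets are intersected with the background before testing.
#'
#' @param sig_genes Character vector of significant genes.
#' @param collection List with `sets` (named list of gene id vectors) and
#'   `background` (character universe), as returned by [read_gmt()] plus a
#'   background.
#' @return data.frame (set, set_size, overlap, p, q).
#' @export
pathway_enrichment <- function(sig_genes, collection) {
  background <- unique(collection$background)
  if (!length(background)) stop("empty background universe")
  dropped <- setdiff(sig_genes, background)
  if (length(dropped))
    message(length(dropped), " significant gene(s) outside the background dropped")
  sig <- unique(intersect(sig_genes, background))
  N <- length(background)
  n_draw <- length(sig)
  res <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], background)
    if (!length(set)) return(NULL)
    k <- length(intersect(sig, set))
    K <- length(set)
    p <- if (n_draw == 0L) 1 else phyper(k - 1L, K, N - K, n_draw,
                                         lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no gene set overlaps the background")
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}
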