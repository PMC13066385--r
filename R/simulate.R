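#' Configuration for the synthetic ccRCC-like cohort generator
#'
#' Defaults mirror the study conditions the downstream analyses assume:
#' cohort sizes IN = 68, MM = 44, SM = 80; tumor purity uniform on
#' (0.25, 0.85); administrative censoring at 96 months (8 years of
#' follow-up) with uniform loss-to-follow-up calibrated so that the median
#' follow-up of censored patients is about 51 months.
#'
#' @param n_in,n_mm,n_sm Samples per cohort (indolent, metachronous
#'   metastatic, synchronous metastatic); each must be >= 2.
#' @param n_genes Number of genes.
#' @param purity_range Length-2 interval strictly inside (0, 1); per-sample
#'   tumor purity is drawn uniformly from it.
#' @param frac_cancer_de,frac_stroma_de,frac_both_de Fractions of genes with
#'   a planted MM-vs-IN fold-change restricted to the cancer compartment,
#'   the stroma compartment, or present in both. Fractions must lie in
#'   [0, 1] and sum to at most 1.
#' @param log2fc_magnitude Absolute planted effect size on the log2(X+1)
#'   scale (1 = a 2-fold change of the linear compartment abundance).
#' @param de_direction Sign convention of planted changes: `"up"`
#'   (default), `"down"`, or `"random"` (per-gene coin flip). The DE
#'   score's sign identifies the changed compartment only for positive
#'   changes, so the reference scenario plants up-regulation.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   log2(X+1) bulk values.
#' @param cna_region List describing one contiguous copy-number-loss region:
#'   `chrom`, `start`, `end` (0-based half-open gene coordinates),
#'   `loss_frequency` (named per-group probabilities of a one-copy loss) and
#'   `dosage_slope` (log2 expression shift per copy lost). `NULL` disables
#'   the copy-number scenario.
#' @param baseline_hazard_rate Baseline exponential hazard of metastasis,
#'   per month; must be positive.
#' @param planted_betas Named numeric vector mapping gene ids to log hazard
#'   ratios per 1-SD of bulk log2 expression.
#' @param censor_time_months Administrative censoring horizon.
#' @param dropout_max_months Upper bound of the uniform loss-to-follow-up
#'   time. The default 114 calibrates the median follow-up of censored
#'   (indolent-like) patients to about 51 months under the default baseline
#'   hazard, accounting for shorter censoring times being more likely to
#'   precede the event.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_in = 68L, n_mm = 44L, n_sm = 80L,
                              n_genes = 1000L,
                              purity_range = c(0.25, 0.85),
                              frac_cancer_de = 0.05,
                              frac_stroma_de = 0.05,
                              frac_both_de = 0,
                              log2fc_magnitude = 1,
                              de_direction = c("up", "down", "random"),
                              noise_sd = 0.2,
                              cna_region = list(
                                chrom = 1L, start = 100L, end = 200L,
                                loss_frequency = c(IN = 0.1, MM = 0.6, SM = 0.3),
                                dosage_slope = 0.5),
                              baseline_hazard_rate = 0.004,
                              planted_betas = numeric(0),
                              censor_time_months = 96,
                              dropout_max_months = 114,
                              seed = 1L) {
  cfg <- list(n_in = as.integer(n_in), n_mm = as.integer(n_mm),
              n_sm = as.integer(n_sm), n_genes = as.integer(n_genes),
              purity_range = as.numeric(purity_range),
              frac_cancer_de = frac_cancer_de,
              frac_stroma_de = frac_stroma_de,
              frac_both_de = frac_both_de,
              log2fc_magnitude = log2fc_magnitude,
              de_direction = match.arg(de_direction),
              noise_sd = noise_sd,
              cna_region = cna_region,
              baseline_hazard_rate = baseline_hazard_rate,
              planted_betas = planted_betas,
              censor_time_months = censor_time_months,
              dropout_max_months = dropout_max_months,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_in, n_mm, n_sm) < 2L)) stop("cohort sizes must be >= 2")
    if (n_genes < 1L) stop("n_genes must be positive")
    fr <- c(frac_cancer_de, frac_stroma_de, frac_both_de)
    if (any(fr < 0) || any(fr > 1)) stop("DE fractions must lie in [0, 1]")
    if (sum(fr) > 1) stop("DE fractions must sum to at most 1")
    if (length(purity_range) != 2L ||
        purity_range[1] <= 0 || purity_range[2] >= 1)
      stop("purity_range must lie strictly inside (0, 1)")
    if (purity_range[1] >= purity_range[2])
      stop("degenerate purity interval: lower bound must be below upper")
    if (noise_sd < 0) stop("noise_sd must be nonnegative")
    if (baseline_hazard_rate <= 0) stop("baseline hazard must be positive")
    if (censor_time_months <= 0 || dropout_max_months <= 0)
      stop("censoring times must be positive")
    if (!is.null(cna_region)) {
      n_chrom <- ceiling(n_genes / 1000)
      if (cna_region$chrom < 1L || cna_region$chrom > n_chrom ||
          cna_region$start < 0 || cna_region$end > 1000 ||
          cna_region$start >= cna_region$end)
        stop("cna_region lies outside the simulated coordinate space")
    }
  })
  invisible(cfg)
}

#' Deterministic synthetic gene coordinates
#'
#' The synthetic genome places 1000 genes per chromosome at unit spacing:
#' gene i sits on chromosome `ceiling(i/1000)` with 0-based half-open
#' interval `[(i-1) mod 1000, (i-1) mod 1000 + 1)`.
#'
#' @param n_genes Number of genes.
#' @return data.frame with columns gene, chrom, start, end.
#' @export
gene_coordinates <- function(n_genes) {
  i <- seq_len(n_genes)
  data.frame(gene = sprintf("g%04d", i),
             chrom = as.integer(ceiling(i / 1000)),
             start = as.integer((i - 1L) %% 1000L),
             end = as.integer((i - 1L) %% 1000L + 1L),
             stringsAsFactors = FALSE)
}

#' Simulate a purity-mixed two-compartment cohort
#'
#' Generates ground-truth cancer and stroma compartment profiles per group,
#' draws per-sample purity, mixes the compartments on the linear scale
#' (`bulk = purity * X_cancer + (1 - purity) * X_stroma` with
#' `X = 2^e - 1`), applies the copy-number dosage effect, adds Gaussian
#' noise on the log2(X+1) scale, and simulates right-censored
#' time-to-metastasis from gene-linked hazards.
#'
#' @param config A [simulation_config()].
#' @return List with components:
#'   `expression` (linear-scale [expression_matrix()]),
#'   `annotation` (data.frame: sample, group, purity, time_months, event),
#'   `truth` (list: cancer_expr / stroma_expr gene-by-group matrices of
#'   true log2(X+1) compartment expression, `de_labels` in
#'   cancer/stroma/both/none, `de_sign`, `cna_matrix`, `segments`,
#'   `true_betas`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(stage_seed(config$seed, "expression"))

  groups <- c("IN", "MM", "SM")
  n_per <- c(IN = config$n_in, MM = config$n_mm, SM = config$n_sm)
  sample_group <- rep(groups, times = n_per)
  sample_ids <- sprintf("%s_%03d", sample_group, unlist(lapply(n_per, seq_len)))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  G <- config$n_genes

  # baseline compartment profiles (log2(X+1) scale), shared across groups
  e_c_base <- runif(G, 2, 8)
  e_s_base <- pmax(e_c_base + rnorm(G, 0, 1), 0)

  # planted MM-vs-IN fold changes in the named compartment(s)
  n_c <- round(config$frac_cancer_de * G)
  n_s <- round(config$frac_stroma_de * G)
  n_b <- round(config$frac_both_de * G)
  idx <- sample.int(G, n_c + n_s + n_b)
  de_labels <- rep("none", G)
  de_labels[idx[seq_len(n_c)]] <- "cancer"
  if (n_s) de_labels[idx[n_c + seq_len(n_s)]] <- "stroma"
  if (n_b) de_labels[idx[n_c + n_s + seq_len(n_b)]] <- "both"
  de_sign <- switch(config$de_direction,
                    up = rep(1, G),
                    down = rep(-1, G),
                    random = ifelse(runif(G) < 0.5, -1, 1)) *
    (de_labels != "none")

  cancer_expr <- matrix(e_c_base, G, 3, dimnames = list(genes, groups))
  stroma_expr <- matrix(e_s_base, G, 3, dimnames = list(genes, groups))
  shift <- de_sign * config$log2fc_magnitude
  in_cancer <- de_labels %in% c("cancer", "both")
  in_stroma <- de_labels %in% c("stroma", "both")
  cancer_expr[in_cancer, "MM"] <- pmax(cancer_expr[in_cancer, "MM"] +
                                         shift[in_cancer], 0)
  stroma_expr[in_stroma, "MM"] <- pmax(stroma_expr[in_stroma, "MM"] +
                                         shift[in_stroma], 0)

  purity <- runif(length(sample_ids), config$purity_range[1],
                  config$purity_range[2])
  names(purity) <- sample_ids

  # linear-scale mixture per sample
  gi <- match(sample_group, groups)
  x_c <- 2^cancer_expr - 1
  x_s <- 2^stroma_expr - 1
  bulk <- x_c[, gi, drop = FALSE] %*% diag(purity) +
    x_s[, gi, drop = FALSE] %*% diag(1 - purity)
  # the diag() products above scale columns; rebuild names
  dimnames(bulk) <- list(genes, sample_ids)

  annotation <- data.frame(sample = sample_ids, group = sample_group,
                           purity = unname(purity),
                           stringsAsFactors = FALSE)

  cna <- simulate_cna_segments(config, annotation)
  log_bulk <- log2(bulk + 1)
  if (!is.null(cna$cna_matrix)) {
    log_bulk <- log_bulk + config$cna_region$dosage_slope * cna$cna_matrix
    log_bulk <- pmax(log_bulk, 0)
  }
  set.seed(stage_seed(config$seed, "noise"))
  if (config$noise_sd > 0)
    log_bulk <- pmax(log_bulk + matrix(rnorm(length(log_bulk), 0,
                                             config$noise_sd),
                                       nrow(log_bulk)), 0)
  expression <- expression_matrix(2^log_bulk - 1, scale = "linear")

  surv <- simulate_survival_labels(config, expression)
  annotation$time_months <- surv$time_months[annotation$sample]
  annotation$event <- surv$event[annotation$sample]

  truth <- list(cancer_expr = cancer_expr, stroma_expr = stroma_expr,
                de_labels = setNames(de_labels, genes),
                de_sign = setNames(de_sign, genes),
                cna_matrix = cna$cna_matrix, segments = cna$segments,
                true_betas = config$planted_betas)
  list(expression = expression, annotation = annotation, truth = truth)
}

#' Simulate copy-number segments with a planted loss region
#'
#' Draws, per sample, a one-copy loss of the configured contiguous region
#' with its group-specific frequency, and emits both a segment table and the
#' gene-level copy-number-change matrix (0 = neutral, -1 = one copy lost).
#' The dosage effect on expression (`dosage_slope` per copy lost) is applied
#' by [simulate_cohort()].
#'
#' @param config A [simulation_config()].
#' @param annotation Sample annotation with `sample` and `group` columns.
#' @return List with `segments` (data.frame: sample, chrom, start, end,
#'   seg_mean; 0-based half-open) and `cna_matrix` (gene x sample), or
#'   `NULL` components when the scenario is disabled.
#' @export
simulate_cna_segments <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$cna_region))
    return(list(segments = NULL, cna_matrix = NULL))
  region <- config$cna_region
  coords <- gene_coordinates(config$n_genes)
  set.seed(stage_seed(config$seed, "cna"))

  freq <- region$loss_frequency[annotation$group]
  if (anyNA(freq))
    stop("loss_frequency must name every group present in the annotation")
  lost <- rbinom(nrow(annotation), 1L, freq) == 1L

  in_region <- coords$chrom == region$chrom &
    coords$start >= region$start & coords$end <= region$end
  cna_matrix <- matrix(0, config$n_genes, nrow(annotation),
                       dimnames = list(coords$gene, annotation$sample))
  cna_matrix[in_region, lost] <- -1

  chrom_len <- 1000L
  segs <- lapply(seq_len(nrow(annotation)), function(i) {
    s <- annotation$sample[i]
    if (!lost[i]) {
      data.frame(sample = s, chrom = region$chrom, start = 0L,
                 end = chrom_len, seg_mean = 0)
    } else {
      data.frame(sample = s,
                 chrom = region$chrom,
                 start = c(0L, region$start, region$end),
                 end = c(region$start, region$end, chrom_len),
                 seg_mean = c(0, -1, 0))
    }
  })
  segments <- do.call(rbind, segs)
  segments <- segments[segments$start < segments$end, , drop = FALSE]
  rownames(segments) <- NULL
  list(segments = segments, cna_matrix = cna_matrix)
}

#' Simulate right-censored time-to-metastasis from gene-linked hazards
#'
#' Event times are exponential with per-sample hazard
#' `baseline * exp(sum_g beta_g * z_g)`, where `z_g` is the z-scored bulk
#' log2(X+1) expression of gene `g`. Censoring is the minimum of the
#' administrative horizon and a uniform loss-to-follow-up time.
#'
#' @param config A [simulation_config()]; `planted_betas` must reference
#'   genes present in `expr`.
#' @param expr Linear-scale [expression_matrix()].
#' @return List of named vectors `time_months` (> 0) and `event`
#'   (1 = metastasis, 0 = censored).
#' @export
simulate_survival_labels <- function(config, expr) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$baseline_hazard_rate <= 0)
    stop("baseline hazard must be positive")
  betas <- config$planted_betas
  if (length(betas) && !all(names(betas) %in% rownames(expr)))
    stop("planted_betas reference genes absent from the expression matrix")
  set.seed(stage_seed(config$seed, "survival"))

  n <- ncol(expr)
  lp <- rep(0, n)
  if (length(betas)) {
    z <- t(scale(t(log2(expr[names(betas), , drop = FALSE] + 1))))
    z[is.nan(z)] <- 0
    lp <- as.numeric(crossprod(z, betas))
  }
  hazard <- config$baseline_hazard_rate * exp(lp)
  t_event <- rexp(n, rate = hazard)
  t_censor <- pmin(config$censor_time_months,
                   runif(n, 0, config$dropout_max_months))
  time <- pmax(pmin(t_event, t_censor), 1e-6)
  event <- as.integer(t_event <= t_censor)
  list(time_months = setNames(time, colnames(expr)),
       event = setNames(event, colnames(expr)))
}
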