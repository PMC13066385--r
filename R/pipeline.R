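#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "deconvolute", "de_test", "cna_test", "risk_cv")`,
#'   executed in dependency order.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   via [stage_seed()].
#' @param simulation A [simulation_config()] for the simulate stage
#'   (default configuration if omitted).
#' @param min_median Expression filter threshold (default 2).
#' @param n_perm Permutations for the DE stage (study default 50000).
#' @param groups The two cohorts compared (default IN vs MM).
#' @param q_threshold Significance threshold (default 0.25).
#' @param signature Feature columns for the risk model; `NULL` selects the
#'   top 5 genes from the univariate screen.
#' @param k,repeats,target_sensitivity Cross-validation settings
#'   (defaults 5, 100, 0.878).
#' @param expression,annotation,purity Optional paths to input TSVs used
#'   when the simulate stage is disabled.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "deconvolute", "de_test"),
                       seed = 1L,
                       simulation = NULL,
                       min_median = 2,
                       n_perm = 50000L,
                       groups = c("IN", "MM"),
                       q_threshold = 0.25,
                       signature = NULL,
                       k = 5L, repeats = 100L,
                       target_sensitivity = 0.878,
                       expression = NULL, annotation = NULL,
                       purity = NULL) {
  known <- c("simulate", "deconvolute", "de_test", "cna_test", "risk_cv")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 simulation = simulation, min_median = min_median,
                 n_perm = as.integer(n_perm), groups = groups,
                 q_threshold = q_threshold, signature = signature,
                 k = as.integer(k), repeats = as.integer(repeats),
                 target_sensitivity = target_sensitivity,
                 expression = expression, annotation = annotation,
                 purity = purity),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level YAML keys map to [run_config()] arguments; the optional
#' `simulation` block maps to [simulation_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulation_config, y$simulation)
  do.call(run_config, y)
}

#' Run the analysis pipeline
#'
#' Validates stage dependencies (failing before any computation), executes
#' the enabled stages in order, writes each stage's outputs as TSV under
#' the configured output directory, and returns (and writes) a manifest
#' with package version, per-stage seeds, timings and output checksums.
#' Re-running an identical configuration reproduces identical checksums.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return The manifest, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages

  needs <- list(de_test = "deconvolute")
  for (st in stages) {
    for (dep in needs[[st]] %||% character())
      if (!dep %in% stages)
        stop("stage '", st, "' requires stage '", dep, "' to be enabled")
  }
  if (!"simulate" %in% stages) {
    need_inputs <- c("expression", "annotation", "purity")
    missing <- need_inputs[vapply(config[need_inputs], is.null, logical(1))]
    if (length(intersect(stages,
                         c("deconvolute", "de_test", "cna_test", "risk_cv")))
        && length(missing))
      stop("without the simulate stage, input path(s) required: ",
           paste(missing, collapse = ", "))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "deconvMM",
                   version = as.character(utils::packageVersion("deconvMM")),
                   master_seed = config$seed, stages = list())
  outputs <- character()
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    round(proc.time()[["elapsed"]] - t0, 3)
  }

  expr <- ann <- purity <- profile <- NULL

  if ("simulate" %in% stages) {
    sim_cfg <- config$simulation %||% simulation_config(seed = config$seed)
    el <- t_stage({
      cohort <- simulate_cohort(sim_cfg)
      expr <- cohort$expression
      ann <- cohort$annotation
      purity <- setNames(ann$purity, ann$sample)
      f_expr <- file.path(config$out_dir, "expression.tsv")
      f_ann <- file.path(config$out_dir, "annotation.tsv")
      write_expression_tsv(expr, f_expr)
      write_tsv(ann, f_ann)
      if (!is.null(cohort$truth$segments))
        write_seg(cohort$truth$segments,
                  file.path(config$out_dir, "segments.seg"))
      outputs <<- c(outputs, f_expr, f_ann)
    })
    manifest$stages$simulate <- list(
      seed = stage_seed(sim_cfg$seed, "expression"), elapsed = el)
  } else {
    expr <- read_expression_tsv(config$expression)
    ann <- read_annotation_tsv(config$annotation)
    pt <- read_purity_tsv(config$purity)
    purity <- if (ncol(pt) > 2L) consensus_purity(pt)
      else setNames(pt[[2]], pt[[1]])
  }

  if ("deconvolute" %in% stages) {
    el <- t_stage({
      expr_log <- prepare_expression(expr, min_median = config$min_median)
      labels <- setNames(ann$group, ann$sample)
      profile <- compartment_profile(expr_log, purity, labels,
                                     groups = config$groups)
      f <- file.path(config$out_dir, "compartment_profile.tsv")
      write_tsv(profile, f)
      outputs <<- c(outputs, f)
    })
    manifest$stages$deconvolute <- list(elapsed = el)
  }

  if ("de_test" %in% stages) {
    el <- t_stage({
      expr_log <- prepare_expression(expr, min_median = config$min_median)
      labels <- setNames(ann$group, ann$sample)
      de <- permutation_de_test(expr_log, purity, labels, config$groups,
                                n_perm = config$n_perm,
                                seed = stage_seed(config$seed, "de_test"))
      f <- file.path(config$out_dir, "de_results.tsv")
      write_tsv(de, f)
      outputs <<- c(outputs, f)
    })
    manifest$stages$de_test <- list(
      seed = stage_seed(config$seed, "de_test"), elapsed = el)
  }

  if ("cna_test" %in% stages) {
    el <- t_stage({
      seg_path <- file.path(config$out_dir, "segments.seg")
      if (!file.exists(seg_path))
        stop("cna_test requires a segments.seg produced by the simulate stage")
      segments <- read_seg(seg_path)
      genes <- gene_coordinates(nrow(expr))
      genes <- genes[genes$gene %in% rownames(expr), , drop = FALSE]
      cna <- map_segments_to_genes(segments, genes)
      labels <- setNames(ann$group, ann$sample)
      res <- two_group_locus_test(cna, labels, config$groups,
                                  q_threshold = config$q_threshold)
      f <- file.path(config$out_dir, "cna_test.tsv")
      write_tsv(res, f)
      outputs <<- c(outputs, f)
    })
    manifest$stages$cna_test <- list(elapsed = el)
  }

  if ("risk_cv" %in% stages) {
    el <- t_stage({
      expr_log <- prepare_expression(expr, min_median = config$min_median)
      sub <- ann[ann$group %in% config$groups, , drop = FALSE]
      feats <- as.data.frame(t(unclass(expr_log)[, sub$sample, drop = FALSE]))
      tab <- build_feature_table(feats, sub)
      sig <- config$signature
      if (is.null(sig)) {
        screen <- univariate_cox_screen(tab)
        sig <- head(screen$feature[screen$converged], 5L)
      }
      cv <- repeated_cv_evaluate(tab, sig, k = config$k,
                                 repeats = config$repeats,
                                 target_sensitivity = config$target_sensitivity,
                                 seed = stage_seed(config$seed, "risk_cv"))
      f <- file.path(config$out_dir, "cv_report.tsv")
      write_tsv(cv$per_repeat, f)
      outputs <<- c(outputs, f)
    })
    manifest$stages$risk_cv <- list(
      seed = stage_seed(config$seed, "risk_cv"), elapsed = el)
  }

  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
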