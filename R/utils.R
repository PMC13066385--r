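#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from the master seed and a short stage tag, so stages can be re-run in
#' isolation without perturbing each other's random streams.
#'
#' @param seed Master seed (integer).
#' @param tag Character stage tag, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 131) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an expression matrix with an explicit scale flag
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param scale Either `"linear"` (nonnegative FPKM-like abundances) or
#'   `"log2"` (log2(X+1)-transformed values).
#' @return The matrix with attribute `scale` set and class
#'   `expression_matrix` prepended.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop("negative entries in a linear-scale expression matrix")
  attr(values, "scale") <- scale
  class(values) <- c("expression_matrix", class(values))
  values
}

expr_scale <- function(x) attr(x, "scale") %||% "linear"

assert_two_groups <- function(labels, groups) {
  if (length(groups) != 2L) stop("exactly two groups must be compared")
  missing <- setdiff(groups, unique(labels))
  if (length(missing))
    stop("group(s) not present in labels: ", paste(missing, collapse = ", "))
  invisible(groups)
}
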