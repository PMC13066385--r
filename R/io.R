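#' Read / write the package's tab-separated interchange formats
#'
#' Expression tables have gene rows (first column `gene`) and sample
#' columns; annotation tables carry sample, group, purity, time_months,
#' event; SEG files follow the segmented copy-number convention (sample,
#' chrom, start, end, seg_mean; 1-based inclusive on disk, converted to
#' 0-based half-open in memory); GMT files are the usual
#' name / description / genes... layout; MAF-lite is sample, gene,
#' variant_class; GPR rule tables are reaction_id, subsystem, rule.
#'
#' @param path File path.
#' @param scale Scale flag for the expression matrix being read.
#' @name deconvmm_io
NULL

#' @rdname deconvmm_io
#' @export
read_expression_tsv <- function(path, scale = "linear") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, scale = scale)
}

#' @rdname deconvmm_io
#' @param expr Expression matrix to write.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname deconvmm_io
#' @export
read_annotation_tsv <- function(path)
  read.delim(path, stringsAsFactors = FALSE)

#' @rdname deconvmm_io
#' @param df Table to write.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname deconvmm_io
#' @export
read_purity_tsv <- function(path)
  read.delim(path, stringsAsFactors = FALSE)

#' @rdname deconvmm_io
#' @export
read_seg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) != 5L)
    stop("malformed SEG file: expected 5 columns, found ", ncol(df))
  names(df) <- c("sample", "chrom", "start", "end", "seg_mean")
  # SEG is 1-based inclusive; internal convention is 0-based half-open
  df$start <- df$start - 1L
  df
}

#' @rdname deconvmm_io
#' @param segments In-memory segment table (0-based half-open).
#' @export
write_seg <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1L   # back to 1-based inclusive on disk
  names(out) <- c("sample", "chrom", "loc.start", "loc.end", "seg.mean")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname deconvmm_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname deconvmm_io
#' @export
read_maf_lite <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "gene", "variant_class")
  if (!all(req %in% names(df)))
    stop("MAF-lite file must have columns: ", paste(req, collapse = ", "))
  df
}

#' @rdname deconvmm_io
#' @export
read_gpr_rules <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("reaction_id", "subsystem", "rule")
  if (!all(req %in% names(df)))
    stop("GPR rule table must have columns: ", paste(req, collapse = ", "))
  df
}
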