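#' Parse a gene-protein-reaction boolean rule
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := gene | "(" expr ")"`. `and` binds tighter than `or`;
#' operators are case-insensitive; chains of the same operator are
#' flattened into one n-ary node. Errors (unbalanced parentheses, dangling
#' operator, empty rule) report the offending character position.
#'
#' @param rule_text Rule string, e.g. `"(A and B) or C"`.
#' @return A `gpr_rule` tree: leaves are `list(gene = id)`, internal nodes
#'   `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  toks <- gpr_tokenize(rule_text)
  if (!nrow(toks)) stop("empty rule")
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L
  tree <- gpr_parse_or(state)
  if (state$i <= nrow(state$toks))
    stop("unexpected token '", state$toks$text[state$i],
         "' at position ", state$toks$pos[state$i])
  class(tree) <- "gpr_rule"
  tree
}

gpr_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(data.frame(text = character(), pos = integer()))
  txt <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  data.frame(text = txt, pos = as.integer(m), stringsAsFactors = FALSE)
}

gpr_peek <- function(state) {
  if (state$i > nrow(state$toks)) NULL else state$toks$text[state$i]
}
gpr_pos <- function(state) {
  if (state$i > nrow(state$toks)) NA_integer_ else state$toks$pos[state$i]
}
gpr_is_op <- function(tok) !is.null(tok) && tolower(tok) %in% c("and", "or")

gpr_parse_or <- function(state) {
  args <- list(gpr_parse_and(state))
  while (!is.null(tok <- gpr_peek(state)) && tolower(tok) == "or") {
    state$i <- state$i + 1L
    args <- c(args, list(gpr_parse_and(state)))
  }
  if (length(args) == 1L) args[[1]] else gpr_flatten("or", args)
}

gpr_parse_and <- function(state) {
  args <- list(gpr_parse_factor(state))
  while (!is.null(tok <- gpr_peek(state)) && tolower(tok) == "and") {
    state$i <- state$i + 1L
    args <- c(args, list(gpr_parse_factor(state)))
  }
  if (length(args) == 1L) args[[1]] else gpr_flatten("and", args)
}

gpr_parse_factor <- function(state) {
  tok <- gpr_peek(state)
  pos <- gpr_pos(state)
  if (is.null(tok))
    stop("dangling operator: expected a gene or '(' at end of rule")
  if (gpr_is_op(tok))
    stop("dangling operator '", tok, "' at position ", pos)
  if (tok == ")")
    stop("unbalanced parentheses: unexpected ')' at position ", pos)
  if (tok == "(") {
    state$i <- state$i + 1L
    inner <- gpr_parse_or(state)
    if (is.null(gpr_peek(state)))
      stop("unbalanced parentheses: '(' at position ", pos, " never closed")
    if (gpr_peek(state) != ")")
      stop("expected ')' at position ", gpr_pos(state))
    state$i <- state$i + 1L
    return(inner)
  }
  state$i <- state$i + 1L
  list(gene = tok)
}

gpr_flatten <- function(op, args) {
  flat <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  list(op = op, args = flat)
}

#' Canonical string form of a GPR rule
#'
#' `parse_gpr(gpr_to_string(tree))` reproduces the tree: `and` arguments
#' that are `or` nodes are parenthesized, nothing else is.
#'
#' @param rule A `gpr_rule`.
#' @return Character rule string.
#' @export
gpr_to_string <- function(rule) {
  if (!is.null(rule$gene)) return(rule$gene)
  parts <- vapply(rule$args, function(a) {
    s <- gpr_to_string(a)
    if (rule$op == "and" && !is.null(a$op) && a$op == "or")
      paste0("(", s, ")")
    else s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

#' Genes referenced by a GPR rule
#' @param rule A `gpr_rule`.
#' @return Character vector of leaf gene ids (with repeats).
#' @export
gpr_genes <- function(rule) {
  if (!is.null(rule$gene)) return(rule$gene)
  unlist(lapply(rule$args, gpr_genes))
}

#' Evaluate a GPR rule over gene expression values
#'
#' Recursively substitutes `or -> max` and `and -> min`. Genes missing
#' from `expr_of` are dropped from their parent's operand list; a node
#' whose operands are all missing evaluates to `NA` and is dropped the
#' same way, so the result is `NA` only when no leaf resolves. In strict
#' mode a missing leaf under `and` poisons that node to `NA` instead.
#'
#' @param rule A `gpr_rule` (or rule string, parsed on the fly).
#' @param expr_of Named numeric vector (or list) mapping gene id to
#'   expression; may be partial.
#' @param strict_and Missing operand under `and` yields `NA` (default
#'   `FALSE`: drop-missing).
#' @return Numeric value, or `NA` when nothing resolves.
#' @export
evaluate_gpr <- function(rule, expr_of, strict_and = FALSE) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  ev <- function(node) {
    if (!is.null(node$gene)) {
      if (!node$gene %in% names(expr_of)) return(NA_real_)
      return(as.numeric(expr_of[[node$gene]]))
    }
    vals <- vapply(node$args, ev, numeric(1))
    if (node$op == "and" && strict_and && anyNA(vals)) return(NA_real_)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (node$op == "and") min(vals) else max(vals)
  }
  ev(rule)
}

#' Score metabolic reactions from a compartment profile
#'
#' Evaluates every reaction's GPR rule (OR -> max, AND -> min) on the
#' deconvoluted cancer and stroma expression of each group, on the scale
#' the profile is stored on.
#'
#' @param rules data.frame (reaction_id, subsystem, rule) as from
#'   [read_gpr_rules()], or a named list of `gpr_rule` trees.
#' @param profile Long compartment profile (gene, group, e_c, e_s) from
#'   [compartment_profile()].
#' @param strict_and Forwarded to [evaluate_gpr()].
#' @return List with `scores` (data.frame: reaction_id, group, compartment,
#'   score, n_missing) and a `differential` helper is available via
#'   [reaction_differential()].
#' @export
score_reactions <- function(rules, profile, strict_and = FALSE) {
  if (is.data.frame(rules)) {
    if (!all(c("reaction_id", "rule") %in% names(rules)))
      stop("rules table needs reaction_id and rule columns")
    trees <- lapply(rules$rule, parse_gpr)
    names(trees) <- rules$reaction_id
  } else trees <- rules
  if (!length(trees)) stop("empty rule set")
  groups <- unique(profile$group)
  leaves <- lapply(trees, function(tr) unique(gpr_genes(tr)))
  if (!any(unlist(leaves) %in% profile$gene))
    stop("profile covers no rule gene")
  out <- list()
  for (g in groups) {
    pg <- profile[profile$group == g, , drop = FALSE]
    maps <- list(cancer = setNames(pg$e_c, pg$gene),
                 stroma = setNames(pg$e_s, pg$gene))
    for (cmp in names(maps)) {
      mp <- maps[[cmp]]
      mp <- mp[!is.na(mp)]
      sc <- vapply(trees, evaluate_gpr, numeric(1), expr_of = mp,
                   strict_and = strict_and)
      miss <- vapply(leaves, function(lv) sum(!lv %in% names(mp)),
                     integer(1))
      out[[paste(g, cmp)]] <- data.frame(
        reaction_id = names(trees), group = g, compartment = cmp,
        score = unname(sc), n_missing = unname(miss),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Differential reaction scores between two groups
#'
#' @param scores Reaction score table from [score_reactions()].
#' @param group1,group2 Group labels; the difference is group2 - group1.
#' @return data.frame (reaction_id, compartment, score_1, score_2, delta).
#' @export
reaction_differential <- function(scores, group1, group2) {
  s1 <- scores[scores$group == group1, c("reaction_id", "compartment", "score")]
  s2 <- scores[scores$group == group2, c("reaction_id", "compartment", "score")]
  m <- merge(s1, s2, by = c("reaction_id", "compartment"),
             suffixes = c("_1", "_2"))
  m$delta <- m$score_2 - m$score_1
  m[order(m$reaction_id, m$compartment), , drop = FALSE]
}
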