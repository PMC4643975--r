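#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene (ORF) identifiers stating
#' when a reaction's catalyst is available: `and` encodes a protein complex
#' (all subunits required), `or` encodes isozymes (any one suffices).
#' Grammar: `ORF | expr "and" expr | expr "or" expr | "(" expr ")"`, with
#' case-insensitive keywords and `and` binding tighter than `or` (the
#' COBRA/SBML-FBC convention). `&`/`|` are accepted as synonyms.
#'
#' @param text GPR string.
#' @return a `gpr` expression tree (leaves carry gene ids, internal nodes
#'   are `and`/`or` with arbitrary nesting). `format()` serializes it back
#'   to a normalized, fully parenthesized string.
#' @examples
#' format(parse_gpr("G1 and G2 or G3"))  # "((G1 and G2) or G3)"
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- gpr_tokenize(text)
  if (length(tokens$value) == 0L) stop("empty GPR expression")
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  st$tok <- tokens
  node <- gpr_parse_or(st)
  if (st$pos <= length(st$tok$value)) {
    stop("unexpected token '", st$tok$value[st$pos], "' at position ",
         st$tok$at[st$pos], " in GPR")
  }
  node
}

gpr_tokenize <- function(text) {
  value <- character()
  type <- character()
  at <- integer()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      value <- c(value, ch); type <- c(type, ch); at <- c(at, i)
      i <- i + 1L; next
    }
    if (ch %in% c("&", "|")) {
      value <- c(value, ch)
      type <- c(type, if (ch == "&") "and" else "or")
      at <- c(at, i); i <- i + 1L; next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^()&|[:space:]]+", substr(text, i, n)))
    word <- m[1]
    lw <- tolower(word)
    value <- c(value, word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "gene")
    at <- c(at, i)
    i <- i + nchar(word)
  }
  list(value = value, type = type, at = at)
}

gpr_peek <- function(st) if (st$pos <= length(st$tok$type)) st$tok$type[st$pos] else ""

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("or", args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("and", args)
}

gpr_parse_atom <- function(st) {
  tp <- gpr_peek(st)
  if (tp == "(") {
    open_at <- st$tok$at[st$pos]
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st)
    if (gpr_peek(st) != ")") {
      stop("unbalanced parenthesis opened at position ", open_at, " in GPR")
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tp == "gene") {
    g <- st$tok$value[st$pos]
    st$pos <- st$pos + 1L
    return(gpr_node("gene", gene = g))
  }
  stop("expected gene or '(' at position ",
       if (st$pos <= length(st$tok$at)) st$tok$at[st$pos] else "end",
       " in GPR")
}

gpr_node <- function(op, args = NULL, gene = NULL) {
  structure(list(op = op, args = args, gene = gene), class = "gpr")
}

#' @export
format.gpr <- function(x, ...) {
  if (x$op == "gene") return(x$gene)
  inner <- vapply(x$args, format, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", x$op, " ")), ")")
}

#' @export
print.gpr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Genes referenced by a GPR tree
#' @param assoc a `gpr` tree (or `NULL`).
#' @return character vector of gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(assoc) {
  if (is.null(assoc)) return(character())
  if (assoc$op == "gene") return(assoc$gene)
  unique(unlist(lapply(assoc$args, gpr_genes)))
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' A leaf is TRUE iff its gene is not deleted; `and`/`or` nodes follow
#' boolean semantics. A reaction with no GPR is never disabled by
#' deletions.
#'
#' @param assoc a `gpr` tree (from [parse_gpr()]) or a GPR string, or
#'   `NULL` for "no rule".
#' @param deleted character vector of deleted gene ids.
#' @return logical: is the reaction's catalyst still available?
#' @export
evaluate_gpr <- function(assoc, deleted = character()) {
  if (is.null(assoc)) return(TRUE)
  if (is.character(assoc)) {
    if (is.na(assoc)) return(TRUE)
    assoc <- parse_gpr(assoc)
  }
  switch(assoc$op,
    gene = !(assoc$gene %in% deleted),
    and = all(vapply(assoc$args, evaluate_gpr, logical(1), deleted = deleted)),
    or = any(vapply(assoc$args, evaluate_gpr, logical(1), deleted = deleted))
  )
}

#' Apply gene deletions to a model
#'
#' Every reaction whose GPR evaluates to FALSE under the deletion set gets
#' bounds (0, 0); all other bounds are untouched and the input model is not
#' modified. Gene ids not present in the model are ignored with a warning
#' (reference lists routinely cover the whole genome while a model covers a
#' subset).
#'
#' @param model a `metabolic_model`.
#' @param deleted character vector of gene ids to delete.
#' @param warn_unknown warn about ids absent from the model (default TRUE).
#' @return a modified copy of the model.
#' @export
apply_deletions <- function(model, deleted, warn_unknown = TRUE) {
  deleted <- unique(as.character(deleted))
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown) && warn_unknown) {
    warning("ignoring ", length(unknown), " gene id(s) not in model '",
            model$model_id, "': ", paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
  }
  deleted <- intersect(deleted, model$genes)
  if (length(deleted) == 0L) return(model)
  disabled <- disabled_reactions(model, deleted)
  if (length(disabled)) {
    i <- model$reactions$id %in% disabled
    model$reactions$lb[i] <- 0
    model$reactions$ub[i] <- 0
  }
  model
}

#' Reactions disabled by a deletion set
#' @inheritParams apply_deletions
#' @return character vector of reaction ids whose GPR evaluates FALSE.
#' @export
disabled_reactions <- function(model, deleted) {
  has <- !is.na(model$reactions$gpr)
  if (!any(has)) return(character())
  # only reactions whose GPR mentions a deleted gene can change state
  hit <- vapply(model$reactions$gpr[has], function(g) {
    any(vapply(deleted, function(d) grepl(d, g, fixed = TRUE), logical(1)))
  }, logical(1))
  cand <- which(has)[hit]
  off <- vapply(cand, function(j) {
    !evaluate_gpr(parse_gpr(model$reactions$gpr[j]), deleted)
  }, logical(1))
  model$reactions$id[cand][off]
}
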