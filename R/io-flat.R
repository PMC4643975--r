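#' Read and write the flat tabular model dialect
#'
#' A plain-text, four-section TSV format that carries the full content of a
#' `metabolic_model` without any SBML tooling. Sections, in order:
#' \describe{
#'   \item{`[objective]`}{a single line: the objective reaction id.}
#'   \item{`[metabolites]`}{columns `id`, `name`, `compartment`, `chebi`
#'     (`|`-separated, may be empty), `boundary` (0/1).}
#'   \item{`[reactions]`}{columns `id`, `name`, `lb`, `ub`, `stoich`
#'     (`;`-separated `metabolite=coefficient`, negative = consumed).}
#'   \item{`[gpr]`}{columns `reaction_id`, `gpr` (boolean rule string);
#'     reactions without a rule are simply absent.}
#' }
#' Lines starting with `#` are comments; `# model_id:` records the model
#' name. Reading and writing are bijective on model contents, and writing
#' is byte-deterministic for a given model.
#'
#' @param path file path.
#' @return [read_flat_model()] returns a `metabolic_model`;
#'   [write_model()] returns `path` invisibly.
#' @export
read_flat_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_id <- tools::file_path_sans_ext(basename(path))
  idm <- grep("^# *model_id:", lines, value = TRUE)
  if (length(idm)) model_id <- trimws(sub("^# *model_id:", "", idm[1]))
  lines <- lines[!startsWith(trimws(lines), "#")]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- trimws(lines[grepl("^\\[", lines)])
  chunks <- split(lines[!grepl("^\\[", lines)],
                  factor(sec[!grepl("^\\[", lines)], levels = seq_along(headers)))
  names(chunks) <- gsub("\\[|\\]", "", headers)
  get_section <- function(name) {
    x <- chunks[[name]]
    if (is.null(x)) NULL else x[nzchar(trimws(x))]
  }

  obj <- get_section("objective")
  if (is.null(obj) || length(obj) == 0L) stop("no objective section in ", path)
  objective <- trimws(obj[1])

  parse_tsv <- function(x) {
    if (is.null(x) || length(x) < 1L) stop("missing section in ", path)
    con <- textConnection(x)
    on.exit(close(con))
    utils::read.table(con, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      quote = "", colClasses = "character")
  }
  mt <- parse_tsv(get_section("metabolites"))
  rt <- parse_tsv(get_section("reactions"))

  metabolites <- tibble::tibble(
    id = mt$id, name = mt$name, compartment = mt$compartment,
    chebi = lapply(strsplit(mt$chebi, "|", fixed = TRUE),
                   function(x) x[nzchar(x)]),
    boundary = mt$boundary == "1"
  )
  stoich <- lapply(rt$stoich, function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  })
  reactions <- tibble::tibble(
    id = rt$id, name = rt$name,
    lb = as.numeric(rt$lb), ub = as.numeric(rt$ub),
    stoich = stoich, gpr = NA_character_
  )
  gp <- get_section("gpr")
  if (!is.null(gp) && length(gp)) {
    for (line in gp) {
      kv <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (identical(kv[1], "reaction_id")) next
      i <- match(kv[1], reactions$id)
      if (is.na(i)) stop("GPR for unknown reaction '", kv[1], "' in ", path)
      reactions$gpr[i] <- kv[2]
    }
  }
  metabolic_model(model_id, metabolites, reactions, objective)
}

#' @rdname read_flat_model
#' @param model a `metabolic_model` to serialize.
#' @export
write_model <- function(model, path) {
  num <- function(x) sprintf("%.10g", x)
  out <- c(
    paste0("# model_id: ", model$model_id),
    "[objective]",
    model$objective,
    "[metabolites]",
    paste(c("id", "name", "compartment", "chebi", "boundary"), collapse = "\t"),
    vapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      paste(c(m$id, m$name, m$compartment,
              paste(m$chebi[[1]], collapse = "|"),
              if (m$boundary) "1" else "0"), collapse = "\t")
    }, character(1)),
    "[reactions]",
    paste(c("id", "name", "lb", "ub", "stoich"), collapse = "\t"),
    vapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      s <- r$stoich[[1]]
      paste(c(r$id, r$name, num(r$lb), num(r$ub),
              paste(paste0(names(s), "=", num(s)), collapse = ";")),
            collapse = "\t")
    }, character(1)),
    "[gpr]",
    paste(c("reaction_id", "gpr"), collapse = "\t")
  )
  has <- which(!is.na(model$reactions$gpr))
  if (length(has)) {
    out <- c(out, paste(model$reactions$id[has], model$reactions$gpr[has],
                        sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}
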