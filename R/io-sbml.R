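#' Read a metabolic model from SBML
#'
#' Supports the two encodings in circulation for constraint-based models:
#' SBML Level 3 with the FBC extension (flux bounds as referenced
#' parameters, `fbc:geneProductAssociation` rules, `fbc:listOfObjectives`)
#' and the older Level 2 COBRA dialect (bounds as `LOWER_BOUND` /
#' `UPPER_BOUND` kinetic-law parameters, `GENE_ASSOCIATION:` strings in
#' reaction notes, `OBJECTIVE_COEFFICIENT` marking the biomass reaction).
#' Boundary species are recognized via the `boundaryCondition` attribute or
#' the `"_b"` id-suffix convention, whichever the file uses. ChEBI
#' identifiers are collected, in file order, from identifiers.org /
#' urn-style resource annotations on species.
#'
#' Reactions lacking explicit bounds default to (-1000, 1000) when marked
#' reversible and (0, 1000) otherwise; each such default is logged via
#' `message()`.
#'
#' @param path path to an SBML file.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("unparsable SBML file '", path, "': ", conditionMessage(e))
  })
  ns <- xml2::xml_ns(doc)
  sbml_ns <- names(ns)[startsWith(unname(ns), "http://www.sbml.org/sbml/")][1]
  if (is.na(sbml_ns)) stop("unparsable SBML file '", path, "': no SBML namespace")
  q <- function(tag) paste0(".//", sbml_ns, ":", tag)
  model_node <- xml2::xml_find_first(doc, q("model"))
  if (inherits(model_node, "xml_missing")) {
    stop("unparsable SBML file '", path, "': no <model> element")
  }
  model_id <- xml2::xml_attr(model_node, "id") %|NA|%
    tools::file_path_sans_ext(basename(path))
  has_fbc <- any(startsWith(unname(ns), "http://www.sbml.org/sbml/level3/version1/fbc/"))

  # global parameters (L3 flux bounds live here)
  params <- xml2::xml_find_all(model_node,
    paste0("./", sbml_ns, ":listOfParameters/", sbml_ns, ":parameter"))
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))

  # ---- species ----
  sp <- xml2::xml_find_all(model_node,
                           paste0("./", sbml_ns, ":listOfSpecies/", sbml_ns, ":species"))
  if (length(sp) == 0L) stop("unparsable SBML file '", path, "': no species")
  met_id <- strip_sbml_prefix(xml2::xml_attr(sp, "id"))
  chebi <- lapply(sp, function(node) {
    res <- xml2::xml_find_all(node, ".//*")
    uris <- xml2::xml_attr(res, "resource")
    uris <- uris[!is.na(uris)]
    hits <- regmatches(uris, regexpr("CHEBI[:%3A]*[0-9]+", uris))
    unique(sub("%3A", ":", hits, fixed = TRUE))
  })
  metabolites <- tibble::tibble(
    id = met_id,
    name = xml2::xml_attr(sp, "name") %|NA|% met_id,
    compartment = xml2::xml_attr(sp, "compartment") %|NA|% "c",
    chebi = chebi,
    boundary = (xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")) |
      grepl("_b$", met_id)
  )

  # ---- reactions ----
  rx <- xml2::xml_find_all(model_node,
                           paste0("./", sbml_ns, ":listOfReactions/", sbml_ns, ":reaction"))
  if (length(rx) == 0L) stop("unparsable SBML file '", path, "': no reactions")
  parse_side <- function(node, tag, sign) {
    refs <- xml2::xml_find_all(node,
      paste0("./", sbml_ns, ":", tag, "/", sbml_ns, ":speciesReference"))
    if (length(refs) == 0L) return(numeric())
    coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coef[is.na(coef)] <- 1
    stats::setNames(sign * coef, strip_sbml_prefix(xml2::xml_attr(refs, "species")))
  }
  objective_l2 <- character()
  rows <- purrr::map(rx, function(node) {
    rid <- strip_sbml_prefix(xml2::xml_attr(node, "id"))
    reversible <- !(xml2::xml_attr(node, "reversible") %in% c("false", "0"))
    cons <- parse_side(node, "listOfReactants", -1)
    prod <- parse_side(node, "listOfProducts", +1)
    stoich <- c(cons, prod)
    dup <- unique(names(stoich)[duplicated(names(stoich))])
    if (length(dup)) {
      stoich <- vapply(split(stoich, names(stoich)), sum, numeric(1))
      stoich <- stoich[stoich != 0]
    }
    lb <- ub <- NA_real_
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub <- par_val[[ub_ref]]
    kl <- xml2::xml_find_all(node,
      paste0("./", sbml_ns, ":kineticLaw//", sbml_ns, ":parameter"))
    if (length(kl)) {
      kid <- xml2::xml_attr(kl, "id")
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kval[match("LOWER_BOUND", kid)]
      if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kval[match("UPPER_BOUND", kid)]
      oc <- kval[match("OBJECTIVE_COEFFICIENT", kid)]
      if (!is.na(oc) && oc != 0) objective_l2 <<- c(objective_l2, rid)
    }
    if (is.na(lb)) {
      lb <- if (reversible) -1000 else 0
      message("read_sbml: no lower bound for '", rid, "', defaulting to ", lb)
    }
    if (is.na(ub)) {
      ub <- 1000
      message("read_sbml: no upper bound for '", rid, "', defaulting to 1000")
    }
    gpr <- NA_character_
    gpa <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpr <- sbml_gpa_to_string(kids[[1]])
    }
    if (is.na(gpr)) {
      notes <- xml2::xml_find_all(node, paste0("./", sbml_ns, ":notes//*"))
      txt <- xml2::xml_text(notes)
      ga <- grep("GENE[ _]ASSOCIATION *:", txt, value = TRUE)
      if (length(ga)) {
        g <- trimws(sub(".*GENE[ _]ASSOCIATION *:", "", ga[1]))
        if (nzchar(g)) gpr <- g
      }
    }
    tibble::tibble(id = rid,
                   name = xml2::xml_attr(node, "name") %|NA|% rid,
                   lb = lb, ub = ub, stoich = list(stoich), gpr = gpr)
  })
  reactions <- dplyr::bind_rows(rows)

  # ---- objective ----
  objective <- NA_character_
  obj_ref <- xml2::xml_find_first(model_node,
    ".//*[local-name()='fluxObjective']")
  if (!inherits(obj_ref, "xml_missing")) {
    objective <- strip_sbml_prefix(xml2::xml_attr(obj_ref, "reaction"))
  }
  if (is.na(objective) && length(objective_l2)) objective <- objective_l2[1]
  if (is.na(objective)) {
    cand <- grep("biomass", reactions$id, ignore.case = TRUE, value = TRUE)
    if (length(cand)) objective <- cand[1]
  }
  if (is.na(objective)) stop("no objective found in SBML file '", path, "'")

  genes <- character()
  gps <- xml2::xml_find_all(model_node, ".//*[local-name()='geneProduct']")
  if (length(gps)) {
    genes <- xml2::xml_attr(gps, "label") %|NA|%
      strip_sbml_prefix(xml2::xml_attr(gps, "id"))
  }
  metabolic_model(model_id, metabolites, reactions, objective, genes = genes)
}

strip_sbml_prefix <- function(x) sub("^(M_|R_|G_|S_)", "", x)

sbml_gpa_to_string <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    lab <- xml2::xml_attr(node, "label")
    return(if (!is.na(lab)) lab else strip_sbml_prefix(g))
  }
  kids <- xml2::xml_children(node)
  inner <- vapply(kids, sbml_gpa_to_string, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(inner, collapse = op), ")")
}

`%|NA|%` <- function(a, b) {
  out <- a
  i <- is.na(out)
  if (length(b) == 1L) out[i] <- b else out[i] <- b[i]
  out
}

#' Write a metabolic model as SBML Level 3 + FBC
#'
#' Emits an SBML L3v1 document with the FBC v2 extension: flux bounds as
#' shared parameters, gene products with ORF labels, nested
#' `fbc:and`/`fbc:or` gene associations and a maximization objective.
#' ChEBI identifiers are written as identifiers.org resource annotations.
#' `read_sbml(write_sbml(m))` round-trips all model fields.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.10g", x)
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  pid <- stats::setNames(paste0("fb_", seq_along(bounds)), num(bounds))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
           'xmlns:bqbiol="http://biomodels.net/biology-qualifiers/" ',
           'level="3" version="1" fbc:required="false">'),
    paste0('<model id="', esc(model$model_id), '" fbc:strict="true">'),
    "<listOfCompartments>",
    paste0('<compartment id="', esc(unique(model$metabolites$compartment)),
           '" constant="true"/>'),
    "</listOfCompartments>",
    "<listOfSpecies>"
  )
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    open <- paste0('<species id="M_', esc(m$id), '" name="', esc(m$name),
                   '" compartment="', esc(m$compartment),
                   '" boundaryCondition="', tolower(as.character(m$boundary)),
                   '" hasOnlySubstanceUnits="false" constant="false"')
    ch <- m$chebi[[1]]
    if (length(ch)) {
      lines <- c(lines, paste0(open, ">"),
        "<annotation><rdf:RDF><rdf:Description><bqbiol:is><rdf:Bag>",
        paste0('<rdf:li rdf:resource="http://identifiers.org/chebi/',
               esc(ch), '"/>'),
        "</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>",
        "</species>")
    } else {
      lines <- c(lines, paste0(open, "/>"))
    }
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>",
    paste0('<parameter id="', pid, '" value="', names(pid),
           '" constant="true"/>'),
    "</listOfParameters>",
    "<fbc:listOfGeneProducts>",
    if (length(model$genes)) {
      paste0('<fbc:geneProduct fbc:id="G_', gsub("[^A-Za-z0-9_]", "_", model$genes),
             '" fbc:label="', esc(model$genes), '"/>')
    },
    "</fbc:listOfGeneProducts>",
    "<listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- r$stoich[[1]]
    lines <- c(lines,
      paste0('<reaction id="R_', esc(r$id), '" name="', esc(r$name),
             '" reversible="', tolower(as.character(r$lb < 0)),
             '" fast="false" fbc:lowerFluxBound="', pid[[num(r$lb)]],
             '" fbc:upperFluxBound="', pid[[num(r$ub)]], '">'))
    cons <- s[s < 0]; prod <- s[s > 0]
    if (length(cons)) {
      lines <- c(lines, "<listOfReactants>",
        paste0('<speciesReference species="M_', esc(names(cons)),
               '" stoichiometry="', num(-cons), '" constant="true"/>'),
        "</listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "<listOfProducts>",
        paste0('<speciesReference species="M_', esc(names(prod)),
               '" stoichiometry="', num(prod), '" constant="true"/>'),
        "</listOfProducts>")
    }
    if (!is.na(r$gpr)) {
      lines <- c(lines, "<fbc:geneProductAssociation>",
                 gpa_to_sbml(parse_gpr(r$gpr)),
                 "</fbc:geneProductAssociation>")
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    paste0('<fbc:fluxObjective fbc:reaction="R_', esc(model$objective),
           '" fbc:coefficient="1"/>'),
    "</fbc:listOfFluxObjectives>", "</fbc:objective>", "</fbc:listOfObjectives>",
    "</model>", "</sbml>")
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))  # validates well-formedness
  xml2::write_xml(doc, path)
  invisible(path)
}

gpa_to_sbml <- function(tree) {
  if (tree$op == "gene") {
    return(paste0('<fbc:geneProductRef fbc:geneProduct="G_',
                  gsub("[^A-Za-z0-9_]", "_", tree$gene),
                  '" fbc:label="', tree$gene, '"/>'))
  }
  kids <- unlist(lapply(tree$args, gpa_to_sbml))
  c(paste0("<fbc:", tree$op, ">"), kids, paste0("</fbc:", tree$op, ">"))
}
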