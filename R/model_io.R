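#' Construct a genome-scale metabolic model object
#'
#' The central container of the package: a stoichiometric reconstruction with
#' flux bounds, pathway-level subsystem labels, gene-protein-reaction rules,
#' and a biomass-type objective reaction. All fluxes are in mmol/gDW/h.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `gpr` (rule text, possibly `""`).
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (metabolite id -> signed coefficient).
#' @param objective id of the objective (biomass) reaction.
#' @param id optional model identifier.
#' @return validated object of class `metabolic_model`; its `genes` field is
#'   the union of all GPR leaf identifiers.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry, objective,
                            id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  metabolites$compartment[!nzchar(metabolites$compartment)] <- "c"
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- "unassigned"
  reactions$subsystem[is.na(reactions$subsystem) |
                        !nzchar(reactions$subsystem)] <- "unassigned"
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  model <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry[reactions$id],
    genes = character(0),
    objective = objective
  ), class = "metabolic_model")
  model$genes <- sort(unique(unlist(lapply(reactions$gpr, function(g)
    gpr_genes(parse_gpr(g))))))
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering, stoichiometry referencing only
#' defined metabolites, non-empty reaction stoichiometries, gene-set
#' consistency with the GPRs, and presence of the objective reaction.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  if (any(!nzchar(mets)) || anyDuplicated(mets))
    stop("model validation: metabolite ids must be non-empty and unique")
  if (any(!nzchar(rxns)) || anyDuplicated(rxns))
    stop("model validation: reaction ids must be non-empty and unique")
  if (any(model$reactions$lower_bound > model$reactions$upper_bound))
    stop("model validation: lower_bound exceeds upper_bound for reaction(s): ",
         paste(rxns[model$reactions$lower_bound > model$reactions$upper_bound],
               collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxns))
    stop("model validation: stoichiometry entries must match reaction ids")
  for (r in rxns) {
    sto <- model$stoichiometry[[r]]
    if (length(sto) == 0 || all(sto == 0))
      stop("model validation: reaction '", r,
           "' has no nonzero stoichiometric coefficient")
    missing <- setdiff(names(sto), mets)
    if (length(missing) > 0)
      stop("model validation: reaction '", r,
           "' references undefined metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  if (!model$objective %in% rxns)
    stop("model validation: objective reaction '", model$objective,
         "' is not in the model")
  gpr_gene_union <- sort(unique(unlist(lapply(model$reactions$gpr, function(g)
    gpr_genes(parse_gpr(g))))))
  if (!identical(sort(model$genes), gpr_gene_union))
    stop("model validation: gene set does not equal the union of GPR genes")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model '%s': %d metabolites, %d reactions, %d genes, %d subsystems; objective '%s'>\n",
    x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes),
    length(unique(x$reactions$subsystem)), x$objective))
  invisible(x)
}

#' Load a metabolic model from SBML or JSON
#'
#' JSON follows the common constraint-based layout (reactions carry
#' `metabolites`, `lower_bound`, `upper_bound`, `subsystem`,
#' `gene_reaction_rule`); SBML is Level 3 with the FBC package (bounds,
#' objectives, gene products). Default bounds when a JSON reaction omits
#' them: (0, 1000), or (-1000, 1000) if flagged `reversible`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"`, or `"sbml"`.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "json") load_model_json(path) else load_model_sbml(path)
}

load_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("unparseable JSON model file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("unparseable JSON model: missing 'metabolites' or 'reactions'")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    name = vapply(doc$metabolites, function(m)
      as.character(m$name %||% m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m)
      as.character(m$compartment %||% "c"), character(1)),
    stringsAsFactors = FALSE)
  sto <- list()
  objective <- doc$objective %||% NULL
  rx <- lapply(doc$reactions, function(r) {
    rev <- isTRUE(r$reversible)
    lb <- r$lower_bound %||% if (rev) -1000 else 0
    ub <- r$upper_bound %||% 1000
    data.frame(id = as.character(r$id),
               name = as.character(r$name %||% r$id),
               lower_bound = as.numeric(lb), upper_bound = as.numeric(ub),
               subsystem = as.character(r$subsystem %||% "unassigned"),
               gpr = as.character(r$gene_reaction_rule %||% ""),
               obj_coef = as.numeric(r$objective_coefficient %||% 0),
               stringsAsFactors = FALSE)
  })
  reactions <- do.call(rbind, rx)
  for (r in doc$reactions)
    sto[[as.character(r$id)]] <- unlist(r$metabolites)
  if (is.null(objective)) {
    w <- which(reactions$obj_coef != 0)
    if (length(w) == 0)
      stop("JSON model has no objective (no 'objective' field and no ",
           "reaction with nonzero objective_coefficient)")
    objective <- reactions$id[w[1]]
  }
  reactions$obj_coef <- NULL
  metabolic_model(mets, reactions, sto, objective,
                  id = as.character(doc$id %||% "model"))
}

#' Save a metabolic model to SBML or JSON
#'
#' Round-trips with [load_model()]: `load_model(save_model(m, p), ...)` is
#' structurally identical to `m` in both formats (empty GPRs stay empty).
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"json"`, or `"sbml"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "json") save_model_json(model, path) else save_model_sbml(model, path)
  invisible(path)
}

save_model_json <- function(model, path) {
  rx <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    list(id = r$id, name = r$name,
         metabolites = as.list(model$stoichiometry[[r$id]]),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem,
         gene_reaction_rule = r$gpr,
         objective_coefficient = if (r$id == model$objective) 1 else 0)
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  doc <- list(id = model$id, objective = model$objective,
              metabolites = mets, reactions = rx,
              genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix S (metabolites x reactions) with dimnames;
#'   `S[i, j]` is the coefficient of metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (r in model$reactions$id) {
    sto <- model$stoichiometry[[r]]
    S[names(sto), r] <- sto
  }
  S
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SBML Level 3 + FBC v2 ----

sbml_id <- function(prefix, x) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", x))

strip_sbml_prefix <- function(x, prefix) {
  sub(paste0("^", prefix), "", x)
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable SBML file: ", path,
                                           " (", conditionMessage(e), ")"))
  ln <- function(node, name)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  mdl <- ln(doc, "model")
  if (length(mdl) == 0) stop("unparseable SBML file: no <model> element")
  mdl <- mdl[[1]]

  attr_any <- function(node, name) {
    # attribute irrespective of namespace prefix
    at <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", name, "$"), names(at))
    if (length(hit) == 0) NA_character_ else unname(at[hit[1]])
  }

  sp <- ln(mdl, "species")
  mets <- data.frame(
    id = strip_sbml_prefix(vapply(sp, attr_any, character(1), "id"), "M_"),
    name = vapply(sp, function(s) {
      nm <- attr_any(s, "name")
      if (is.na(nm)) strip_sbml_prefix(attr_any(s, "id"), "M_") else nm
    }, character(1)),
    compartment = vapply(sp, attr_any, character(1), "compartment"),
    stringsAsFactors = FALSE)

  params <- ln(mdl, "parameter")
  pvals <- stats::setNames(
    vapply(params, function(p) as.numeric(attr_any(p, "value")), numeric(1)),
    vapply(params, attr_any, character(1), "id"))

  gps <- ln(mdl, "geneProduct")
  glabels <- stats::setNames(
    vapply(gps, function(g) {
      lab <- attr_any(g, "label")
      if (is.na(lab)) strip_sbml_prefix(attr_any(g, "id"), "G_") else lab
    }, character(1)),
    vapply(gps, attr_any, character(1), "id"))

  gpa_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(node, "geneProduct")
      lab <- glabels[ref]
      return(if (is.na(lab)) strip_sbml_prefix(ref, "G_") else unname(lab))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_text, character(1))
    op <- if (nm == "and") " and " else " or "
    wrapped <- vapply(seq_along(kids), function(i) {
      if (nm == "and" && xml2::xml_name(kids[[i]]) == "or")
        paste0("(", parts[i], ")") else parts[i]
    }, character(1))
    paste(wrapped, collapse = op)
  }

  rns <- ln(mdl, "reaction")
  sto <- list()
  rx <- lapply(rns, function(rn) {
    rid <- strip_sbml_prefix(attr_any(rn, "id"), "R_")
    lbp <- attr_any(rn, "lowerFluxBound")
    ubp <- attr_any(rn, "upperFluxBound")
    rev <- identical(attr_any(rn, "reversible"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else
      if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else 1000
    coefs <- numeric(0)
    for (sr in ln(rn, "speciesReference")) {
      sid <- strip_sbml_prefix(attr_any(sr, "species"), "M_")
      stoich <- as.numeric(attr_any(sr, "stoichiometry"))
      if (is.na(stoich)) stoich <- 1
      parent <- xml2::xml_name(xml2::xml_parent(sr))
      sgn <- if (parent == "listOfReactants") -1 else 1
      coefs[sid] <- (if (sid %in% names(coefs)) coefs[sid] else 0) + sgn * stoich
    }
    sto[[rid]] <<- coefs
    gpa <- ln(rn, "geneProductAssociation")
    gpr <- if (length(gpa) > 0) {
      kids <- xml2::xml_children(gpa[[1]])
      if (length(kids) > 0) gpa_to_text(kids[[1]]) else ""
    } else ""
    nm <- attr_any(rn, "name")
    grp <- ln(rn, "subsystem")  # package-private annotation (see writer)
    subsystem <- if (length(grp) > 0) xml2::xml_text(grp[[1]]) else "unassigned"
    data.frame(id = rid, name = if (is.na(nm)) rid else nm,
               lower_bound = lb, upper_bound = ub,
               subsystem = subsystem, gpr = gpr, stringsAsFactors = FALSE)
  })
  reactions <- do.call(rbind, rx)

  fo <- ln(mdl, "fluxObjective")
  if (length(fo) == 0)
    stop("SBML model has no flux objective (fbc:listOfObjectives missing)")
  objective <- strip_sbml_prefix(attr_any(fo[[1]], "reaction"), "R_")

  mid <- attr_any(mdl, "id")
  metabolic_model(mets, reactions, sto, objective,
                  id = if (is.na(mid)) "model" else mid)
}

save_model_sbml <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'xmlns:cf="https://contextflux.r-pkg/annotations" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('<model id="%s" fbc:strict="true">', esc(sbml_id("", model$id))))

  comps <- unique(model$metabolites$compartment)
  out <- c(out, "<listOfCompartments>",
           sprintf('<compartment id="%s" constant="true"/>',
                   vapply(comps, function(x) esc(sbml_id("", x)), character(1))),
           "</listOfCompartments>")

  out <- c(out, "<listOfSpecies>",
           vapply(seq_len(nrow(model$metabolites)), function(i) {
             m <- model$metabolites[i, ]
             sprintf(paste0('<species id="%s" name="%s" compartment="%s" ',
                            'constant="false" boundaryCondition="false" ',
                            'hasOnlySubstanceUnits="false"/>'),
                     esc(sbml_id("M_", m$id)), esc(m$name),
                     esc(sbml_id("", m$compartment)))
           }, character(1)),
           "</listOfSpecies>")

  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- stats::setNames(sprintf("cf_bound_%d", seq_along(bounds)), num(bounds))
  out <- c(out, "<listOfParameters>",
           sprintf('<parameter id="%s" value="%s" constant="true"/>',
                   bid, names(bid)),
           "</listOfParameters>")

  gpr_to_xml <- function(expr) {
    switch(expr$kind,
      gene = sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                     esc(sbml_id("G_", expr$gene))),
      and = paste0("<fbc:and>",
                   paste(vapply(expr$children, gpr_to_xml, character(1)),
                         collapse = ""), "</fbc:and>"),
      or = paste0("<fbc:or>",
                  paste(vapply(expr$children, gpr_to_xml, character(1)),
                        collapse = ""), "</fbc:or>"))
  }

  out <- c(out, "<listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sto <- model$stoichiometry[[r$id]]
    out <- c(out, sprintf(
      paste0('<reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(sbml_id("R_", r$id)), esc(r$name),
      if (r$lower_bound < 0) "true" else "false",
      bid[num(r$lower_bound)], bid[num(r$upper_bound)]))
    out <- c(out, sprintf("<cf:subsystem>%s</cf:subsystem>", esc(r$subsystem)))
    reac <- sto[sto < 0]; prod <- sto[sto > 0]
    if (length(reac) > 0)
      out <- c(out, "<listOfReactants>",
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       vapply(names(reac), function(x) esc(sbml_id("M_", x)), character(1)),
                       num(-unname(reac))),
               "</listOfReactants>")
    if (length(prod) > 0)
      out <- c(out, "<listOfProducts>",
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       vapply(names(prod), function(x) esc(sbml_id("M_", x)), character(1)),
                       num(unname(prod))),
               "</listOfProducts>")
    if (nzchar(r$gpr)) {
      expr <- parse_gpr(r$gpr)
      out <- c(out, "<fbc:geneProductAssociation>", gpr_to_xml(expr),
               "</fbc:geneProductAssociation>")
    }
    out <- c(out, "</reaction>")
  }
  out <- c(out, "</listOfReactions>")

  out <- c(out,
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(sbml_id("R_", model$objective))),
    "</fbc:listOfFluxObjectives>", "</fbc:objective>",
    "</fbc:listOfObjectives>")

  if (length(model$genes) > 0)
    out <- c(out, "<fbc:listOfGeneProducts>",
             sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                     vapply(model$genes, function(g) esc(sbml_id("G_", g)), character(1)),
                     vapply(model$genes, esc, character(1))),
             "</fbc:listOfGeneProducts>")

  out <- c(out, "</model>", "</sbml>")
  # validate well-formedness before writing
  xml2::read_xml(paste(out, collapse = "\n"))
  writeLines(out, path)
}
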