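#' Read a metabolic model from SBML or JSON
#'
#' Dispatches on file extension: `.xml`/`.sbml` are parsed as SBML
#' Level 3 with the FBC extension (flux bounds, objective, gene
#' associations); `.json` uses the package's compact fixture dialect
#' (see [write_model_json()]). Exchange reactions are recognized by
#' single-metabolite stoichiometry on a boundary species whose
#' compartment is `d`, `e` or `u`; that compartment becomes the
#' exchange's facing tag.
#'
#' @param path model file.
#' @param kind `"bacterium"` or `"host"` (not encoded in SBML).
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, kind = "bacterium") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_model_json(path, kind = kind),
         xml = ,
         sbml = read_model_sbml(path, kind = kind),
         stop("read_model: unknown model format: .", ext))
}

#' Write a metabolic model to SBML or JSON (by extension)
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = write_model_json(model, path),
         xml = ,
         sbml = write_model_sbml(model, path),
         stop("write_model: unknown model format: .", ext))
}

## ---------------------------------------------------------------- SBML

.SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' @rdname read_model
#' @export
read_model_sbml <- function(path, kind = "bacterium") {
  doc <- xml2::read_xml(path)
  ln <- function(node, xp) xml2::xml_find_all(node, xp)
  model_node <- ln(doc, ".//*[local-name()='model']")[[1]]
  mid <- xml2::xml_attr(model_node, "id")

  sp <- ln(model_node, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  formula <- xml2::xml_attr(sp, "chemicalFormula")
  mets$carbon <- .carbon_from_formula(formula)

  pars <- ln(model_node, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))

  rx <- ln(model_node, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx) == 0L) stop("read_model_sbml: model has no reactions")
  n <- length(rx)
  rids <- xml2::xml_attr(rx, "id")
  lb <- ub <- numeric(n)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, rids))
  gpr <- character(0)
  for (i in seq_len(n)) {
    node <- rx[[i]]
    lb_id <- xml2::xml_attr(node, "lowerFluxBound")
    ub_id <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lb_id) || is.na(ub_id) ||
        is.na(pval[lb_id]) || is.na(pval[ub_id]))
      stop("read_model_sbml: missing FBC flux bounds on reaction ", rids[i])
    lb[i] <- pval[[lb_id]]; ub[i] <- pval[[ub_id]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- ln(node, paste0("./*[local-name()='", side,
                              "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0L) next
      sid <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (any(!sid %in% mets$id))
        stop("read_model_sbml: reaction ", rids[i],
             " references unknown species ",
             paste(setdiff(sid, mets$id), collapse = ", "))
      sgn <- if (side == "listOfReactants") -1 else 1
      S[sid, i] <- S[sid, i] + sgn * st
    }
    ga <- ln(node, ".//*[local-name()='geneProductAssociation']")
    if (length(ga) > 0L)
      gpr[rids[i]] <- .gpr_string_from_node(xml2::xml_children(ga[[1]])[[1]])
  }

  fo <- ln(model_node, ".//*[local-name()='fluxObjective']")
  if (length(fo) == 0L)
    stop("read_model_sbml: model has no FBC objective")
  obj_rxn <- xml2::xml_attr(fo[[1]], "reaction")
  rxns <- data.frame(id = rids, lb = lb, ub = ub,
                     objective = rids == obj_rxn,
                     stringsAsFactors = FALSE)

  metabolic_model(mid, mets, rxns, S,
                  exchanges = .detect_exchanges(S, mets),
                  gpr = gpr, kind = kind)
}

.carbon_from_formula <- function(formula) {
  out <- rep(NA_real_, length(formula))
  hit <- !is.na(formula) & grepl("C[0-9]*", formula)
  cnt <- regmatches(formula, regexpr("C(?![a-z])[0-9]*", formula, perl = TRUE))
  has <- !is.na(formula) & lengths(regmatches(formula,
           gregexpr("C(?![a-z])[0-9]*", formula, perl = TRUE))) > 0
  for (i in which(has)) {
    mm <- regmatches(formula[i],
                     regexpr("C(?![a-z])([0-9]*)", formula[i], perl = TRUE))
    num <- sub("^C", "", mm)
    out[i] <- if (num == "") 1 else as.numeric(num)
  }
  out[!is.na(formula) & !has] <- 0
  out
}

## recover "g1 and (g2 or g3)" strings from nested fbc association nodes
.gpr_string_from_node <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef")
    return(sub("^G_", "", xml2::xml_attr(node, "geneProduct")))
  kids <- vapply(xml2::xml_children(node), .gpr_string_from_node, "")
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(kids, collapse = op), ")")
}

.detect_exchanges <- function(S, mets) {
  nz <- colSums(S != 0)
  comp <- stats::setNames(mets$compartment, mets$id)
  out <- data.frame(rxn_id = character(0), compound = character(0),
                    facing = character(0))
  for (j in which(nz == 1L)) {
    sid <- rownames(S)[S[, j] != 0]
    fc <- comp[[sid]]
    if (!fc %in% c("d", "e", "u")) next
    compound <- sub("^M_", "", sid)
    compound <- sub(paste0("_", fc, "$"), "", compound)
    out <- rbind(out, data.frame(rxn_id = colnames(S)[j],
                                 compound = compound, facing = fc))
  }
  out
}

#' @rdname write_model
#' @export
write_model_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x); x <- gsub("<", "&lt;", x)
    gsub(">", "&gt;", x)
  }
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', .SBML_CORE_NS, '" xmlns:fbc="', .SBML_FBC_NS,
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="', esc(model$id), '" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (cp in unique(model$mets$compartment))
    add('      <compartment id="', esc(cp), '" constant="true"/>')
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    carb <- model$mets$carbon[i]
    frm <- if (!is.null(carb) && !is.na(carb) && carb > 0)
      paste0(' fbc:chemicalFormula="C', format(carb), '"') else ""
    add('      <species id="', esc(model$mets$id[i]), '" compartment="',
        esc(model$mets$compartment[i]),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
        ' constant="false"', frm, '/>')
  }
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  for (i in seq_len(nrow(model$rxns))) {
    add('      <parameter id="lb_', i, '" value="', num(model$rxns$lb[i]),
        '" constant="true"/>')
    add('      <parameter id="ub_', i, '" value="', num(model$rxns$ub[i]),
        '" constant="true"/>')
  }
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  for (i in seq_len(nrow(model$rxns))) {
    rid <- model$rxns$id[i]
    add('      <reaction id="', esc(rid), '" reversible="',
        tolower(model$rxns$lb[i] < 0), '" fast="false"',
        ' fbc:lowerFluxBound="lb_', i, '" fbc:upperFluxBound="ub_', i, '">')
    col <- model$S[, i]
    for (side in c(-1, 1)) {
      sel <- which(sign(col) == side)
      if (length(sel) == 0L) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      add('        <', tag, '>')
      for (k in sel)
        add('          <speciesReference species="', esc(rownames(model$S)[k]),
            '" stoichiometry="', num(abs(col[k])), '" constant="true"/>')
      add('        </', tag, '>')
    }
    if (rid %in% names(model$gpr)) {
      add('        <fbc:geneProductAssociation>')
      add(.gpr_node_from_string(model$gpr[[rid]], indent = 10L))
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  obj <- objective_reaction(model)
  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  add('          <fbc:fluxObjective fbc:reaction="', esc(obj),
      '" fbc:coefficient="1"/>')
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')
  genes <- unique(unlist(lapply(model$gpr, .gpr_genes)))
  if (length(genes) > 0L) {
    add('    <fbc:listOfGeneProducts>')
    for (g in genes)
      add('      <fbc:geneProduct fbc:id="G_', esc(g), '" fbc:label="',
          esc(g), '"/>')
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(unlist(L), path)
  invisible(path)
}

## serialize a parsed GPR tree as nested fbc and/or/geneProductRef nodes
.gpr_node_from_string <- function(gpr, indent = 0L) {
  tree <- .parse_gpr(gpr)
  pad <- function(d) strrep(" ", indent + 2L * d)
  rec <- function(t, d) {
    if (is.character(t))
      return(paste0(pad(d), '<fbc:geneProductRef fbc:geneProduct="G_', t, '"/>'))
    op <- t$op
    kids <- vapply(t$args, rec, "", d = d + 1L)
    paste0(pad(d), "<fbc:", op, ">\n",
           paste(kids, collapse = "\n"), "\n", pad(d), "</fbc:", op, ">")
  }
  rec(tree, 0L)
}

## ---------------------------------------------------------------- JSON

#' Write/read the compact JSON model dialect
#'
#' A hand-auditable fixture format: `id`, `kind`, `metabolites` (id,
#' compartment, carbon), `reactions` (id, lb, ub, metabolites as a
#' stoichiometry map, optional gpr), `objective`, and the exchange
#' registry. Round-trips losslessly through [read_model_json()].
#'
#' @param model a `metabolic_model`.
#' @param path file path.
#' @return `path` invisibly (writer); a `metabolic_model` (reader).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- lapply(seq_len(nrow(model$rxns)), function(i) {
    col <- model$S[, i]
    nz <- which(col != 0)
    r <- list(id = model$rxns$id[i], lb = model$rxns$lb[i],
              ub = model$rxns$ub[i],
              metabolites = as.list(col[nz]))
    rid <- model$rxns$id[i]
    if (rid %in% names(model$gpr)) r$gpr <- model$gpr[[rid]]
    r
  })
  obj <- list(id = model$id, kind = model$kind,
              metabolites = model$mets,
              reactions = rx,
              objective = objective_reaction(model),
              exchanges = model$exchanges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @param kind agent kind for the loaded model (JSON files carry their
#'   own `kind`; this argument is only a fallback).
#' @export
read_model_json <- function(path, kind = "bacterium") {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment,
               carbon = if (is.null(m$carbon)) NA_real_ else m$carbon)))
  n <- length(x$reactions)
  rids <- vapply(x$reactions, `[[`, "", "id")
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, rids))
  gpr <- character(0)
  lb <- ub <- numeric(n)
  for (i in seq_len(n)) {
    r <- x$reactions[[i]]
    lb[i] <- r$lb; ub[i] <- r$ub
    stoich <- unlist(r$metabolites)
    bad <- setdiff(names(stoich), mets$id)
    if (length(bad) > 0L)
      stop("read_model_json: reaction ", r$id,
           " references unknown metabolite(s) ", paste(bad, collapse = ", "))
    S[names(stoich), i] <- stoich
    if (!is.null(r$gpr)) gpr[r$id] <- r$gpr
  }
  if (is.null(x$objective))
    stop("read_model_json: model has no objective")
  rxns <- data.frame(id = rids, lb = lb, ub = ub,
                     objective = rids == x$objective)
  ex <- if (is.null(x$exchanges) || length(x$exchanges) == 0L) NULL else
    do.call(rbind, lapply(x$exchanges, function(e)
      data.frame(rxn_id = e$rxn_id, compound = e$compound,
                 facing = e$facing)))
  metabolic_model(x$id, mets, rxns, S, exchanges = ex, gpr = gpr,
                  kind = if (is.null(x$kind)) kind else x$kind)
}
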