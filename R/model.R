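#' Construct a constraint-based metabolic model
#'
#' The in-memory representation used by the whole package: a dense
#' stoichiometric matrix plus reaction bounds, one objective reaction,
#' and an exchange registry that tags every boundary reaction with the
#' compartment it faces: `"d"` (dietary pool, bacteria only), `"e"`
#' (shared apical/local pool) or `"u"` (basolateral blood reservoir).
#' Sign convention for exchange fluxes: negative = uptake, positive =
#' secretion.
#'
#' @param id model identifier (species id in community simulations).
#' @param mets data.frame with columns `id`, `compartment` and optional
#'   `carbon` (carbon atoms, used by the toy-community balance check).
#' @param rxns data.frame with columns `id`, `lb`, `ub` (mmol/gDW/h) and
#'   logical `objective` (exactly one `TRUE`).
#' @param S numeric matrix, metabolites x reactions, dimnames matching
#'   `mets$id` / `rxns$id`.
#' @param exchanges data.frame with columns `rxn_id`, `compound`,
#'   `facing`; may be zero-row. Each listed reaction must have
#'   single-metabolite stoichiometry.
#' @param gpr named character vector of gene-protein-reaction rules
#'   (boolean expressions over gene ids with `and`/`or`/parentheses),
#'   names = reaction ids; may be empty.
#' @param kind `"bacterium"` or `"host"`; drives agent behavior.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, mets, rxns, S, exchanges = NULL,
                            gpr = character(0), kind = "bacterium") {
  S <- as.matrix(S)
  mets <- as.data.frame(mets); rxns <- as.data.frame(rxns)
  if (is.null(exchanges))
    exchanges <- data.frame(rxn_id = character(0),
                            compound = character(0),
                            facing = character(0))
  if (!all(c("id", "compartment") %in% names(mets)))
    stop("metabolic_model: mets needs id + compartment columns")
  if (!all(c("id", "lb", "ub", "objective") %in% names(rxns)))
    stop("metabolic_model: rxns needs id, lb, ub, objective columns")
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rxns))
    stop("metabolic_model: S dimensions do not match mets/rxns")
  dimnames(S) <- list(mets$id, rxns$id)
  bad <- rxns$id[rxns$lb > rxns$ub]
  if (length(bad) > 0L)
    stop("metabolic_model: lb > ub for reaction(s) ", paste(bad, collapse = ", "))
  if (sum(rxns$objective) != 1L)
    stop("metabolic_model: exactly one objective reaction required, got ",
         sum(rxns$objective))
  if (nrow(exchanges) > 0L) {
    miss <- setdiff(exchanges$rxn_id, rxns$id)
    if (length(miss) > 0L)
      stop("metabolic_model: exchange registry names unknown reaction(s) ",
           paste(miss, collapse = ", "))
    nmet <- colSums(S[, exchanges$rxn_id, drop = FALSE] != 0)
    if (any(nmet != 1L))
      stop("metabolic_model: exchange reaction(s) without single-metabolite ",
           "stoichiometry: ",
           paste(exchanges$rxn_id[nmet != 1L], collapse = ", "))
    if (!all(exchanges$facing %in% c("d", "e", "u")))
      stop("metabolic_model: exchange facing must be one of d, e, u")
  }
  m <- list(id = id, mets = mets, rxns = rxns, S = S,
            exchanges = exchanges, gpr = gpr, kind = kind)
  class(m) <- "metabolic_model"
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model", x$id, "(", x$kind, "):",
      nrow(x$mets), "metabolites,", nrow(x$rxns), "reactions,",
      nrow(x$exchanges), "exchanges; objective:",
      x$rxns$id[x$rxns$objective], "\n")
  invisible(x)
}

#' Objective reaction id of a model
#' @param model a `metabolic_model`.
#' @return character scalar.
#' @export
objective_reaction <- function(model) {
  model$rxns$id[model$rxns$objective]
}

## apply a named list/vector of c(lb, ub) or single lower bounds to a
## model's reaction bound columns; used by fba()/pfba() overrides
.apply_bound_overrides <- function(model, bound_overrides) {
  if (is.null(bound_overrides) || length(bound_overrides) == 0L)
    return(model)
  for (rid in names(bound_overrides)) {
    i <- match(rid, model$rxns$id)
    if (is.na(i))
      stop("bound override names unknown reaction: ", rid)
    bv <- bound_overrides[[rid]]
    if (length(bv) == 1L) {
      model$rxns$lb[i] <- bv
    } else {
      model$rxns$lb[i] <- bv[1]
      model$rxns$ub[i] <- bv[2]
    }
  }
  model
}

#' Re-tag dietary exchanges to the exclusive "d" compartment
#'
#' Bacterial models take dietary nutrients only from the lumen: for each
#' compound of `diet_compounds`, its `"e"`-facing exchange is re-tagged
#' to face the `"d"` (diet) pool and renamed accordingly. The
#' environment exposes diet pools only to `"d"`-facing exchanges, so
#' host models (which have none) cannot consume dietary input. Internal
#' stoichiometry is untouched: only the registry tag and the reaction id
#' change.
#'
#' @param model a `metabolic_model`.
#' @param diet_compounds character vector of compound ids.
#' @return the modified model.
#' @export
add_diet_compartment <- function(model, diet_compounds) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(diet_compounds) == 0L) return(model)
  ex <- model$exchanges
  hit <- ex$compound %in% diet_compounds & ex$facing == "e"
  already <- ex$compound[ex$facing == "d"]
  missing <- setdiff(diet_compounds, c(ex$compound[hit], already))
  if (length(missing) > 0L)
    stop("add_diet_compartment: no e-facing exchange for compound(s) ",
         paste(missing, collapse = ", "))
  for (i in which(hit)) {
    old_id <- ex$rxn_id[i]
    new_id <- sub("_e$", "_d", old_id)
    if (new_id == old_id) new_id <- paste0(old_id, "_d")
    j <- match(old_id, model$rxns$id)
    model$rxns$id[j] <- new_id
    colnames(model$S)[j] <- new_id
    if (length(model$gpr) > 0L && old_id %in% names(model$gpr))
      names(model$gpr)[names(model$gpr) == old_id] <- new_id
    ex$rxn_id[i] <- new_id
    ex$facing[i] <- "d"
  }
  model$exchanges <- ex
  model
}

#' Add a basolateral ("u") exchange compartment to a host model
#'
#' For every `"e"`-facing exchange, creates a `"u"`-facing copy (same
#' compound, same bounds at creation). `"u"` exchanges interact with the
#' blood reservoir, `"e"` exchanges with the local apical pool, so a
#' host cell can exchange compounds on both of its sides. Idempotent: a
#' compound that already has a `"u"` exchange is skipped.
#'
#' @param model a `metabolic_model` with at least one e-facing exchange.
#' @return the modified model.
#' @export
add_basolateral_compartment <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  ex <- model$exchanges
  e_idx <- which(ex$facing == "e")
  if (length(e_idx) == 0L)
    stop("add_basolateral_compartment: model has no e-facing exchanges")
  for (i in e_idx) {
    if (ex$compound[i] %in% ex$compound[ex$facing == "u"]) next
    old_id <- ex$rxn_id[i]
    new_id <- sub("_e$", "_u", old_id)
    if (new_id == old_id) new_id <- paste0(old_id, "_u")
    if (new_id %in% model$rxns$id)
      stop("add_basolateral_compartment: reaction id collision: ", new_id)
    j <- match(old_id, model$rxns$id)
    model$rxns <- rbind(model$rxns, within(model$rxns[j, ], id <- new_id))
    model$S <- cbind(model$S, model$S[, j, drop = FALSE])
    colnames(model$S)[ncol(model$S)] <- new_id
    ex <- rbind(ex, data.frame(rxn_id = new_id,
                               compound = ex$compound[i], facing = "u"))
  }
  rownames(model$rxns) <- NULL
  model$exchanges <- ex
  model
}
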