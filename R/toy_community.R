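## Toy genome-scale stand-ins ----------------------------------------
##
## Genome-scale bacterial reconstructions and the curated human model
## are deliberately out of scope; these hand-sized models reproduce the
## mechanisms the simulator exercises: mucin foraging, cross-feeding of
## a short-chain fatty acid producer on the degrader's acetate, and a
## host cell fed from the blood side that can also oxidize microbial
## butyrate at its apical side. All internal reactions are carbon
## balanced by construction and checked at generation time.

.TOY_COMPOUNDS <- data.frame(
  compound = c("nana", "fuc", "glc", "ac", "but", "ala", "co2", "o2"),
  carbon = c(11, 6, 6, 2, 4, 3, 1, 0),
  mw = c(309.27, 164.16, 180.16, 60.05, 88.11, 89.09, 44.01, 32.00))

#' Specification of a toy microbial-host community
#'
#' @param species data.frame with columns `id` and `role`, roles drawn
#'   from `"mucus_degrader"`, `"scfa_producer"`, `"fermenter"`,
#'   `"host"`. The default is the minimal three-member community.
#' @param n_fermenters extra generic glucose fermenters appended to the
#'   species table (used to emulate larger defined communities).
#' @param seed integer; fermenter yield jitter is drawn
#'   deterministically from it.
#' @return object of class `toy_community_spec`.
#' @export
toy_community_spec <- function(species = NULL, n_fermenters = 0L,
                               seed = 1L) {
  if (is.null(species))
    species <- data.frame(
      id = c("ToyMucivorans", "ToyButyrivibrio", "ToyColonocyte"),
      role = c("mucus_degrader", "scfa_producer", "host"))
  ok <- c("mucus_degrader", "scfa_producer", "fermenter", "host")
  if (!all(species$role %in% ok))
    stop("toy_community_spec: unknown role(s): ",
         paste(setdiff(species$role, ok), collapse = ", "))
  if (n_fermenters > 0L)
    species <- rbind(species, data.frame(
      id = paste0("ToyFermenter", seq_len(n_fermenters)),
      role = "fermenter"))
  structure(list(species = species, seed = as.integer(seed)),
            class = "toy_community_spec")
}

.toy_builder <- function(role, id, yield) {
  mk <- function(ids, comps) {
    base <- sub("_[cdeu]$", "", ids)
    carbon <- .TOY_COMPOUNDS$carbon[match(base, .TOY_COMPOUNDS$compound)]
    carbon[base == "bio"] <- NA   # biomass unit: carbon bookkeeping via yield
    carbon[base == "atp"] <- 0
    data.frame(id = ids, compartment = comps, carbon = carbon)
  }
  rxn <- function(id, stoich, lb = 0, ub = 1000, objective = FALSE)
    list(id = id, stoich = stoich, lb = lb, ub = ub, objective = objective)
  ex <- function(compound, facing, lb = 0, ub = 1000)
    rxn(paste0("EX_", compound, "_", facing),
        stats::setNames(-1, paste0(compound, "_", facing)), lb, ub)

  if (role == "mucus_degrader") {
    ## sialic acid forager: mucin-derived N-acetylneuraminate -> acetate;
    ## also ferments dietary glucose (mucus generalists do both)
    mets <- mk(c("nana_e", "nana_c", "glc_d", "glc_c", "ac_c", "ac_e",
                 "bio_c"),
               c("e", "c", "d", "c", "c", "e", "c"))
    bio_carbon <- (11 - 2 * 2) / yield   # carbon closure of CAT_nana
    rxns <- list(
      ex("nana", "e", lb = -10),
      rxn("T_nana", c(nana_e = -1, nana_c = 1)),
      rxn("CAT_nana", c(nana_c = -1, ac_c = 2, bio_c = yield)),
      ex("glc", "d", lb = -10),
      rxn("T_glc", c(glc_d = -1, glc_c = 1)),
      rxn("FERM_glc", c(glc_c = -1, ac_c = 2, bio_c = 2 / bio_carbon)),
      rxn("T_ac", c(ac_c = -1, ac_e = 1), lb = -1000),
      ex("ac", "e"),
      rxn("BIOMASS", c(bio_c = -1), objective = TRUE))
  } else if (role == "scfa_producer") {
    ## grows on dietary glucose, mucin fucose or cross-fed acetate;
    ## secretes butyrate
    mets <- mk(c("glc_d", "glc_c", "fuc_e", "fuc_c", "ac_e", "ac_c",
                 "but_c", "but_e", "ala_e", "ala_c", "bio_c"),
               c("d", "c", "e", "c", "e", "c", "c", "e", "e", "c", "c"))
    bio_carbon <- 2 / yield         # from FERM_ac closure below
    rxns <- list(
      ex("glc", "d", lb = -10),
      rxn("T_glc", c(glc_d = -1, glc_c = 1)),
      rxn("FERM_glc", c(glc_c = -1, ac_c = 2,
                        bio_c = 2 / bio_carbon)),
      ex("fuc", "e", lb = -10),
      rxn("T_fuc", c(fuc_e = -1, fuc_c = 1)),
      rxn("FERM_fuc", c(fuc_c = -1, ac_c = 2,
                        bio_c = 2 / bio_carbon)),
      ex("ac", "e", lb = -10),
      rxn("T_ac", c(ac_e = -1, ac_c = 1), lb = -1000),
      rxn("FERM_ac", c(ac_c = -3, but_c = 1, bio_c = yield)),
      rxn("T_but", c(but_c = -1, but_e = 1)),
      ex("but", "e"),
      ex("ala", "e", lb = -10),
      rxn("T_ala", c(ala_e = -1, ala_c = 1)),
      rxn("CAT_ala", c(ala_c = -2, ac_c = 1,
                       bio_c = 4 / bio_carbon)),
      rxn("BIOMASS", c(bio_c = -1), objective = TRUE))
  } else if (role == "fermenter") {
    ## generic fermenter of dietary glucose and mucin fucose
    mets <- mk(c("glc_d", "glc_c", "fuc_e", "fuc_c", "ac_c", "ac_e",
                 "bio_c"),
               c("d", "c", "e", "c", "c", "e", "c"))
    bio_carbon <- 2 / yield
    rxns <- list(
      ex("glc", "d", lb = -10),
      rxn("T_glc", c(glc_d = -1, glc_c = 1)),
      rxn("FERM_glc", c(glc_c = -1, ac_c = 2, bio_c = yield)),
      ex("fuc", "e", lb = -10),
      rxn("T_fuc", c(fuc_e = -1, fuc_c = 1)),
      rxn("FERM_fuc", c(fuc_c = -1, ac_c = 2, bio_c = yield)),
      rxn("T_ac", c(ac_c = -1, ac_e = 1)),
      ex("ac", "e"),
      rxn("BIOMASS", c(bio_c = -1), objective = TRUE))
  } else if (role == "host") {
    ## colonocyte: blood-side glucose and oxygen, apical-side butyrate
    mets <- mk(c("but_e", "but_c", "glc_u", "glc_c", "o2_u", "o2_c",
                 "co2_c", "co2_e", "atp_c", "bio_c", "ala_c", "ala_e"),
               c("e", "c", "u", "c", "u", "c", "c", "e", "c", "c",
                 "c", "e"))
    bio_carbon <- 2 / yield
    rxns <- list(
      ex("but", "e", lb = -10),
      rxn("T_but", c(but_e = -1, but_c = 1)),
      ex("glc", "u", lb = -10),
      rxn("T_glc_u", c(glc_u = -1, glc_c = 1)),
      ex("o2", "u", lb = -20),
      rxn("T_o2", c(o2_u = -1, o2_c = 1)),
      rxn("RESP_but", c(but_c = -1, o2_c = -1, co2_c = 2, atp_c = 2,
                        bio_c = yield)),
      rxn("RESP_glc", c(glc_c = -1, o2_c = -1, co2_c = 4, atp_c = 2,
                        bio_c = yield)),
      rxn("SYN_ala", c(glc_c = -1, ala_c = 2)),
      rxn("T_ala", c(ala_c = -1, ala_e = 1)),
      ex("ala", "e"),
      rxn("T_co2", c(co2_c = -1, co2_e = 1)),
      ex("co2", "e"),
      rxn("DM_atp_c", c(atp_c = -1)),
      rxn("BIOMASS", c(bio_c = -1), objective = TRUE))
  } else stop("unknown role: ", role)

  rids <- vapply(rxns, `[[`, "", "id")
  S <- matrix(0, nrow(mets), length(rxns),
              dimnames = list(mets$id, rids))
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$stoich
    S[names(st), j] <- st
  }
  rdf <- data.frame(id = rids,
                    lb = vapply(rxns, `[[`, 0, "lb"),
                    ub = vapply(rxns, `[[`, 0, "ub"),
                    objective = vapply(rxns, `[[`, FALSE, "objective"))
  mets$carbon[is.na(mets$carbon)] <- bio_carbon
  gpr <- if (role == "host")
    c(RESP_but = "g_bdh and g_scot", RESP_glc = "g_hk or g_gk",
      SYN_ala = "g_alt", T_but = "g_mct1", T_glc_u = "g_glut2",
      T_o2 = "g_dif", T_ala = "g_asct2", T_co2 = "g_dif") else character(0)
  metabolic_model(id, mets, rdf, S,
                  exchanges = .detect_exchanges(S, mets), gpr = gpr,
                  kind = if (role == "host") "host" else "bacterium")
}

#' Carbon balance check
#'
#' Verifies that every internal (non-exchange, non-demand, non-biomass)
#' reaction conserves carbon given the metabolite `carbon` annotation.
#'
#' @param model a `metabolic_model`.
#' @param tol balance tolerance.
#' @return `TRUE` invisibly; errors listing unbalanced reactions.
#' @export
check_carbon_balance <- function(model, tol = 1e-9) {
  carbon <- model$mets$carbon
  if (any(is.na(carbon)))
    stop("check_carbon_balance: missing carbon annotation")
  skip <- union(model$exchanges$rxn_id,
                model$rxns$id[model$rxns$objective |
                                grepl("^DM_|^BIOMASS", model$rxns$id)])
  bal <- drop(carbon %*% model$S)
  bad <- setdiff(model$rxns$id[abs(bal) > tol], skip)
  if (length(bad) > 0L)
    stop("check_carbon_balance: carbon created/destroyed by ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Generate the toy community models
#'
#' Deterministic given the spec's seed: fermenter biomass yields are
#' jittered around 0.05 biomass units per glucose so species differ.
#' Every generated model passes the carbon balance check and grows on
#' the toy medium (gap-free by construction).
#'
#' @param spec a [toy_community_spec()].
#' @return named list of [metabolic_model()]s.
#' @export
#' @examples
#' mods <- generate_toy_community(toy_community_spec())
#' vapply(mods, function(m) fba(m)$status, "")
generate_toy_community <- function(spec = toy_community_spec()) {
  stopifnot(inherits(spec, "toy_community_spec"))
  set.seed(spec$seed)
  yields <- stats::runif(nrow(spec$species), 0.04, 0.06)
  out <- list()
  for (i in seq_len(nrow(spec$species))) {
    m <- .toy_builder(spec$species$role[i], spec$species$id[i],
                      round(yields[i], 4))
    check_carbon_balance(m)
    out[[m$id]] <- m
  }
  out
}

#' Default toy medium for an arena
#'
#' The stated nutritional world of the toy community: dietary glucose in
#' the lumen (reserved for bacteria via the `"d"` compartment),
#' mucin-derived N-acetylneuraminate in the mucus layers (inner layer 4x
#' the outer per cell), and glucose + oxygen in the blood reservoir for
#' the host. Amounts are scaled to the picogram biomass of single-cell
#' agents: a lumen cell holds 5e-11 mmol glucose and a mucus cell on the
#' order of 1.5e-11 mmol sialic acid, so a maximal degrader consumes a
#' noticeable fraction (~20-30%) of its local mucus per 1-h step.
#'
#' @param geometry an `arena_geometry`.
#' @param mucus_only if `TRUE`, return only the N-acetylneuraminate
#'   mucus compound (the medium of the cross-feeding experiment: only
#'   the degrader can grow on it directly).
#' @return data.frame in the medium TSV schema.
#' @export
toy_medium <- function(geometry, mucus_only = FALSE) {
  cnt <- geometry$sector_counts
  mucus_amt <- (cnt[["OUTER_MUCUS"]] + 4 * cnt[["INNER_MUCUS"]]) * 1.5e-11
  if (mucus_only)
    return(data.frame(compound_id = "nana", class = "mucus",
                      amount_mmol = mucus_amt,
                      molecular_weight = 309.27))
  data.frame(
    compound_id = c("glc", "nana", "fuc", "glc", "o2"),
    class = c("luminal", "mucus", "mucus", "blood", "oxygen"),
    amount_mmol = c(cnt[["LUMEN"]] * 5e-11, mucus_amt, mucus_amt,
                    cnt[["HOST"]] * 1e-9,
                    cnt[["HOST"]] * 1e-9),
    molecular_weight = c(180.16, 309.27, 164.16, 180.16, 32))
}
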