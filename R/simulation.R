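#' Default relative abundances of the eight-species defined community
#'
#' Initial relative abundances of the simplified human intestinal
#' microbiota (SIHUMIx) members, derived from their concentrations in
#' human feces. Sums to 1 within 1e-6.
#' @export
sihumix_abundances <- c(
  "Anaerostipes_caccae" = 0.1263867,
  "Bacteroides_thetaiotaomicron" = 0.1444797,
  "Bifidobacterium_longum" = 0.1388008,
  "Blautia_producta" = 0.1385367,
  "Clostridium_butyricum" = 0.1065769,
  "Clostridium_ramosum" = 0.1263867,
  "Escherichia_coli" = 0.118859,
  "Lactobacillus_plantarum" = 0.09997359)

#' Simulation configuration
#'
#' @param models named list of [metabolic_model()]s (bacteria and at
#'   most one host model; host agents fill every host slot).
#' @param abundances named numeric vector of relative abundances over
#'   the bacterial species (must sum to 1 within 1e-6). Single-species
#'   (mono-colonization) runs use `c(species = 1)`.
#' @param medium medium data.frame or TSV path (see [load_medium()]).
#' @param geometry an [arena_config()].
#' @param n_iterations iterations of length `dt`; default 7.
#' @param dt hours per iteration; default 1.
#' @param diffusion_only_first if `TRUE` (default) the first iteration
#'   only disperses compounds; metabolism starts at iteration 2.
#' @param n_replicates default 10.
#' @param seed root seed; each replicate derives independent placement,
#'   update-order and movement streams from it.
#' @param diet_compounds compounds reserved for the bacterial `"d"`
#'   exchanges; default `"glc"`.
#' @param seed_override optional named counts
#'   `c(LUMEN = , OUTER_MUCUS = , INNER_MUCUS = )` bypassing the
#'   inoculum formula.
#' @param advection_shift lumen advection in columns per iteration
#'   (default 0 = off); `advection_mode` as in [advect_lumen()].
#' @param advection_mode `"wrap"` or `"inflow"`.
#' @param diffusion diffusion parameters, a [diffusion_spec()].
#' @param require_growth_at_start if `TRUE` (default), error at startup
#'   when any model cannot grow on the configured medium (mirroring the
#'   gap-filling requirement of the reference workflow). Disable for
#'   deliberate starvation experiments such as the cross-feeding assay.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(models, abundances, medium,
                              geometry = arena_config(),
                              n_iterations = 7L, dt = 1,
                              diffusion_only_first = TRUE,
                              n_replicates = 10L, seed = 1L,
                              diet_compounds = "glc",
                              seed_override = NULL,
                              advection_shift = 0L,
                              advection_mode = "wrap",
                              diffusion = diffusion_spec(),
                              require_growth_at_start = TRUE) {
  stopifnot(inherits(geometry, "arena_config"))
  if (n_iterations < 1L) stop("simulation_config: n_iterations >= 1 required")
  kinds <- vapply(models, `[[`, "", "kind")
  bact <- names(models)[kinds == "bacterium"]
  if (length(abundances) > 0L) {
    if (any(abundances <= 0))
      stop("simulation_config: abundances must be positive")
    if (abs(sum(abundances) - 1) > 1e-6)
      stop("simulation_config: abundances must sum to 1 (got ",
           format(sum(abundances)), ")")
    miss <- setdiff(names(abundances), bact)
    if (length(miss) > 0L)
      stop("simulation_config: abundances name unknown bacterial model(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(models = models, abundances = abundances,
                 medium = medium, geometry = geometry,
                 n_iterations = as.integer(n_iterations), dt = dt,
                 diffusion_only_first = diffusion_only_first,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 diet_compounds = diet_compounds,
                 seed_override = seed_override,
                 advection_shift = as.integer(advection_shift),
                 advection_mode = advection_mode,
                 diffusion = diffusion,
                 require_growth_at_start = require_growth_at_start),
            class = "simulation_config")
}

#' Starting bacterial counts per sector from the inoculum formula
#'
#' Implements the published seeding rule: the bacterial amount of a
#' sector is its area fraction of the arena times the arena volume
#' times the inoculum,
#' `round(area_sector / area_total * volume_arena * inoculum_cfu)`,
#' with `volume_arena = (arena area in cm^2)^(3/2)` (the printed volume
#' formula is dimensionally inconsistent; this reading reproduces the
#' published starting counts). Under the default geometry this gives
#' lumen 29, outer mucus 18, inner mucus 9.
#'
#' @param geometry an `arena_geometry`.
#' @param config optional `simulation_config` carrying a
#'   `seed_override`.
#' @return named integer vector over the three bacterial seeding
#'   sectors.
#' @export
#' @examples
#' seed_counts(build_arena(arena_config()))
seed_counts <- function(geometry, config = NULL) {
  if (!is.null(config) && !is.null(config$seed_override))
    return(config$seed_override)
  cfg <- geometry$config
  area <- cfg$n_rows * cfg$n_cols * cfg$cell_edge^2       # cm^2
  volume_arena <- area^1.5                                # cm^3
  fr <- sector_areas(geometry)
  sectors <- c("LUMEN", "OUTER_MUCUS", "INNER_MUCUS")
  counts <- round(fr[sectors] * volume_arena * cfg$inoculum_cfu)
  free <- geometry$sector_counts[sectors]
  over <- counts > free
  if (any(over))
    stop("seed_counts: counts exceed free cells in sector(s) ",
         paste(sectors[over], collapse = ", "))
  stats::setNames(as.integer(counts), sectors)
}

## largest-remainder apportionment of `total` among abundances
.apportion <- function(total, abundances) {
  q <- total * abundances
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0L) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(abundances))
}

#' Place starting agents
#'
#' Within each seeding sector, species counts follow largest-remainder
#' apportionment of the sector total by relative abundance (so the
#' community composition is deterministic); positions are sampled
#' uniformly over the free cells of the sector. Host agents fill every
#' host slot. Uses the current RNG stream.
#'
#' @param counts named sector counts from [seed_counts()].
#' @param abundances named relative abundances of bacterial species.
#' @param geometry an `arena_geometry`.
#' @param models named model list (host placement needs `kind`).
#' @return list of agents.
#' @export
place_agents <- function(counts, abundances, geometry, models) {
  agents <- list()
  nid <- 0L
  for (sec in names(counts)) {
    ntot <- counts[[sec]]
    if (ntot == 0L) next
    per_species <- .apportion(ntot, abundances)
    cells <- which(geometry$sector_map == sec, arr.ind = TRUE)
    if (nrow(cells) < ntot)
      stop("place_agents: sector ", sec, " too small for ", ntot, " agents")
    pick <- cells[sample.int(nrow(cells), ntot), , drop = FALSE]
    k <- 0L
    for (sp in names(per_species)) {
      for (z in seq_len(per_species[[sp]])) {
        k <- k + 1L; nid <- nid + 1L
        agents[[nid]] <- new_agent(nid, sp, "bacterium",
                                   pick[k, 1], pick[k, 2])
      }
    }
  }
  hosts <- names(models)[vapply(models, `[[`, "", "kind") == "host"]
  if (length(hosts) > 0L) {
    hs <- geometry$host_slots
    for (i in seq_len(nrow(hs))) {
      nid <- nid + 1L
      agents[[nid]] <- new_agent(nid, hosts[[1L]], "host",
                                 hs[i, "row"], hs[i, "col"])
    }
  }
  agents
}

## run expr under a dedicated RNG stream identified by a small seed
.with_stream <- function(state_env, name, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state_env[[name]], globalenv())
  on.exit({
    state_env[[name]] <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  eval.parent(substitute(expr))
}

.init_streams <- function(rep_seed) {
  env <- new.env()
  for (k in seq_along(c("placement", "order", "movement"))) {
    nm <- c("placement", "order", "movement")[k]
    set.seed((rep_seed * 101L + k) %% .Machine$integer.max)
    env[[nm]] <- get(".Random.seed", globalenv())
  }
  env
}

#' Run the colon simulation
#'
#' Per replicate: the medium is loaded and, when
#' `diffusion_only_first`, iteration 1 only disperses compounds.
#' Every later iteration runs the agents' metabolic steps in a freshly
#' randomized order, then division/death, then movement, then
#' diffusion of every field, the blood boundary, and (optionally)
#' lumen advection. All exchange fluxes of every agent step are
#' recorded. Replicates are independent given the derived seeds and
#' bit-identical under identical configuration and seed.
#'
#' @param config a [simulation_config()].
#' @return list of `simulation_result` objects, one per replicate, each
#'   with `flux_records`, `agent_snapshots`, `field_totals`, `fields`
#'   (final state), `replicate` and `seeds`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  geometry <- build_arena(config$geometry)
  dspec <- config$diffusion

  medium <- config$medium
  if (is.character(medium)) medium <- utils::read.delim(medium)

  ## startup viability check: every model must grow on the medium
  for (m in if (config$require_growth_at_start) config$models else list()) {
    present <- unique(medium$compound_id)
    ov <- list()
    for (i in seq_len(nrow(m$exchanges))) {
      if (!m$exchanges$compound[i] %in% present) {
        rid <- m$exchanges$rxn_id[i]
        j <- match(rid, m$rxns$id)
        if (m$rxns$lb[j] < 0) ov[[rid]] <- c(0, m$rxns$ub[j])
      }
    }
    s <- fba(m, ov)
    if (s$status != "optimal" || s$objective_value <= 1e-9)
      stop("run_simulation: model ", m$id,
           " cannot grow on the configured medium")
  }

  lapply(seq_len(config$n_replicates), function(rep)
    .run_replicate(config, geometry, dspec, medium, rep))
}

## flatten the per-agent-step entries into one long data.frame: each
## entry contributes its exchange rows plus one NA-compound growth row
.assemble_flux_records <- function(entries) {
  if (length(entries) == 0L) return(NULL)
  counts <- vapply(entries, function(e) length(e$xc$compound) + 1L, 0L)
  grab <- function(nm, proto)
    rep(vapply(entries, `[[`, proto, nm), counts)
  xc <- function(nm, na)
    unlist(lapply(entries, function(e) c(e$xc[[nm]], na)),
           use.names = FALSE)
  data.frame(agent_id = grab("agent_id", 0L),
             species = grab("species", ""),
             kind = grab("kind", ""),
             row = grab("row", 0L), col = grab("col", 0L),
             sector = grab("sector", ""),
             compound = xc("compound", NA_character_),
             facing = xc("facing", NA_character_),
             flux = xc("flux", NA_real_),
             mass_flux = xc("mass_flux", NA_real_),
             time = grab("time", 0L),
             growth_rate = grab("growth_rate", 0),
             stringsAsFactors = FALSE)
}

.run_replicate <- function(config, geometry, dspec, medium, rep) {
  rep_seed <- (config$seed + rep - 1L) %% .Machine$integer.max
  streams <- .init_streams(rep_seed)

  fields <- load_medium(medium, geometry, dspec, config$diet_compounds)
  counts <- seed_counts(geometry, config)
  agents <- .with_stream(streams, "placement",
                         place_agents(counts, config$abundances, geometry,
                                      config$models))
  occupancy <- matrix(FALSE, nrow(geometry$sector_map),
                      ncol(geometry$sector_map))
  for (a in agents) occupancy[a$row, a$col] <- TRUE
  next_id <- length(agents)

  flux_records <- list()
  snapshots <- list()
  field_totals <- list()
  lp_cache <- new.env(parent = emptyenv())
  snap <- function(time, growth = NULL) {
    alive <- Filter(function(a) a$alive, agents)
    if (length(alive) == 0L)
      return(data.frame(time = integer(0), agent_id = integer(0),
                        species = character(0), kind = character(0),
                        row = integer(0), col = integer(0),
                        sector = character(0), biomass = numeric(0)))
    data.frame(
      time = time,
      agent_id = vapply(alive, `[[`, 0L, "id"),
      species = vapply(alive, `[[`, "", "species_id"),
      kind = vapply(alive, `[[`, "", "kind"),
      row = vapply(alive, `[[`, 0L, "row"),
      col = vapply(alive, `[[`, 0L, "col"),
      sector = geometry$sector_map[cbind(
        vapply(alive, `[[`, 0L, "row"), vapply(alive, `[[`, 0L, "col"))],
      biomass = vapply(alive, `[[`, 0, "biomass"),
      stringsAsFactors = FALSE)
  }
  snapshots[[1L]] <- cbind(snap(0L))

  for (it in seq_len(config$n_iterations)) {
    metabolic <- !(config$diffusion_only_first && it == 1L)
    if (metabolic) {
      ord <- .with_stream(streams, "order",
                          sample(seq_along(agents)))
      for (k in ord) {
        ag <- agents[[k]]
        if (!ag$alive) next
        st <- step_agent(ag, fields, geometry,
                         config$models[[ag$species_id]], config$dt,
                         cache = lp_cache, raw = TRUE)
        agents[[k]] <- st$agent
        fields <- st$fields
        ## one entry per agent-step: its exchange fluxes plus a growth
        ## observation (assembled into a data.frame once, at the end)
        flux_records[[length(flux_records) + 1L]] <- list(
          agent_id = ag$id, species = ag$species_id, kind = ag$kind,
          row = ag$row, col = ag$col,
          sector = geometry$sector_map[ag$row, ag$col],
          time = it, growth_rate = st$growth_rate,
          xc = st$exchanges)
      }
      ## division & death
      for (k in seq_along(agents)) {
        ag <- agents[[k]]
        if (!ag$alive || ag$kind == "host") next
        dd <- .with_stream(streams, "movement",
                           divide_or_die(ag, geometry, occupancy,
                                         next_id = next_id + 1L))
        agents[[k]] <- dd$agent
        if (dd$died) occupancy[ag$row, ag$col] <- FALSE
        if (!is.null(dd$offspring)) {
          next_id <- next_id + 1L
          agents[[length(agents) + 1L]] <- dd$offspring
          occupancy[dd$offspring$row, dd$offspring$col] <- TRUE
        }
      }
      ## movement
      for (k in seq_along(agents)) {
        ag <- agents[[k]]
        if (!ag$alive || ag$kind == "host") next
        moved <- .with_stream(streams, "movement",
                              move_agent(ag, geometry, occupancy, fields))
        if (moved$row != ag$row || moved$col != ag$col) {
          occupancy[ag$row, ag$col] <- FALSE
          occupancy[moved$row, moved$col] <- TRUE
        }
        agents[[k]] <- moved
      }
    }
    ## transport
    for (nm in names(fields))
      fields[[nm]] <- diffuse(fields[[nm]], geometry, dspec, config$dt)
    for (nm in names(fields))
      fields[[nm]] <- apply_blood_boundary(fields[[nm]], geometry)
    if (config$advection_shift > 0L) {
      adv <- advect_lumen(fields, agents, geometry,
                          config$advection_shift, config$advection_mode)
      fields <- adv$fields
      for (k in seq_along(adv$agents)) {
        if (!identical(adv$agents[[k]]$col, agents[[k]]$col) ||
            !adv$agents[[k]]$alive) {
          occupancy[agents[[k]]$row, agents[[k]]$col] <- FALSE
          if (adv$agents[[k]]$alive)
            occupancy[adv$agents[[k]]$row, adv$agents[[k]]$col] <- TRUE
        }
      }
      agents <- adv$agents
    }
    snapshots[[it + 1L]] <- snap(it)
    field_totals[[it]] <- data.frame(
      time = it, compound = names(fields),
      total = vapply(fields, function(f) sum(f$amounts), numeric(1)),
      row.names = NULL)
  }

  fr <- .assemble_flux_records(flux_records)
  structure(list(replicate = rep,
                 flux_records = fr,
                 agent_snapshots = do.call(rbind, snapshots),
                 field_totals = do.call(rbind, field_totals),
                 fields = fields,
                 agents = agents,
                 seeds = rep_seed,
                 dt = config$dt),
            class = "simulation_result")
}
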