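## Agent-level behavior: local uptake limits, pFBA metabolism, growth,
## division, death and movement. One agent occupies one grid cell;
## bacteria never enter the HOST sector, host cells never move.

.BAC_MIN_BIOMASS <- 1e-12   # gDW, ~1 pg dry weight of a bacterial cell
BACTERIA_SECTORS <- c("LUMEN", "OUTER_MUCUS", "INNER_MUCUS", "INTERMEDIATE")

#' Create an agent
#'
#' @param id integer agent id (unique within a replicate).
#' @param species_id id of the agent's metabolic model.
#' @param kind `"bacterium"` or `"host"`.
#' @param row,col 1-based grid position.
#' @param biomass gDW; defaults to the kind's minimum weight
#'   (bacterium: 1e-12 gDW; host: that times the min-weight scaling
#'   factor 132.73229/4.42).
#' @return an `agent` list.
#' @export
new_agent <- function(id, species_id, kind, row, col, biomass = NULL) {
  sc <- host_scaling()
  if (is.null(biomass))
    biomass <- if (kind == "host")
      .BAC_MIN_BIOMASS * sc$min_weight_factor else .BAC_MIN_BIOMASS
  structure(list(id = as.integer(id), species_id = species_id,
                 kind = kind, row = as.integer(row), col = as.integer(col),
                 biomass = biomass, alive = TRUE, starvation = 0L),
            class = "agent")
}

## 8-neighborhood of a position, clipped to the grid
.neighbors8 <- function(row, col, nr, nc) {
  dr <- rep(-1:1, times = 3); dc <- rep(-1:1, each = 3)
  keep <- !(dr == 0 & dc == 0)
  r <- row + dr[keep]; c <- col + dc[keep]
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  cbind(row = r[ok], col = c[ok])
}

## apical cells a host agent exchanges with on its "e" side: adjacent
## non-host cells of the intermediate space or the inner mucus
.host_apical_cells <- function(agent, geometry) {
  nb <- .neighbors8(agent$row, agent$col, nrow(geometry$sector_map),
                    ncol(geometry$sector_map))
  sec <- geometry$sector_map[nb]
  nb[sec %in% c("INTERMEDIATE", "INNER_MUCUS"), , drop = FALSE]
}

## the grid cells a given exchange reaction draws from / secretes into
.exchange_cells <- function(agent, facing, geometry) {
  if (agent$kind == "host" && facing == "e")
    return(.host_apical_cells(agent, geometry))
  cbind(row = agent$row, col = agent$col)
}

#' Local uptake bounds from compound availability
#'
#' For each exchange reaction of the agent's model, the uptake (lower)
#' bound is tightened to
#' `-min(|default lb|, available_mmol / (biomass * dt))`, the standard
#' amount-to-rate conversion that prevents an agent from consuming more
#' than its surroundings hold in one time step. `"d"`-facing exchanges
#' see only dietary pools, `"e"`-facing the shared local pool (for host
#' agents: the apical pool of adjacent intermediate / inner mucus
#' cells), `"u"`-facing the blood reservoir on the agent's own host
#' cell. An absent compound gives a bound of 0.
#'
#' @param agent an agent.
#' @param fields named list of [compound_field()]s.
#' @param geometry an `arena_geometry`.
#' @param model the agent's [metabolic_model()].
#' @param dt step length in hours.
#' @return named list of `c(lb, ub)` overrides for [pfba()].
#' @export
compute_uptake_bounds <- function(agent, fields, geometry, model, dt = 1) {
  ex <- model$exchanges
  out <- list()
  for (i in seq_len(nrow(ex))) {
    rid <- ex$rxn_id[i]
    j <- match(rid, model$rxns$id)
    lb0 <- model$rxns$lb[j]
    if (lb0 >= 0) next                          # no uptake route anyway
    key <- .find_field(fields, ex$compound[i], ex$facing[i])
    avail <- 0
    if (!is.na(key)) {
      cells <- .exchange_cells(agent, ex$facing[i], geometry)
      if (nrow(cells) > 0L)
        avail <- sum(fields[[key]]$amounts[cells])
    }
    out[[rid]] <- c(max(lb0, -avail / (agent$biomass * dt)),
                    model$rxns$ub[j])
  }
  out
}

#' One metabolic step of an agent
#'
#' Computes local uptake bounds, solves parsimonious FBA, debits and
#' credits the environment by `flux * biomass * dt` per exchanged
#' compound and updates biomass. An infeasible or zero-growth solution
#' increments the starvation counter and leaves the environment
#' unchanged (pFBA drives all fluxes to zero at zero growth).
#' Secreted compounds without an existing field get a fresh luminal
#' field created on the fly.
#'
#' @inheritParams compute_uptake_bounds
#' @param cache optional environment used to memoize pFBA solutions by
#'   (model, bounds); identical subproblems recur constantly in a
#'   simulation step and the solver is deterministic, so caching does
#'   not change any result.
#' @param raw if `TRUE`, return the exchange observations as plain
#'   vectors (`exchanges` element) instead of assembling a data.frame;
#'   used by the scheduler's hot loop.
#' @return list with `agent` (updated), `fields` (updated), `record`
#'   (data.frame of nonzero exchange fluxes plus the growth rate).
#' @export
step_agent <- function(agent, fields, geometry, model, dt = 1,
                       cache = NULL, raw = FALSE) {
  sector <- geometry$sector_map[agent$row, agent$col]
  bounds <- compute_uptake_bounds(agent, fields, geometry, model, dt)
  if (!is.null(cache)) {
    key <- paste(model$id, paste(names(bounds), collapse = ","),
                 paste(signif(unlist(bounds), 12), collapse = ","),
                 sep = "|")
    sol <- cache[[key]]
    if (is.null(sol)) {
      sol <- pfba(model, bounds)
      cache[[key]] <- sol
    }
  } else {
    sol <- pfba(model, bounds)
  }
  growth <- if (sol$status == "optimal") sol$objective_value else 0
  xc_comp <- character(0); xc_face <- character(0)
  xc_flux <- numeric(0); xc_mass <- numeric(0)
  if (sol$status == "optimal" && growth > 1e-9) {
    agent$starvation <- 0L
    ex <- model$exchanges
    for (i in seq_len(nrow(ex))) {
      v <- sol$fluxes[[ex$rxn_id[i]]]
      if (abs(v) < 1e-12) next
      delta <- v * agent$biomass * dt            # mmol; v<0 is uptake
      comp <- ex$compound[i]
      key <- .find_field(fields, comp, ex$facing[i])
      if (is.na(key)) {
        if (delta < 0) next                      # nothing there to take
        ## secretion into a compound the medium never contained:
        ## create a fresh (non-diet) luminal field for it
        mwrow <- match(comp, .TOY_COMPOUNDS$compound)
        key <- paste(comp, "luminal", sep = ".")
        fields[[key]] <- compound_field(
          comp, matrix(0, nrow(geometry$sector_map),
                       ncol(geometry$sector_map)),
          class = "luminal",
          molecular_weight = if (is.na(mwrow)) NA_real_ else
            .TOY_COMPOUNDS$mw[mwrow])
      }
      cells <- .exchange_cells(agent, ex$facing[i], geometry)
      if (nrow(cells) == 0L) next
      amts <- fields[[key]]$amounts[cells]
      if (delta < 0) {                           # uptake: debit pro rata
        tot <- sum(amts)
        take <- min(-delta, tot)
        if (tot > 0) {
          fields[[key]]$amounts[cells] <- pmax(amts - take * amts / tot, 0)
        }
      } else {                                   # secretion: split evenly
        fields[[key]]$amounts[cells] <- amts + delta / nrow(cells)
      }
      xc_comp <- c(xc_comp, comp); xc_face <- c(xc_face, ex$facing[i])
      xc_flux <- c(xc_flux, v); xc_mass <- c(xc_mass, delta)
    }
    agent <- update_biomass(agent, growth, dt)
  } else {
    agent$starvation <- agent$starvation + 1L
  }
  if (raw)
    return(list(agent = agent, fields = fields,
                exchanges = list(compound = xc_comp, facing = xc_face,
                                 flux = xc_flux, mass_flux = xc_mass),
                growth_rate = growth))
  k <- length(xc_comp)
  rec <- data.frame(agent_id = rep(agent$id, k),
                    species = rep(agent$species_id, k),
                    kind = rep(agent$kind, k),
                    row = rep(agent$row, k), col = rep(agent$col, k),
                    sector = rep(sector, k), compound = xc_comp,
                    facing = xc_face, flux = xc_flux,
                    mass_flux = xc_mass, stringsAsFactors = FALSE)
  attr(rec, "growth_rate") <- growth
  list(agent = agent, fields = fields, record = rec,
       growth_rate = growth)
}

#' Update agent biomass after a metabolic step
#'
#' Bacteria grow exponentially, `m <- m * exp(mu * dt)`. Host cells grow
#' linearly, `m <- m + mu * m0 * dt` with `m0` the host minimum weight,
#' capped at the host maximum weight (the 70 modeled cells stand in for
#' ~1000 crypt cells); host cells never divide.
#'
#' @param agent an agent.
#' @param growth_rate pFBA objective value (1/h), >= 0.
#' @param dt hours.
#' @return the updated agent.
#' @export
update_biomass <- function(agent, growth_rate, dt = 1) {
  if (growth_rate <= 0) return(agent)
  if (agent$kind == "bacterium") {
    agent$biomass <- agent$biomass * exp(growth_rate * dt)
  } else {
    sc <- host_scaling()
    m0 <- .BAC_MIN_BIOMASS * sc$min_weight_factor
    mmax <- m0 * sc$max_weight_factor
    agent$biomass <- min(agent$biomass + growth_rate * m0 * dt, mmax)
  }
  agent
}

#' Division and death of a bacterial agent
#'
#' A bacterium at or above twice the minimum mass divides, placing an
#' equal-mass offspring uniformly at random on a free 8-neighbor cell in
#' an allowed (non-HOST) sector; with no free neighbor the division is
#' deferred. An agent starved for `death_after` consecutive zero-growth
#' steps dies and is removed (its biomass is not recycled). Host agents
#' neither divide nor die.
#'
#' @param agent an agent.
#' @param geometry an `arena_geometry`.
#' @param occupancy logical matrix of occupied cells.
#' @param min_mass division reference mass (default the bacterial
#'   minimum weight).
#' @param death_after starvation limit in steps (default 2).
#' @param next_id id for a new offspring agent.
#' @return list `agent`, `offspring` (agent or `NULL`), `died` (flag);
#'   the caller updates occupancy.
#' @export
divide_or_die <- function(agent, geometry, occupancy,
                          min_mass = .BAC_MIN_BIOMASS, death_after = 2L,
                          next_id = agent$id + 1L) {
  if (agent$kind == "host")
    return(list(agent = agent, offspring = NULL, died = FALSE))
  if (agent$starvation >= death_after) {
    agent$alive <- FALSE
    return(list(agent = agent, offspring = NULL, died = TRUE))
  }
  offspring <- NULL
  if (agent$biomass >= 2 * min_mass) {
    nb <- .neighbors8(agent$row, agent$col, nrow(occupancy), ncol(occupancy))
    free <- nb[!occupancy[nb] &
                 geometry$sector_map[nb] %in% BACTERIA_SECTORS, ,
               drop = FALSE]
    if (nrow(free) > 0L) {
      pick <- free[sample.int(nrow(free), 1L), ]
      agent$biomass <- agent$biomass / 2
      offspring <- new_agent(next_id, agent$species_id, "bacterium",
                             pick[["row"]], pick[["col"]],
                             biomass = agent$biomass)
    }
  }
  list(agent = agent, offspring = offspring, died = FALSE)
}

#' Random-walk movement of a bacterial agent
#'
#' Moves to a uniformly chosen free 8-neighbor cell within the allowed
#' sectors (never HOST). An agent sitting in the inner mucus is trapped
#' until the local mucus is partially degraded: it moves only once the
#' summed mucus-class amount at its cell has fallen below
#' `degradation_threshold` times the initial per-cell amount.
#'
#' @param agent a bacterial agent.
#' @param geometry an `arena_geometry`.
#' @param occupancy logical occupancy matrix.
#' @param fields named list of compound fields (mucus gate).
#' @param degradation_threshold fraction of the initial local mucus
#'   amount below which the inner mucus becomes passable (default 0.5).
#' @return the (possibly moved) agent; caller updates occupancy.
#' @export
move_agent <- function(agent, geometry, occupancy, fields,
                       degradation_threshold = 0.5) {
  if (agent$kind == "host") return(agent)
  sector <- geometry$sector_map[agent$row, agent$col]
  if (sector == "INNER_MUCUS") {
    muc <- Filter(function(f) f$class == "mucus", fields)
    init <- sum(vapply(muc, function(f)
      f$initial_per_cell[agent$row, agent$col], numeric(1)))
    now <- sum(vapply(muc, function(f)
      f$amounts[agent$row, agent$col], numeric(1)))
    if (init > 0 && now >= degradation_threshold * init)
      return(agent)                              # intact mucus: trapped
  }
  nb <- .neighbors8(agent$row, agent$col, nrow(occupancy), ncol(occupancy))
  free <- nb[!occupancy[nb] &
               geometry$sector_map[nb] %in% BACTERIA_SECTORS, ,
             drop = FALSE]
  if (nrow(free) == 0L) return(agent)
  pick <- free[sample.int(nrow(free), 1L), ]
  agent$row <- pick[["row"]]; agent$col <- pick[["col"]]
  agent
}
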