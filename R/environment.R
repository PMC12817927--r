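#' Fit a power law D = a * MW^b to diffusivity data
#'
#' Least-squares fit of `log D = log a + b log MW`. Used to derive the
#' molecular-weight-dependent diffusion coefficients of the lumen and
#' mucus sectors from a calibration table.
#'
#' @param mw molecular weights (g/mol), all positive.
#' @param d diffusion coefficients (cm^2/s), all positive.
#' @return named numeric vector `c(a = , b = )`.
#' @export
#' @examples
#' fit_power_law(c(18, 180, 1000), 2e-8 * c(18, 180, 1000)^-0.5)
fit_power_law <- function(mw, d) {
  if (length(mw) < 2L || length(mw) != length(d))
    stop("fit_power_law: need >= 2 (MW, D) pairs")
  if (any(mw <= 0) || any(d <= 0))
    stop("fit_power_law: molecular weights and diffusivities must be positive")
  fit <- stats::lm(log(d) ~ log(mw))
  co <- stats::coef(fit)
  c(a = unname(exp(co[1])), b = unname(co[2]))
}

#' Diffusion parameters of the sectored arena
#'
#' @param lumen_coeffs,mucus_coeffs power-law coefficients `c(a, b)` of
#'   `D = a * MW^b` (cm^2/s) for the lumen and for mucus. Defaults are
#'   fitted from the synthetic calibration table shipped in
#'   `inst/extdata/diffusion_calibration.tsv` (the historical intestinal
#'   measurements behind the original coefficients are not
#'   redistributable; the synthetic defaults keep lumen > mucus and are
#'   scaled so a 1-h explicit step stays affordable).
#' @param outer_mucus_multiplier,inner_mucus_multiplier fractions of the
#'   mucus coefficient applied in the outer (2/3) and inner (1/3) mucus
#'   layers.
#' @param mucus_concentration_factor per-cell concentration ratio of
#'   mucus compounds between the two layers (default 4).
#' @param inner_denser if `TRUE` (default) the inner layer holds
#'   `mucus_concentration_factor` times the outer layer's per-cell
#'   amount; `FALSE` flips the direction.
#' @param glucose_mw fallback molecular weight for compounds without one
#'   (default 180.16, glucose).
#' @param max_substeps safety cap on automatic FTCS sub-stepping.
#' @return object of class `diffusion_spec`.
#' @export
diffusion_spec <- function(lumen_coeffs = NULL, mucus_coeffs = NULL,
                           outer_mucus_multiplier = 2 / 3,
                           inner_mucus_multiplier = 1 / 3,
                           mucus_concentration_factor = 4,
                           inner_denser = TRUE,
                           glucose_mw = 180.16,
                           max_substeps = 20000L) {
  if (is.null(lumen_coeffs) || is.null(mucus_coeffs)) {
    cal <- utils::read.delim(system.file("extdata",
                                         "diffusion_calibration.tsv",
                                         package = "colonsim"))
    if (is.null(lumen_coeffs)) {
      sub <- cal[cal$medium == "lumen", ]
      lumen_coeffs <- fit_power_law(sub$mw, sub$d_cm2_s)
    }
    if (is.null(mucus_coeffs)) {
      sub <- cal[cal$medium == "mucus", ]
      mucus_coeffs <- fit_power_law(sub$mw, sub$d_cm2_s)
    }
  }
  structure(list(lumen_coeffs = lumen_coeffs,
                 mucus_coeffs = mucus_coeffs,
                 outer_mucus_multiplier = outer_mucus_multiplier,
                 inner_mucus_multiplier = inner_mucus_multiplier,
                 mucus_concentration_factor = mucus_concentration_factor,
                 inner_denser = inner_denser,
                 glucose_mw = glucose_mw,
                 max_substeps = as.integer(max_substeps)),
            class = "diffusion_spec")
}

#' A per-compound concentration field on the arena grid
#'
#' @param compound_id compound identifier (matches the models' exchange
#'   registry `compound` column).
#' @param amounts numeric matrix of mmol per grid cell (same shape as
#'   the sector map).
#' @param class one of `"luminal"`, `"mucus"`, `"oxygen"`, `"blood"`.
#' @param molecular_weight g/mol; `NA` falls back to glucose.
#' @param diet if `TRUE`, only `"d"`-facing exchanges may draw from this
#'   field (dietary compounds are reserved for the bacteria).
#' @param blood_level per-host-cell Dirichlet level for blood/oxygen
#'   class compounds, re-imposed by [apply_blood_boundary()].
#' @return object of class `compound_field`.
#' @export
compound_field <- function(compound_id, amounts, class = "luminal",
                           molecular_weight = NA_real_, diet = FALSE,
                           blood_level = NA_real_) {
  class_ <- match.arg(class, c("luminal", "mucus", "oxygen", "blood"))
  if (any(amounts < 0)) stop("compound_field: negative amounts")
  structure(list(compound_id = compound_id, amounts = amounts,
                 class = class_, molecular_weight = molecular_weight,
                 diet = diet, blood_level = blood_level,
                 initial_per_cell = amounts,
                 lumen_fresh = NA_real_),
            class = "compound_field")
}

#' Sector-wise diffusion coefficient of a compound
#'
#' Encodes the arena's transport rules: the lumen uses the lumen power
#' law; outer/inner mucus use 2/3 and 1/3 of the mucus power law; the
#' intermediate layer and host space are impermeable to luminal and
#' mucus compounds; mucus compounds never diffuse anywhere; blood-class
#' compounds move only within host + intermediate sectors; oxygen only
#' within the host area (host + intermediate).
#'
#' @param field a [compound_field()] (or a list with `class` and
#'   `molecular_weight`).
#' @param sector sector label, one of `SECTORS`.
#' @param spec a [diffusion_spec()].
#' @return D in cm^2/s (possibly 0).
#' @export
diffusion_coefficient <- function(field, sector, spec = diffusion_spec()) {
  mw <- field$molecular_weight
  if (is.na(mw)) mw <- spec$glucose_mw
  if (field$class == "mucus") return(0)
  host_area <- sector %in% c("HOST", "INTERMEDIATE")
  if (field$class %in% c("blood", "oxygen"))
    return(if (host_area)
      spec$lumen_coeffs[["a"]] * mw^spec$lumen_coeffs[["b"]] else 0)
  ## luminal compounds
  if (sector == "LUMEN")
    return(spec$lumen_coeffs[["a"]] * mw^spec$lumen_coeffs[["b"]])
  dm <- spec$mucus_coeffs[["a"]] * mw^spec$mucus_coeffs[["b"]]
  if (sector == "OUTER_MUCUS") return(spec$outer_mucus_multiplier * dm)
  if (sector == "INNER_MUCUS") return(spec$inner_mucus_multiplier * dm)
  0
}

## per-cell D matrix for a field on a geometry
.d_matrix <- function(field, geometry, spec) {
  ds <- vapply(SECTORS, function(s) diffusion_coefficient(field, s, spec),
               numeric(1))
  matrix(ds[geometry$sector_map], nrow(geometry$sector_map),
         ncol(geometry$sector_map))
}

#' One diffusion step of a compound field
#'
#' Conservative explicit finite differences (FTCS) on the 4-neighbor
#' stencil with per-cell diffusivity. The interface coefficient between
#' two cells is the arithmetic mean of their diffusivities, or 0 if
#' either side is impermeable, which gives zero-flux boundaries at the
#' grid border and at sector boundaries automatically. Sub-steps are
#' chosen to satisfy the stability bound `D dt / h^2 <= 1/4`. Total
#' amount is conserved to machine precision.
#'
#' @param field a [compound_field()].
#' @param geometry an `arena_geometry`.
#' @param spec a [diffusion_spec()].
#' @param dt time step in hours.
#' @return the field after diffusion.
#' @export
diffuse <- function(field, geometry, spec = diffusion_spec(), dt = 1) {
  D <- .d_matrix(field, geometry, spec)
  dmax <- max(D)
  if (dmax == 0 || dt <= 0) return(field)
  h2 <- geometry$config$cell_edge^2
  dt_s <- dt * 3600
  n_sub <- ceiling(dt_s * dmax / (0.25 * h2))
  if (n_sub > spec$max_substeps)
    stop("diffuse: stability requires ", n_sub, " sub-steps (cap ",
         spec$max_substeps, "); lower the diffusion coefficients or dt")
  tau <- dt_s / n_sub / h2
  A <- field$amounts
  nr <- nrow(A); nc <- ncol(A)
  ## interface diffusivities (0 when either side is impermeable),
  ## pre-scaled by dt_sub / h^2 for the compiled kernel
  Dv <- (D[-nr, , drop = FALSE] + D[-1, , drop = FALSE]) / 2 *
    (D[-nr, , drop = FALSE] > 0) * (D[-1, , drop = FALSE] > 0) * tau
  Dh <- (D[, -nc, drop = FALSE] + D[, -1, drop = FALSE]) / 2 *
    (D[, -nc, drop = FALSE] > 0) * (D[, -1, drop = FALSE] > 0) * tau
  A <- .ftcs_diffuse_cpp(A, Dv, Dh, as.integer(n_sub))
  if (any(A < -1e-15 * max(abs(field$amounts), 1e-300)))
    stop("diffuse: negative concentrations; stability bound violated")
  A[A < 0] <- 0
  field$amounts <- A
  field
}

#' Impose the blood reservoir on host-sector cells
#'
#' Blood and oxygen class compounds are fed from the circulation:
#' host-sector cells are reset to the field's `blood_level` each step
#' (Dirichlet boundary), from where the compound diffuses into the
#' intermediate space. Luminal and mucus fields are untouched.
#'
#' @param field a [compound_field()].
#' @param geometry an `arena_geometry`.
#' @return the updated field.
#' @export
apply_blood_boundary <- function(field, geometry) {
  if (!field$class %in% c("blood", "oxygen")) return(field)
  if (is.na(field$blood_level)) return(field)
  field$amounts[geometry$sector_map == "HOST"] <- field$blood_level
  field
}

#' Translate lumen contents along the flow axis (peristalsis)
#'
#' Shifts the lumen-sector content of every field (and the lumen-sector
#' agents) `shift_cells` columns along x. `mode = "wrap"` conserves
#' totals exactly; `mode = "inflow"` discards the outflow and fills the
#' inflowing columns with fresh medium at each field's initial lumen
#' per-cell amount. Off by default in simulations (`shift_cells = 0`).
#'
#' @param fields named list of [compound_field()]s.
#' @param agents list of agents (possibly empty).
#' @param geometry an `arena_geometry`.
#' @param shift_cells non-negative integer columns per step.
#' @param mode `"wrap"` or `"inflow"`.
#' @return list with elements `fields` and `agents`.
#' @export
advect_lumen <- function(fields, agents, geometry, shift_cells = 0L,
                         mode = c("wrap", "inflow")) {
  mode <- match.arg(mode)
  shift_cells <- as.integer(shift_cells)
  if (shift_cells < 0L) stop("advect_lumen: shift must be >= 0")
  if (shift_cells == 0L) return(list(fields = fields, agents = agents))
  lum <- geometry$sector_map == "LUMEN"
  lum_rows <- which(apply(lum, 1, any))
  nc <- ncol(geometry$sector_map)
  s <- shift_cells %% nc
  new_cols <- function(old) ((old - 1L + s) %% nc) + 1L
  for (nm in names(fields)) {
    A <- fields[[nm]]$amounts
    blk <- A[lum_rows, , drop = FALSE]
    if (mode == "wrap") {
      A[lum_rows, new_cols(seq_len(nc))] <- blk
    } else {
      shifted <- matrix(0, length(lum_rows), nc)
      keep <- if (shift_cells >= nc) integer(0) else seq_len(nc - s)
      if (length(keep) > 0L) shifted[, keep + s] <- blk[, keep]
      fill <- if (shift_cells >= nc) seq_len(nc) else seq_len(s)
      fresh <- fields[[nm]]$lumen_fresh
      if (!is.na(fresh) && length(fill) > 0L) shifted[, fill] <- fresh
      A[lum_rows, ] <- shifted
    }
    fields[[nm]]$amounts <- A
  }
  for (i in seq_along(agents)) {
    ag <- agents[[i]]
    if (geometry$sector_map[ag$row, ag$col] != "LUMEN") next
    if (mode == "wrap") {
      agents[[i]]$col <- new_cols(ag$col)
    } else {
      newc <- ag$col + s
      if (newc > nc || shift_cells >= nc) {
        agents[[i]]$alive <- FALSE      # washed out
      } else {
        agents[[i]]$col <- newc
      }
    }
  }
  list(fields = fields, agents = agents)
}

#' Load a medium definition into compound fields
#'
#' The medium is a TSV/data.frame with columns `compound_id`, `class`
#' (`luminal`, `mucus`, `oxygen`, `blood`), `amount_mmol` (total) and
#' optional `molecular_weight`. Luminal compounds are spread uniformly
#' over lumen cells; mucus compounds over the two mucus layers with the
#' inner layer's per-cell amount `mucus_concentration_factor` times the
#' outer one's; blood and oxygen compounds are spread over host cells
#' and their per-cell level becomes the Dirichlet `blood_level`.
#'
#' @param medium file path or data.frame.
#' @param geometry an `arena_geometry`.
#' @param spec a [diffusion_spec()].
#' @param diet_compounds compounds reserved for `"d"`-facing (bacterial
#'   dietary) exchanges.
#' @return named list of [compound_field()]s.
#' @export
load_medium <- function(medium, geometry, spec = diffusion_spec(),
                        diet_compounds = character(0)) {
  if (is.character(medium))
    medium <- utils::read.delim(medium, stringsAsFactors = FALSE)
  need <- c("compound_id", "class", "amount_mmol")
  if (!all(need %in% names(medium)))
    stop("load_medium: medium needs columns ", paste(need, collapse = ", "))
  if (!"molecular_weight" %in% names(medium))
    medium$molecular_weight <- NA_real_
  sm <- geometry$sector_map
  fields <- list()
  for (i in seq_len(nrow(medium))) {
    cls <- medium$class[i]
    amt <- medium$amount_mmol[i]
    A <- matrix(0, nrow(sm), ncol(sm))
    blood_level <- NA_real_
    fresh <- NA_real_
    if (cls == "luminal") {
      cells <- sm == "LUMEN"
      if (amt > 0 && !any(cells))
        stop("load_medium: no lumen cells for ", medium$compound_id[i])
      if (any(cells)) {
        A[cells] <- amt / sum(cells)
        fresh <- amt / sum(cells)
      }
    } else if (cls == "mucus") {
      f <- spec$mucus_concentration_factor
      io <- if (spec$inner_denser) c(1, f) else c(f, 1)
      no <- sum(sm == "OUTER_MUCUS"); ni <- sum(sm == "INNER_MUCUS")
      denom <- io[1] * no + io[2] * ni
      if (amt > 0 && denom == 0)
        stop("load_medium: no mucus cells for ", medium$compound_id[i])
      if (denom > 0) {
        A[sm == "OUTER_MUCUS"] <- io[1] * amt / denom
        A[sm == "INNER_MUCUS"] <- io[2] * amt / denom
      }
    } else if (cls %in% c("blood", "oxygen")) {
      nh <- sum(sm == "HOST")
      if (amt > 0 && nh == 0)
        stop("load_medium: no host cells for blood compound ",
             medium$compound_id[i])
      if (nh > 0) {
        blood_level <- amt / nh
        A[sm == "HOST"] <- blood_level
      }
    } else {
      stop("load_medium: unknown compound class '", cls, "'")
    }
    fld <- compound_field(medium$compound_id[i], A, cls,
                          medium$molecular_weight[i],
                          diet = cls == "luminal" &&
                            medium$compound_id[i] %in% diet_compounds,
                          blood_level = blood_level)
    fld$lumen_fresh <- fresh
    key <- paste(medium$compound_id[i], cls, sep = ".")
    if (!is.null(fields[[key]])) {
      fields[[key]]$amounts <- fields[[key]]$amounts + fld$amounts
    } else {
      fields[[key]] <- fld
    }
  }
  fields
}

## locate the field a given exchange route talks to; fields are keyed
## by "<compound>.<class>" so one compound may live in several pools
## (e.g. dietary glucose in the lumen and glucose in the blood)
.find_field <- function(fields, compound, facing) {
  for (key in names(fields)) {
    f <- fields[[key]]
    if (f$compound_id != compound) next
    hit <- switch(facing,
                  d = f$diet,
                  e = !f$diet && !f$class %in% c("blood", "oxygen"),
                  u = f$class %in% c("blood", "oxygen"),
                  FALSE)
    if (hit) return(key)
  }
  NA_character_
}
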