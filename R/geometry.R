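## Sector labels used throughout the package. Order matters only for
## display; the sector map stores these strings.
SECTORS <- c("LUMEN", "OUTER_MUCUS", "INNER_MUCUS", "INTERMEDIATE", "HOST")

#' Arena configuration
#'
#' Parameters of the colon-like 2D grid. Defaults reproduce the published
#' reference layout: a 179 x 24 grid of 2.5 um cells, a mucus blanket of
#' 54 rows split 2:1 into outer and inner layers, and a 66-row tissue
#' region carrying two half-crypts whose epithelial lining provides 70
#' host-cell slots (2 x 31-cell crypt walls on the lateral columns plus an
#' 8-cell basal band on the tissue surface).
#'
#' @param n_rows grid cells along y (lumen at the top, tissue at the
#'   bottom); default 179.
#' @param n_cols grid cells along x (direction of luminal flow);
#'   default 24.
#' @param cell_edge edge length of one grid cell in cm; default 0.00025.
#' @param mucus_total_rows total mucus blanket thickness in rows; the
#'   inner layer gets `round(mucus_total_rows / 3)` rows, the outer layer
#'   the remainder. Default 54.
#' @param crypt_depth_rows depth of each half-crypt wall in rows
#'   (default 31, from 31.1 epithelial cells per crypt column).
#' @param tissue_rows rows of the host tissue region (host cells +
#'   intermediate space) at the bottom of the grid; default 66. Set to 0
#'   together with `host_capacity = 0` for a bacteria-only arena.
#' @param host_capacity number of epithelial host-cell slots; default 70
#'   (= 2 x `crypt_depth_rows` + basal band of 8).
#' @param gut_volume total volume of the modeled gut segment in cm^3
#'   (cecum + colon + rectum of a mouse); default 0.37. Contextual
#'   anatomical anchor; not part of the seeding formula (see
#'   [seed_counts()]).
#' @param inoculum_cfu bacterial inoculum in colony-forming units;
#'   default 2e7 (200 uL of 1e8 cfu/mL).
#' @return an object of class `arena_config`.
#' @export
#' @examples
#' cfg <- arena_config()
#' geo <- build_arena(cfg)
#' table(geo$sector_map)
arena_config <- function(n_rows = 179L, n_cols = 24L, cell_edge = 0.00025,
                         mucus_total_rows = 54L, crypt_depth_rows = 31L,
                         tissue_rows = 66L, host_capacity = 70L,
                         gut_volume = 0.37, inoculum_cfu = 2e7) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_edge = cell_edge,
              mucus_total_rows = as.integer(mucus_total_rows),
              crypt_depth_rows = as.integer(crypt_depth_rows),
              tissue_rows = as.integer(tissue_rows),
              host_capacity = as.integer(host_capacity),
              gut_volume = gut_volume, inoculum_cfu = inoculum_cfu)
  if (cfg$n_rows <= 0L || cfg$n_cols <= 0L)
    stop("arena_config: grid dimensions must be positive")
  if (cfg$cell_edge <= 0) stop("arena_config: cell_edge must be positive")
  if (cfg$mucus_total_rows < 0L)
    stop("arena_config: mucus_total_rows must be >= 0")
  if (cfg$crypt_depth_rows >= cfg$n_rows)
    stop("arena_config: crypt_depth_rows (", cfg$crypt_depth_rows,
         ") must be smaller than n_rows (", cfg$n_rows, ")")
  if (cfg$host_capacity > 0L && cfg$tissue_rows < cfg$crypt_depth_rows)
    stop("arena_config: tissue_rows (", cfg$tissue_rows,
         ") cannot be shallower than crypt_depth_rows (",
         cfg$crypt_depth_rows, ")")
  if (cfg$mucus_total_rows + cfg$tissue_rows > cfg$n_rows)
    stop("arena_config: mucus (", cfg$mucus_total_rows, ") + tissue (",
         cfg$tissue_rows, ") rows exceed n_rows (", cfg$n_rows, ")")
  basal <- cfg$host_capacity - 2L * cfg$crypt_depth_rows
  if (cfg$host_capacity > 0L && basal < 0L)
    stop("arena_config: host_capacity (", cfg$host_capacity,
         ") below the 2 crypt walls (", 2L * cfg$crypt_depth_rows, ")")
  if (cfg$host_capacity > 0L && basal > cfg$n_cols - 2L)
    stop("arena_config: basal band (", basal,
         ") wider than the inter-cryptal space (", cfg$n_cols - 2L, ")")
  class(cfg) <- "arena_config"
  cfg
}

#' Build the colon-like arena geometry
#'
#' Deterministically assigns every grid cell to one of five sectors.
#' From the top: `LUMEN` rows, then `OUTER_MUCUS` and `INNER_MUCUS`
#' (2:1 split of the mucus blanket), then the tissue region. Inside the
#' tissue region the two half-crypt walls (leftmost and rightmost
#' columns, `crypt_depth_rows` cells deep from the tissue surface) and
#' the basal band on the surface of the inter-cryptal space are `HOST`;
#' every other tissue cell is `INTERMEDIATE`. Bacteria may never enter
#' `HOST`; they can sit next to host cells in the intermediate space.
#'
#' @param config an [arena_config()].
#' @return an object of class `arena_geometry` with elements
#'   `sector_map` (character matrix `n_rows` x `n_cols`), `host_slots`
#'   (two-column matrix of 1-based (row, col) host positions, ordered),
#'   `sector_counts` (named integer vector) and `config`.
#' @export
build_arena <- function(config = arena_config()) {
  stopifnot(inherits(config, "arena_config"))
  nr <- config$n_rows; nc <- config$n_cols
  sm <- matrix("LUMEN", nr, nc)

  tissue_top <- nr - config$tissue_rows + 1L   # first tissue row (1-based)
  mucus_top <- tissue_top - config$mucus_total_rows
  if (mucus_top < 1L)
    stop("build_arena: mucus blanket does not fit above the tissue region")
  inner_rows <- round(config$mucus_total_rows / 3)
  outer_rows <- config$mucus_total_rows - inner_rows
  if (outer_rows > 0L)
    sm[seq.int(mucus_top, mucus_top + outer_rows - 1L), ] <- "OUTER_MUCUS"
  if (inner_rows > 0L)
    sm[seq.int(mucus_top + outer_rows, tissue_top - 1L), ] <- "INNER_MUCUS"
  if (config$tissue_rows > 0L)
    sm[seq.int(tissue_top, nr), ] <- "INTERMEDIATE"

  host_slots <- matrix(integer(0), 0L, 2L,
                       dimnames = list(NULL, c("row", "col")))
  if (config$host_capacity > 0L) {
    depth <- config$crypt_depth_rows
    wall_rows <- seq.int(tissue_top, tissue_top + depth - 1L)
    basal <- config$host_capacity - 2L * depth
    basal_cols <- if (basal > 0L) {
      start <- 1L + (nc - basal) %/% 2L          # centered in the space
      seq.int(start, start + basal - 1L)
    } else integer(0)
    slots <- rbind(
      cbind(wall_rows, rep(1L, depth)),           # left half-crypt wall
      cbind(wall_rows, rep(nc, depth)),           # right half-crypt wall
      cbind(rep(tissue_top, length(basal_cols)), basal_cols))
    colnames(slots) <- c("row", "col")
    sm[slots] <- "HOST"
    host_slots <- slots
  }

  counts <- vapply(SECTORS, function(s) sum(sm == s), integer(1))
  geo <- list(sector_map = sm, host_slots = host_slots,
              sector_counts = counts, config = config)
  class(geo) <- "arena_geometry"
  geo
}

#' Per-sector area fractions
#'
#' @param geometry an [build_arena()] result.
#' @return named numeric vector of area fractions over all five sectors
#'   (zero-area sectors included); sums to 1.
#' @export
sector_areas <- function(geometry) {
  stopifnot(inherits(geometry, "arena_geometry"))
  geometry$sector_counts / sum(geometry$sector_counts)
}

#' Export the sector map as a tidy TSV raster
#'
#' One line per grid cell: `row`, `col` (1-based), `sector`.
#'
#' @param geometry an `arena_geometry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_arena_tsv <- function(geometry, path) {
  stopifnot(inherits(geometry, "arena_geometry"))
  nr <- nrow(geometry$sector_map); nc <- ncol(geometry$sector_map)
  df <- data.frame(row = rep(seq_len(nr), times = nc),
                   col = rep(seq_len(nc), each = nr),
                   sector = as.vector(geometry$sector_map))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.arena_geometry <- function(x, ...) {
  cfg <- x$config
  cat("arena_geometry:", cfg$n_rows, "x", cfg$n_cols, "grid (",
      cfg$cell_edge, "cm cells )\n")
  print(x$sector_counts)
  invisible(x)
}

#' Area of a circular cell cross-section
#'
#' Utility behind the host-cell weight scaling: a colonocyte of 13 um
#' diameter has cross-section pi * 6.5^2 = 132.73229 um^2, against the
#' 4.42 um^2 default bacterial footprint.
#'
#' @param diameter_um cell diameter in micrometers.
#' @return area in um^2.
#' @export
#' @examples
#' round(circle_area(13), 5)   # 132.73229
circle_area <- function(diameter_um) {
  pi * (diameter_um / 2)^2
}

#' Host-cell weight scaling factors
#'
#' The host epithelial cells are represented on the same grid as
#' bacteria, so their biomass is expressed in bacterium-equivalent
#' units. The minimum-weight factor is the ratio of a 13-um colonocyte
#' cross-section (132.73229 um^2) to the 4.42 um^2 bacterial default;
#' the maximum-weight factor encodes that the 70 modeled epithelial
#' cells stand in for the weight of about 1,000 crypt cells.
#'
#' @param host_cell_diameter_um colonocyte diameter, default 13.
#' @param bacterial_area_um2 default bacterial cross-section, 4.42.
#' @param crypt_cells weight-equivalent cells of a full crypt, 1000.
#' @param host_slots modeled host slots, 70.
#' @return list with `min_weight_factor` (~30.03) and
#'   `max_weight_factor` (1000/70 ~ 14.29), both > 1.
#' @export
host_scaling <- function(host_cell_diameter_um = 13,
                         bacterial_area_um2 = 4.42,
                         crypt_cells = 1000, host_slots = 70) {
  list(min_weight_factor = circle_area(host_cell_diameter_um) /
         bacterial_area_um2,
       max_weight_factor = crypt_cells / host_slots)
}
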