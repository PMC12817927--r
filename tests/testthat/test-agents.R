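# a compact arena with a host raster, used throughout: 30 rows, 8 cols,
# 9 mucus rows (3 inner), 12 tissue rows, two 5-cell crypt walls + 4
# basal cells = 14 host slots
agent_world <- function() {
  cfgc <- arena_config(n_rows = 30, n_cols = 8, mucus_total_rows = 9,
                       crypt_depth_rows = 5, tissue_rows = 12,
                       host_capacity = 14)
  geo <- build_arena(cfgc)
  mods <- generate_toy_community(toy_community_spec())
  fields <- load_medium(toy_medium(geo), geo, diffusion_spec(),
                        diet_compounds = "glc")
  list(geo = geo, mods = mods, fields = fields)
}

test_that("uptake bounds reflect local availability", {
  w <- agent_world()
  deg <- w$mods$ToyMucivorans
  # a lumen cell: glucose present via the diet route, no mucus compound
  a <- new_agent(1, "ToyMucivorans", "bacterium", 2, 2)
  b <- compute_uptake_bounds(a, w$fields, w$geo, deg)
  expect_equal(b$EX_nana_e[1], 0)              # absent locally -> no uptake
  glc_cell <- w$fields[["glc.luminal"]]$amounts[2, 2]
  expect_equal(b$EX_glc_d[1],
               max(-10, -glc_cell / (a$biomass * 1)))
  # abundant compound: bound capped at the model default
  w$fields[["glc.luminal"]]$amounts[2, 2] <- 1
  b2 <- compute_uptake_bounds(a, w$fields, w$geo, deg)
  expect_equal(b2$EX_glc_d[1], -10)
  # an inner mucus cell: nana present
  im <- which(w$geo$sector_map == "INNER_MUCUS", arr.ind = TRUE)[1, ]
  a3 <- new_agent(2, "ToyMucivorans", "bacterium", im[1], im[2])
  b3 <- compute_uptake_bounds(a3, w$fields, w$geo, deg)
  expect_lt(b3$EX_nana_e[1], 0)
})

test_that("host agents draw blood via u and the apical pool via e", {
  w <- agent_world()
  host <- w$mods$ToyColonocyte
  slot <- w$geo$host_slots[nrow(w$geo$host_slots), ]  # basal band cell
  a <- new_agent(1, "ToyColonocyte", "host", slot[["row"]], slot[["col"]])
  b <- compute_uptake_bounds(a, w$fields, w$geo, host)
  expect_lt(b$EX_glc_u[1], 0)                  # blood glucose available
  expect_lt(b$EX_o2_u[1], 0)
  expect_equal(b$EX_but_e[1], 0)               # no butyrate around yet
  # drop butyrate into an adjacent apical cell
  ap <- colonsim:::.host_apical_cells(a, w$geo)
  expect_gt(nrow(ap), 0)
  key <- "but.luminal"
  w$fields[[key]] <- compound_field("but",
                                    matrix(0, 30, 8), "luminal", 88.11)
  w$fields[[key]]$amounts[ap[1, 1], ap[1, 2]] <- 1e-10
  b2 <- compute_uptake_bounds(a, w$fields, w$geo, host)
  expect_lt(b2$EX_but_e[1], 0)
  # dietary glucose is invisible to the host e/u routes
  expect_null(b2$EX_glc_e)
})

test_that("a metabolic step conserves matter exactly", {
  w <- agent_world()
  a <- new_agent(1, "ToyButyrivibrio", "bacterium", 2, 3)
  tot0 <- vapply(w$fields, function(f) sum(f$amounts), numeric(1))
  st <- step_agent(a, w$fields, w$geo, w$mods$ToyButyrivibrio, dt = 1)
  tot1 <- vapply(st$fields, function(f) sum(f$amounts), numeric(1))
  expect_gt(st$growth_rate, 0)
  expect_gt(st$agent$biomass, a$biomass)
  # environment change = -sum(flux * biomass * dt), per compound pool
  # (each record is routed to the pool its facing tag addresses)
  rec_key <- vapply(seq_len(nrow(st$record)), function(i)
    colonsim:::.find_field(st$fields, st$record$compound[i],
                           st$record$facing[i]), "")
  for (key in names(tot1)) {
    expected_delta <- sum(st$record$mass_flux[rec_key == key])
    observed <- tot1[[key]] - if (key %in% names(tot0)) tot0[[key]] else 0
    expect_equal(observed, expected_delta, tolerance = 1e-9)
  }
})

test_that("an agent in an empty world neither grows nor touches it", {
  w <- agent_world()
  empty <- list()
  a <- new_agent(1, "ToyButyrivibrio", "bacterium", 2, 3)
  st <- step_agent(a, empty, w$geo, w$mods$ToyButyrivibrio)
  expect_equal(st$growth_rate, 0)
  expect_identical(st$agent$starvation, 1L)
  expect_identical(nrow(st$record), 0L)
  expect_identical(st$agent$biomass, a$biomass)
})

test_that("a mucus degrader strictly depletes its local mucus patch", {
  w <- agent_world()
  im <- which(w$geo$sector_map == "INNER_MUCUS", arr.ind = TRUE)[5, ]
  a <- new_agent(1, "ToyMucivorans", "bacterium", im[1], im[2])
  fields <- w$fields
  prev <- fields[["nana.mucus"]]$amounts[im[1], im[2]]
  for (k in 1:3) {
    st <- step_agent(a, fields, w$geo, w$mods$ToyMucivorans)
    a <- st$agent; fields <- st$fields
    now <- fields[["nana.mucus"]]$amounts[im[1], im[2]]
    expect_lt(now, prev)
    prev <- now
  }
})

test_that("biomass update follows the stated growth laws", {
  a <- new_agent(1, "x", "bacterium", 1, 1)
  expect_identical(update_biomass(a, 0)$biomass, a$biomass)
  expect_equal(update_biomass(a, log(2), dt = 1)$biomass, 2 * a$biomass,
               tolerance = 1e-12)
  # host: linear growth, hard cap, no divisions ever
  h <- new_agent(2, "h", "host", 1, 1)
  sc <- host_scaling()
  m0 <- h$biomass
  h2 <- update_biomass(h, 0.5, dt = 1)
  expect_equal(h2$biomass, m0 + 0.5 * m0, tolerance = 1e-12)
  h_max <- h
  h_max$biomass <- m0 * sc$max_weight_factor
  expect_equal(update_biomass(h_max, 5, dt = 1)$biomass,
               m0 * sc$max_weight_factor)
  occ <- matrix(FALSE, 3, 3)
  dd <- divide_or_die(h_max, tiny_arena(3, 3, 0), occ)
  expect_null(dd$offspring)
})

test_that("division splits mass, defers when crowded, death removes", {
  geo <- tiny_arena(5, 5, mucus = 0)
  occ <- matrix(FALSE, 5, 5)
  a <- new_agent(1, "x", "bacterium", 3, 3)
  a$biomass <- 2.2 * colonsim:::.BAC_MIN_BIOMASS
  occ[3, 3] <- TRUE
  set.seed(1)
  dd <- divide_or_die(a, geo, occ, next_id = 99L)
  expect_false(dd$died)
  expect_equal(dd$agent$biomass, 1.1 * colonsim:::.BAC_MIN_BIOMASS)
  expect_equal(dd$offspring$biomass, dd$agent$biomass)
  expect_identical(dd$offspring$id, 99L)
  expect_true(abs(dd$offspring$row - 3) <= 1 &&
                abs(dd$offspring$col - 3) <= 1)
  # fully crowded: no division, mass retained
  occ[] <- TRUE
  dd2 <- divide_or_die(a, geo, occ)
  expect_null(dd2$offspring)
  expect_equal(dd2$agent$biomass, a$biomass)
  # starvation death
  s <- new_agent(2, "x", "bacterium", 2, 2)
  s$starvation <- 2L
  dd3 <- divide_or_die(s, geo, occ)
  expect_true(dd3$died)
  expect_false(dd3$agent$alive)
})

test_that("movement: uniform over free neighbors, never into HOST", {
  geo <- tiny_arena(5, 5, mucus = 0)
  occ <- matrix(FALSE, 5, 5)
  a <- new_agent(1, "x", "bacterium", 3, 3)
  set.seed(42)
  tab <- table(replicate(10000, {
    m <- move_agent(a, geo, occ, list())
    paste(m$row, m$col)
  }))
  expect_identical(length(tab), 8L)
  expect_gt(chisq.test(tab)$p.value, 0.001)    # uniform over the 8 cells
  # exhaustive: an agent beside the host raster can never enter it
  w <- agent_world()
  occw <- matrix(FALSE, 30, 8)
  hs <- w$geo$host_slots[1, ]                  # top of the left wall
  nb <- colonsim:::.neighbors8(hs[["row"]], hs[["col"]], 30, 8)
  start <- nb[w$geo$sector_map[nb] != "HOST", , drop = FALSE][1, ]
  ag <- new_agent(2, "x", "bacterium", start[["row"]], start[["col"]])
  for (k in 1:200) {
    ag <- move_agent(ag, w$geo, occw, list())
    expect_false(w$geo$sector_map[ag$row, ag$col] == "HOST")
  }
})

test_that("intact inner mucus traps agents; degraded mucus frees them", {
  w <- agent_world()
  im <- which(w$geo$sector_map == "INNER_MUCUS", arr.ind = TRUE)[4, ]
  a <- new_agent(1, "x", "bacterium", im[1], im[2])
  occ <- matrix(FALSE, 30, 8)
  for (k in 1:50) {
    a2 <- move_agent(a, w$geo, occ, w$fields)
    expect_identical(c(a2$row, a2$col), c(a$row, a$col))
  }
  # degrade below half of the initial amount: now it can move
  fields <- w$fields
  for (key in c("nana.mucus", "fuc.mucus"))
    fields[[key]]$amounts[im[1], im[2]] <-
      0.4 * fields[[key]]$initial_per_cell[im[1], im[2]]
  set.seed(9)
  moved <- any(replicate(20, {
    m <- move_agent(a, w$geo, occ, fields)
    any(c(m$row, m$col) != c(a$row, a$col))
  }))
  expect_true(moved)
})
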