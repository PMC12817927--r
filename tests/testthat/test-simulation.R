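# small but complete world reused by the scheduler tests
sim_world <- function(n_fermenters = 0L) {
  mods <- generate_toy_community(toy_community_spec(
    n_fermenters = n_fermenters))
  bact <- names(mods)[vapply(mods, `[[`, "", "kind") == "bacterium"]
  list(mods = mods,
       ab = stats::setNames(rep(1 / length(bact), length(bact)), bact),
       geoc = arena_config(n_rows = 40, n_cols = 10,
                           mucus_total_rows = 12, crypt_depth_rows = 6,
                           tissue_rows = 14, host_capacity = 16))
}

test_that("seed_counts reproduces the published starting amounts", {
  geo <- build_arena(arena_config())
  counts <- seed_counts(geo)
  expect_identical(counts, c(LUMEN = 29L, OUTER_MUCUS = 18L,
                             INNER_MUCUS = 9L))
  # inoculum 0: all zero
  geo0 <- build_arena(arena_config(inoculum_cfu = 0))
  expect_true(all(seed_counts(geo0) == 0L))
  # linearity in the inoculum before rounding
  fr <- sector_areas(geo)[c("LUMEN", "OUTER_MUCUS", "INNER_MUCUS")]
  vol <- (179 * 24 * 0.00025^2)^1.5
  for (k in c(0.5, 2, 10)) {
    geok <- build_arena(arena_config(inoculum_cfu = 2e7 * k))
    expect_identical(seed_counts(geok),
                     stats::setNames(as.integer(round(fr * vol * 2e7 * k)),
                                     names(fr)))
  }
  # counts exceeding sector capacity raise a seeding error
  tiny <- build_arena(arena_config(n_rows = 40, n_cols = 10,
                                   mucus_total_rows = 12,
                                   crypt_depth_rows = 6,
                                   tissue_rows = 14, host_capacity = 16,
                                   inoculum_cfu = 1e18))
  expect_error(seed_counts(tiny), "exceed")
})

test_that("the default community abundance vector is a composition", {
  expect_equal(sum(sihumix_abundances), 1, tolerance = 1e-6)
  expect_identical(length(sihumix_abundances), 8L)
  expect_true(all(sihumix_abundances > 0))
})

test_that("largest-remainder apportionment matches a brute-force oracle", {
  lr_oracle <- function(total, ab) {
    q <- total * ab
    base <- floor(q)
    need <- total - sum(base)
    ord <- order(q - base, decreasing = TRUE)
    add <- rep(0L, length(ab))
    if (need > 0) add[ord[seq_len(need)]] <- 1L
    as.integer(base + add)
  }
  for (total in c(9L, 18L, 29L, 56L))
    expect_identical(unname(colonsim:::.apportion(total,
                                                  sihumix_abundances)),
                     lr_oracle(total, sihumix_abundances))
  # counts always sum exactly to the sector totals
  for (total in 1:40)
    expect_identical(sum(colonsim:::.apportion(total,
                                               sihumix_abundances)),
                     total)
})

test_that("placement is deterministic, sector-true and species-exact", {
  w <- sim_world(n_fermenters = 6L)   # 8 bacterial species
  geo <- build_arena(w$geoc)
  counts <- c(LUMEN = 20L, OUTER_MUCUS = 12L, INNER_MUCUS = 6L)
  set.seed(4)
  ags <- place_agents(counts, w$ab, geo, w$mods)
  bact <- Filter(function(a) a$kind == "bacterium", ags)
  hosts <- Filter(function(a) a$kind == "host", ags)
  expect_identical(length(bact), 38L)
  expect_identical(length(hosts), 16L)
  secs <- table(vapply(bact, function(a)
    geo$sector_map[a$row, a$col], ""))
  expect_identical(as.integer(secs[names(counts)]), unname(counts))
  # per-sector species counts equal the apportionment oracle
  for (sec in names(counts)) {
    got <- table(factor(vapply(Filter(function(a)
      geo$sector_map[a$row, a$col] == sec, bact),
      `[[`, "", "species_id"), levels = names(w$ab)))
    expect_identical(as.integer(got),
                     unname(colonsim:::.apportion(counts[[sec]], w$ab)))
  }
  # host agents sit on every host slot; same seed => same placement
  expect_identical(t(vapply(hosts, function(a) c(a$row, a$col),
                            integer(2))),
                   unname(cbind(geo$host_slots[, "row"],
                                geo$host_slots[, "col"])))
  set.seed(4)
  ags2 <- place_agents(counts, w$ab, geo, w$mods)
  expect_identical(ags, ags2)
  # single species: everyone is that species
  set.seed(4)
  solo <- place_agents(counts, c(ToyMucivorans = 1), geo,
                       w$mods["ToyMucivorans"])
  expect_true(all(vapply(solo, `[[`, "", "species_id") ==
                    "ToyMucivorans"))
})

test_that("the two-phase schedule produces the stated record structure", {
  w <- sim_world()
  geo <- build_arena(w$geoc)
  med <- toy_medium(geo)
  cfg <- simulation_config(w$mods, w$ab, med, w$geoc, n_iterations = 4,
                           n_replicates = 2, seed = 3,
                           seed_override = c(LUMEN = 8L, OUTER_MUCUS = 4L,
                                             INNER_MUCUS = 2L))
  res <- run_simulation(cfg)
  expect_identical(length(res), 2L)
  r <- res[[1]]
  # occupancy: never two agents on one grid cell, at any time
  for (tt in unique(r$agent_snapshots$time)) {
    s <- r$agent_snapshots[r$agent_snapshots$time == tt, ]
    expect_false(any(duplicated(s[c("row", "col")])))
  }
  # diffusion-only first iteration: no metabolic records at time 1
  expect_false(1L %in% r$flux_records$time)
  expect_setequal(unique(r$flux_records$time), 2:4)
  # surviving lineages log one growth observation per metabolic phase:
  # host agents never die, so each host id appears at times 2..n
  hosts <- unique(r$flux_records$agent_id[r$flux_records$kind == "host"])
  for (h in hosts[1:3]) {
    tt <- sort(unique(r$flux_records$time[r$flux_records$agent_id == h]))
    expect_identical(tt, 2:4)
  }
  # n_iterations = 1: fields diffused once, no metabolic steps at all
  cfg1 <- simulation_config(w$mods, w$ab, med, w$geoc, n_iterations = 1,
                            n_replicates = 1, seed = 3,
                            seed_override = c(LUMEN = 4L,
                                              OUTER_MUCUS = 2L,
                                              INNER_MUCUS = 1L))
  r1 <- run_simulation(cfg1)[[1]]
  expect_null(r1$flux_records)
  expect_identical(nrow(r1$field_totals), length(r1$fields))
})

test_that("identical config and seed give bit-identical replicates", {
  w <- sim_world()
  med <- toy_medium(build_arena(w$geoc))
  cfg <- simulation_config(w$mods, w$ab, med, w$geoc, n_iterations = 3,
                           n_replicates = 1, seed = 11,
                           seed_override = c(LUMEN = 6L, OUTER_MUCUS = 3L,
                                             INNER_MUCUS = 2L))
  r1 <- run_simulation(cfg)[[1]]
  r2 <- run_simulation(cfg)[[1]]
  expect_identical(r1$flux_records, r2$flux_records)
  expect_identical(r1$agent_snapshots, r2$agent_snapshots)
  # a different seed moves at least the placements
  cfg2 <- cfg; cfg2$seed <- 12L
  r3 <- run_simulation(cfg2)[[1]]
  expect_false(identical(r1$agent_snapshots, r3$agent_snapshots))
})

test_that("startup fails loudly when a model cannot grow on the medium", {
  w <- sim_world()
  geo <- build_arena(w$geoc)
  med <- toy_medium(geo, mucus_only = TRUE)
  cfg <- simulation_config(w$mods["ToyButyrivibrio"],
                           c(ToyButyrivibrio = 1), med, w$geoc,
                           n_iterations = 2, n_replicates = 1)
  expect_error(run_simulation(cfg), "ToyButyrivibrio")
})

test_that("dietary compounds are invisible to the host at every step", {
  w <- sim_world()
  geo <- build_arena(w$geoc)
  med <- toy_medium(geo)
  # remove blood glucose: the only glucose left is dietary
  med <- med[!(med$compound_id == "glc" & med$class == "blood"), ]
  cfg <- simulation_config(w$mods, w$ab, med, w$geoc, n_iterations = 4,
                           n_replicates = 1, seed = 5,
                           seed_override = c(LUMEN = 8L, OUTER_MUCUS = 4L,
                                             INNER_MUCUS = 2L),
                           require_growth_at_start = FALSE)
  r <- run_simulation(cfg)[[1]]
  glc_host <- r$flux_records[r$flux_records$kind == "host" &
                               !is.na(r$flux_records$compound) &
                               r$flux_records$compound == "glc", ]
  expect_identical(nrow(glc_host), 0L)
  # and a compound present only in blood is consumed via u, never via e
  r2 <- run_simulation(simulation_config(
    w$mods, w$ab, toy_medium(geo), w$geoc, n_iterations = 3,
    n_replicates = 1, seed = 5,
    seed_override = c(LUMEN = 8L, OUTER_MUCUS = 4L,
                      INNER_MUCUS = 2L)))[[1]]
  glc2 <- r2$flux_records[!is.na(r2$flux_records$compound) &
                            r2$flux_records$compound == "glc", ]
  expect_true(all(glc2$facing[glc2$kind == "host"] == "u"))
  expect_true(all(glc2$facing[glc2$kind == "bacterium"] == "d"))
})
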