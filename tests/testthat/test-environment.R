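test_that("power-law fitting recovers exact and noisy coefficients", {
  mw <- c(18, 60, 180, 342, 1000)
  co <- fit_power_law(mw, 2 * mw^-0.5)
  expect_equal(unname(co[["a"]]), 2, tolerance = 1e-10)
  expect_equal(unname(co[["b"]]), -0.5, tolerance = 1e-10)
  # two points: exact interpolation
  co2 <- fit_power_law(c(10, 1000), c(5e-6, 5e-8))
  expect_equal(unname(co2[["a"]] * 10^co2[["b"]]), 5e-6, tolerance = 1e-12)
  expect_equal(unname(co2[["a"]] * 1000^co2[["b"]]), 5e-8,
               tolerance = 1e-12)
  # noisy fit matches the normal-equation oracle on the log scale
  set.seed(2)
  d <- 3e-6 * mw^-0.4 * exp(rnorm(5, 0, 0.05))
  co3 <- fit_power_law(mw, d)
  X <- cbind(1, log(mw))
  beta <- solve(t(X) %*% X, t(X) %*% log(d))
  expect_equal(unname(co3[["a"]]), exp(beta[1]), tolerance = 1e-9)
  expect_equal(unname(co3[["b"]]), beta[2], tolerance = 1e-9)
  expect_error(fit_power_law(c(1, -2), c(1, 1)), "positive")
})

test_that("sector-wise diffusion rules hold for every compound class", {
  spec <- diffusion_spec()
  lum <- compound_field("x", matrix(0, 2, 2), "luminal",
                        molecular_weight = 180)
  muc <- compound_field("m", matrix(0, 2, 2), "mucus",
                        molecular_weight = 309)
  blo <- compound_field("b", matrix(0, 2, 2), "blood",
                        molecular_weight = 180)
  oxy <- compound_field("o", matrix(0, 2, 2), "oxygen",
                        molecular_weight = 32)
  # outer/inner mucus ratio is exactly (2/3)/(1/3) = 2
  expect_equal(diffusion_coefficient(lum, "OUTER_MUCUS", spec) /
                 diffusion_coefficient(lum, "INNER_MUCUS", spec), 2)
  # mucus compounds never diffuse
  for (s in colonsim:::SECTORS)
    expect_identical(diffusion_coefficient(muc, s, spec), 0)
  # luminal compounds stop at the intermediate layer and host space
  expect_identical(diffusion_coefficient(lum, "INTERMEDIATE", spec), 0)
  expect_identical(diffusion_coefficient(lum, "HOST", spec), 0)
  expect_gt(diffusion_coefficient(lum, "LUMEN", spec), 0)
  # blood molecules move only in the host area; oxygen likewise
  for (f in list(blo, oxy)) {
    expect_gt(diffusion_coefficient(f, "HOST", spec), 0)
    expect_gt(diffusion_coefficient(f, "INTERMEDIATE", spec), 0)
    for (s in c("LUMEN", "OUTER_MUCUS", "INNER_MUCUS"))
      expect_identical(diffusion_coefficient(f, s, spec), 0)
  }
  # lumen is faster than either mucus layer
  expect_gt(diffusion_coefficient(lum, "LUMEN", spec),
            diffusion_coefficient(lum, "OUTER_MUCUS", spec))
})

test_that("diffusion conserves mass, flattens fields, kills variance", {
  geo <- tiny_arena(20, 10, mucus = 0)
  spec <- diffusion_spec()
  # uniform field is a fixed point
  f <- compound_field("x", matrix(2.5e-11, 20, 10), "luminal", 180)
  f2 <- diffuse(f, geo, spec, dt = 1)
  expect_equal(f2$amounts, f$amounts, tolerance = 1e-12)
  # point mass: conservation every step, monotone variance, uniformity
  A <- matrix(0, 20, 10); A[10, 5] <- 1e-9
  f <- compound_field("x", A, "luminal", 180)
  tot0 <- sum(f$amounts)
  v_prev <- var(as.vector(f$amounts))
  for (k in 1:5) {
    f <- diffuse(f, geo, spec, dt = 0.2)
    expect_equal(sum(f$amounts), tot0, tolerance = 1e-9 * tot0)
    v <- var(as.vector(f$amounts))
    expect_lte(v, v_prev + 1e-30)
    v_prev <- v
  }
  f <- diffuse(f, geo, spec, dt = 50)
  expect_equal(max(abs(f$amounts - tot0 / 200)), 0,
               tolerance = 1e-3 * tot0 / 200)
})

test_that("1D spreading matches the analytic heat kernel within 2%", {
  n <- 151L
  geo <- build_arena(arena_config(n_rows = n, n_cols = 1,
                                  mucus_total_rows = 0,
                                  crypt_depth_rows = 0, tissue_rows = 0,
                                  host_capacity = 0))
  spec <- diffusion_spec()
  h <- geo$config$cell_edge
  A <- matrix(0, n, 1); A[(n + 1) / 2, 1] <- 1
  f <- compound_field("x", A, "luminal", 180)
  D <- diffusion_coefficient(f, "LUMEN", spec)
  t_h <- 0.05                        # hours; sigma ~ 7 cells, no edges
  f <- diffuse(f, geo, spec, dt = t_h)
  x <- (seq_len(n) - (n + 1) / 2) * h
  s2 <- 2 * D * t_h * 3600
  exact <- (pnorm((x + h / 2) / sqrt(s2)) - pnorm((x - h / 2) / sqrt(s2)))
  expect_lt(max(abs(f$amounts[, 1] - exact)) / max(exact), 0.02)
})

test_that("blood boundary resets host cells and feeds the tissue only", {
  geo <- build_arena(arena_config())
  spec <- diffusion_spec()
  med <- data.frame(compound_id = "glc", class = "blood",
                    amount_mmol = 7e-8, molecular_weight = 180.16)
  f <- load_medium(med, geo, spec)[["glc.blood"]]
  lvl <- f$blood_level
  f <- diffuse(f, geo, spec, dt = 1)
  f <- apply_blood_boundary(f, geo)
  expect_true(all(f$amounts[geo$sector_map == "HOST"] == lvl))
  out <- !geo$sector_map %in% c("HOST", "INTERMEDIATE")
  expect_true(all(f$amounts[out] == 0))
  # luminal fields are untouched by the boundary
  g <- compound_field("y", matrix(1e-11, 179, 24), "luminal", 180)
  expect_identical(apply_blood_boundary(g, geo)$amounts, g$amounts)
})

test_that("oxygen containment: nothing ever leaks out of the host area", {
  geo <- build_arena(arena_config())
  spec <- diffusion_spec()
  med <- data.frame(compound_id = "o2", class = "oxygen",
                    amount_mmol = 7e-8, molecular_weight = 32)
  f <- load_medium(med, geo, spec)[["o2.oxygen"]]
  out <- !geo$sector_map %in% c("HOST", "INTERMEDIATE")
  for (k in 1:3) {
    f <- diffuse(f, geo, spec, dt = 1)
    expect_true(all(f$amounts[out] == 0))
  }
})

test_that("lumen advection conserves (wrap) and replaces (inflow)", {
  geo <- tiny_arena(12, 6, mucus = 4)
  spec <- diffusion_spec()
  med <- data.frame(compound_id = c("glc", "nana"),
                    class = c("luminal", "mucus"),
                    amount_mmol = c(1e-9, 2e-9),
                    molecular_weight = c(180, 309))
  fields <- load_medium(med, geo, spec)
  fields[["glc.luminal"]]$amounts[1, 2] <- fields[["glc.luminal"]]$amounts[1, 2] * 3  # asymmetry
  # shift 0: identity
  a0 <- advect_lumen(fields, list(), geo, 0L, "wrap")
  expect_identical(a0$fields[["glc.luminal"]]$amounts, fields[["glc.luminal"]]$amounts)
  # wrap conserves exactly and leaves mucus rows alone
  aw <- advect_lumen(fields, list(), geo, 2L, "wrap")
  expect_identical(sum(aw$fields[["glc.luminal"]]$amounts), sum(fields[["glc.luminal"]]$amounts))
  expect_identical(aw$fields[["nana.mucus"]]$amounts, fields[["nana.mucus"]]$amounts)
  # full-turnover inflow: lumen back to fresh medium everywhere
  ai <- advect_lumen(fields, list(), geo, 6L, "inflow")
  lum <- geo$sector_map == "LUMEN"
  expect_true(all(abs(ai$fields[["glc.luminal"]]$amounts[lum] -
                        fields[["glc.luminal"]]$lumen_fresh) < 1e-20))
  # lumen agents ride along under wrap
  ag <- list(new_agent(1, "sp", "bacterium", 1, 5))
  aw2 <- advect_lumen(fields, ag, geo, 2L, "wrap")
  expect_identical(aw2$agents[[1]]$col, 1L)   # (5 - 1 + 2) %% 6 + 1
})

test_that("medium loading distributes amounts per the layer rules", {
  geo <- build_arena(arena_config())
  spec <- diffusion_spec()
  med <- toy_medium(geo)
  fields <- load_medium(med, geo, spec, diet_compounds = "glc")
  # totals conserved, per compound-and-class pool
  for (i in seq_len(nrow(med))) {
    f <- fields[[paste(med$compound_id[i], med$class[i], sep = ".")]]
    expect_equal(sum(f$amounts), med$amount_mmol[i],
                 tolerance = 1e-12 * med$amount_mmol[i])
  }
  # inner mucus cells hold 4x the outer per-cell amount
  nana <- fields[["nana.mucus"]]
  inner <- nana$amounts[geo$sector_map == "INNER_MUCUS"]
  outer <- nana$amounts[geo$sector_map == "OUTER_MUCUS"]
  expect_equal(unique(inner) / unique(outer), 4, tolerance = 1e-12)
  # diet flag is applied, and the two glucose pools stay separate
  expect_true(fields[["glc.luminal"]]$diet)
  expect_false(fields[["nana.mucus"]]$diet)
  expect_false(fields[["glc.blood"]]$diet)
  # empty medium: no fields
  expect_identical(length(load_medium(med[0, ], geo, spec)), 0L)
})
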