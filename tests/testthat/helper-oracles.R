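# Independent oracles used across the suite. The LP oracle enumerates
# basic solutions of {A v = b, lb <= v <= ub} directly (each vertex has
# n - m variables pinned at a bound), entirely bypassing the package's
# simplex path.

oracle_lp_max <- function(cc, A, b, lb, ub) {
  A_full <- as.matrix(A); b_full <- b
  ## drop linearly dependent rows (candidates re-checked on the full
  ## system below)
  qrt <- qr(t(A_full))
  keep <- sort(qrt$pivot[seq_len(qrt$rank)])
  A <- A_full[keep, , drop = FALSE]; b <- b_full[keep]
  n <- ncol(A); m <- nrow(A)
  best <- -Inf; best_v <- NULL
  nb_sets <- utils::combn(n, n - m)
  for (ci in seq_len(ncol(nb_sets))) {
    fix <- nb_sets[, ci]
    free <- setdiff(seq_len(n), fix)
    pats <- as.matrix(expand.grid(rep(list(c(0, 1)), length(fix))))
    for (pi in seq_len(nrow(pats))) {
      v <- numeric(n)
      v[fix] <- ifelse(pats[pi, ] == 1, ub[fix], lb[fix])
      if (any(!is.finite(v[fix]))) next
      Af <- A[, free, drop = FALSE]
      if (nrow(Af) != length(free)) next
      if (abs(det(Af)) < 1e-10) next
      v[free] <- solve(Af, b - A[, fix, drop = FALSE] %*% v[fix])
      if (all(v >= lb - 1e-8 & v <= ub + 1e-8) &&
          all(abs(A_full %*% v - b_full) < 1e-7)) {
        val <- sum(cc * v)
        if (val > best) { best <- val; best_v <- v }
      }
    }
  }
  list(objective = best, v = best_v)
}

# minimal sum(|v|) over the optimal face {A v = 0, c'v = mu, bounds},
# again by direct enumeration on the lifted split problem (negative
# parts only for reversible reactions, which keeps the enumeration
# tractable and is exact: |v| = v whenever lb >= 0)
oracle_min_abs_flux <- function(model, mu) {
  S <- model$S; n <- ncol(S)
  lb <- model$rxns$lb; ub <- model$rxns$ub
  cc <- as.numeric(model$rxns$objective)
  rev <- which(lb < 0)
  A <- rbind(cbind(S, -S[, rev, drop = FALSE]), c(cc, -cc[rev]))
  b <- c(rep(0, nrow(S)), mu)
  r <- oracle_lp_max(-rep(1, n + length(rev)), A, b,
                     c(pmax(0, lb), pmax(0, -ub[rev])),
                     c(pmax(0, ub), -lb[rev]))
  -r$objective
}

# build a fake simulation_result from a long data.frame of flux records
fake_result <- function(records, replicate = 1L) {
  cols <- c("agent_id", "species", "kind", "row", "col", "sector",
            "compound", "facing", "flux", "mass_flux", "time",
            "growth_rate")
  for (nm in setdiff(cols, names(records))) {
    records[[nm]] <- switch(nm,
                            agent_id = seq_len(nrow(records)),
                            kind = "bacterium", row = 1L, col = 1L,
                            sector = "LUMEN", facing = "e",
                            mass_flux = records$flux * 1e-12,
                            time = 2L, growth_rate = 0.1)
  }
  structure(list(replicate = replicate, flux_records = records[cols],
                 agent_snapshots = NULL, field_totals = NULL,
                 fields = NULL, agents = NULL, seeds = replicate,
                 dt = 1),
            class = "simulation_result")
}

tiny_arena <- function(n_rows = 20L, n_cols = 8L, mucus = 6L,
                       tissue = 0L, capacity = 0L, crypt = 0L) {
  build_arena(arena_config(n_rows = n_rows, n_cols = n_cols,
                           mucus_total_rows = mucus,
                           crypt_depth_rows = crypt,
                           tissue_rows = tissue,
                           host_capacity = capacity))
}
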