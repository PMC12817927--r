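## Downstream analytics of recorded exchange fluxes: who produces what,
## who consumes it, where, and how consistently across replicates.

.records_of <- function(results) {
  if (inherits(results, "simulation_result")) results <- list(results)
  recs <- lapply(results, function(r) {
    if (is.null(r$flux_records)) return(NULL)
    fr <- r$flux_records
    fr$replicate <- r$replicate
    fr
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no flux records in the supplied results")
  out
}

#' Net-flux summary per model, compound and layer of origin
#'
#' For each replicate, species and compound, sums all exchange fluxes
#' across time (optionally split by the sector the agent occupied when
#' the flux occurred). A positive sum denotes production, a negative
#' one consumption; to limit numerical artifacts, absolute sums below
#' `epsilon` are classified as zero. The mass-weighted sum
#' (`net_mass`, mmol) is carried alongside the plain flux sum for
#' conservation checks.
#'
#' @param results a `simulation_result` or list of them.
#' @param epsilon zero threshold on the summed flux (default 1e-6).
#' @param by_sector if `TRUE` (default), keep the layer of origin as a
#'   grouping column.
#' @return data.frame `(replicate, species, kind[, sector], compound,
#'   net_flux, net_mass, direction)` with
#'   `direction in c("production", "consumption", "zero")`.
#' @export
net_flux_summary <- function(results, epsilon = 1e-6, by_sector = TRUE) {
  fr <- .records_of(results)
  fr <- fr[!is.na(fr$compound), , drop = FALSE]
  keys <- c("replicate", "species", "kind",
            if (by_sector) "sector", "compound")
  agg <- stats::aggregate(fr[c("flux", "mass_flux")], fr[keys], sum)
  names(agg)[names(agg) == "flux"] <- "net_flux"
  names(agg)[names(agg) == "mass_flux"] <- "net_mass"
  agg$direction <- ifelse(agg$net_flux > epsilon, "production",
                          ifelse(agg$net_flux < -epsilon, "consumption",
                                 "zero"))
  agg[do.call(order, agg[keys]), , drop = FALSE]
}

#' Producer-to-consumer interaction table
#'
#' For each compound, pairs every producing model with every consuming
#' model, keeping host-to-bacteria, bacteria-to-host and
#' bacteria-to-bacteria pairs. With `per_time = TRUE` (default) the
#' classification is done per replicate and time point, which is the
#' unit the interaction-frequency filter counts over; with `FALSE` it
#' is done on the whole-run net flux.
#'
#' @param results a `simulation_result` or list of them.
#' @param epsilon zero threshold per classification unit.
#' @param per_time classify per (replicate, time point) instead of the
#'   whole run.
#' @return data.frame `(replicate[, time], compound, producer,
#'   producer_kind, consumer, consumer_kind, pair_kind)`.
#' @export
interaction_table <- function(results, epsilon = 1e-6, per_time = TRUE) {
  fr <- .records_of(results)
  fr <- fr[!is.na(fr$compound), , drop = FALSE]
  keys <- c("replicate", if (per_time) "time", "species", "kind",
            "compound")
  agg <- stats::aggregate(fr["flux"], fr[keys], sum)
  agg$direction <- ifelse(agg$flux > epsilon, "production",
                          ifelse(agg$flux < -epsilon, "consumption",
                                 "zero"))
  ukeys <- c("replicate", if (per_time) "time", "compound")
  units <- unique(agg[ukeys])
  out <- NULL
  for (i in seq_len(nrow(units))) {
    sel <- rep(TRUE, nrow(agg))
    for (k in ukeys) sel <- sel & agg[[k]] == units[[k]][i]
    prod <- agg[sel & agg$direction == "production", , drop = FALSE]
    cons <- agg[sel & agg$direction == "consumption", , drop = FALSE]
    if (nrow(prod) == 0L || nrow(cons) == 0L) next
    grid <- expand.grid(p = seq_len(nrow(prod)), q = seq_len(nrow(cons)))
    rows <- data.frame(
      units[i, , drop = FALSE][rep(1L, nrow(grid)), , drop = FALSE],
      producer = prod$species[grid$p],
      producer_kind = prod$kind[grid$p],
      consumer = cons$species[grid$q],
      consumer_kind = cons$kind[grid$q],
      row.names = NULL)
    out <- rbind(out, rows)
  }
  if (is.null(out))
    return(data.frame(replicate = integer(0), time = integer(0),
                      compound = character(0), producer = character(0),
                      producer_kind = character(0),
                      consumer = character(0),
                      consumer_kind = character(0),
                      pair_kind = character(0))[
                        , c("replicate", if (per_time) "time", "compound",
                            "producer", "producer_kind", "consumer",
                            "consumer_kind", "pair_kind")])
  out <- out[out$producer != out$consumer, , drop = FALSE]
  out$pair_kind <- paste0(out$producer_kind, "->", out$consumer_kind)
  out <- out[out$pair_kind %in% c("host->bacterium", "bacterium->host",
                                  "bacterium->bacterium"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter interactions by occurrence frequency
#'
#' Keeps a (compound, producer, consumer) pair if it occurs in at least
#' `threshold` of the observation units. The denominator is, by
#' default, every (replicate, time point) unit present in the table
#' (pass `n_units` to fix it explicitly, e.g. replicates x metabolic
#' steps of the full design); with `units = "replicate"` a pair counts
#' once per replicate regardless of time.
#'
#' @param pairs an [interaction_table()] result (with `per_time = TRUE`
#'   for the default unit definition).
#' @param threshold minimum occurrence fraction, default 0.5.
#' @param units `"replicate_time"` or `"replicate"`.
#' @param n_units optional denominator override.
#' @return the filtered pair table with an `frequency` column,
#'   one row per kept pair.
#' @export
frequency_filter <- function(pairs, threshold = 0.5,
                             units = c("replicate_time", "replicate"),
                             n_units = NULL) {
  units <- match.arg(units)
  if (nrow(pairs) == 0L) return(cbind(pairs, frequency = numeric(0)))
  if (units == "replicate_time" && !"time" %in% names(pairs))
    stop("frequency_filter: pairs table has no time column; build it ",
         "with interaction_table(per_time = TRUE)")
  ucols <- if (units == "replicate_time") c("replicate", "time")
           else "replicate"
  if (is.null(n_units))
    n_units <- nrow(unique(pairs[ucols]))
  key <- interaction(pairs$compound, pairs$producer, pairs$consumer,
                     drop = TRUE)
  ukey <- do.call(paste, pairs[ucols])
  occ <- tapply(ukey, key, function(u) length(unique(u)))
  freq <- occ / n_units
  keep <- names(freq)[freq >= threshold]
  sel <- key %in% keep
  out <- unique(pairs[sel, setdiff(names(pairs), c("replicate", "time")),
                      drop = FALSE])
  out$frequency <- as.numeric(freq[match(
    interaction(out$compound, out$producer, out$consumer, drop = FALSE),
    names(freq))])
  rownames(out) <- NULL
  out
}

#' Growth-rate distributions by species and layer
#'
#' Collects the per-agent-step growth rates (the pFBA objective, 1/h)
#' grouped by species and the sector the agent occupied at that step.
#'
#' @param results a `simulation_result` or list of them.
#' @return data.frame `(species, sector, n, mean, median, sd)` plus the
#'   raw observations as attribute `"observations"`.
#' @export
growth_rates_by_layer <- function(results) {
  fr <- .records_of(results)
  obs <- unique(fr[c("replicate", "time", "agent_id", "species", "kind",
                     "sector", "growth_rate")])
  agg <- stats::aggregate(obs["growth_rate"],
                          obs[c("species", "sector")],
                          function(x) c(n = length(x), mean = mean(x),
                                        median = stats::median(x),
                                        sd = stats::sd(x)))
  out <- data.frame(agg[c("species", "sector")],
                    n = agg$growth_rate[, "n"],
                    mean = agg$growth_rate[, "mean"],
                    median = agg$growth_rate[, "median"],
                    sd = agg$growth_rate[, "sd"])
  attr(out, "observations") <- obs
  out
}

#' Compare the exchanged-compound sets of two settings
#'
#' Computes, for each setting, the set of compounds exchanged between
#' bacterial and host models (produced by one kind and consumed by the
#' other in the net-flux summary), optionally restricted to bacterial
#' species whose genus is in `genus_filter`, and returns the set
#' difference and intersection.
#'
#' @param summary_a,summary_b [net_flux_summary()] results of the two
#'   settings (e.g. mono-colonization vs community).
#' @param genus_filter optional character vector of genera; a species'
#'   genus is taken as the part of its id before the first `_`.
#' @return list `unique_a`, `shared`, `unique_b` (character vectors).
#' @export
compare_settings <- function(summary_a, summary_b, genus_filter = NULL) {
  xset <- function(s) {
    if (!is.null(genus_filter)) {
      genus <- sub("_.*$", "", s$species)
      s <- s[s$kind == "host" | genus %in% genus_filter, , drop = FALSE]
    }
    prod_b <- unique(s$compound[s$kind == "bacterium" &
                                  s$direction == "production"])
    cons_b <- unique(s$compound[s$kind == "bacterium" &
                                  s$direction == "consumption"])
    prod_h <- unique(s$compound[s$kind == "host" &
                                  s$direction == "production"])
    cons_h <- unique(s$compound[s$kind == "host" &
                                  s$direction == "consumption"])
    union(intersect(prod_b, cons_h), intersect(prod_h, cons_b))
  }
  a <- xset(summary_a); b <- xset(summary_b)
  list(unique_a = setdiff(a, b), shared = intersect(a, b),
       unique_b = setdiff(b, a))
}
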