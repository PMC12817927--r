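## Bounds of +-Inf are clamped to this magnitude for the simplex core;
## fixture models use |bound| <= 1000 so the clamp is never active there.
.BIG_BOUND <- 1e6

.model_lp_parts <- function(model, bound_overrides = NULL) {
  model <- .apply_bound_overrides(model, bound_overrides)
  lb <- pmax(model$rxns$lb, -.BIG_BOUND)
  ub <- pmin(model$rxns$ub, .BIG_BOUND)
  obj <- as.numeric(model$rxns$objective)
  list(model = model, S = model$S, lb = lb, ub = ub, obj = obj)
}

#' Flux balance analysis
#'
#' Maximizes the model's objective flux subject to steady-state mass
#' balance `S v = 0` and the reaction bounds. Infeasibility or
#' unboundedness is reported in `status`, never as silent zeros.
#'
#' @param model a [metabolic_model()].
#' @param bound_overrides optional named list of per-reaction bounds:
#'   each element either a single lower bound or `c(lb, ub)`. Used by
#'   the agent layer to impose local nutrient availability.
#' @param duals if `TRUE`, also return metabolite shadow prices.
#' @return a `flux_solution` list: `objective_value`, `fluxes` (named),
#'   `status` (`"optimal"`, `"infeasible"` or `"unbounded"`) and
#'   optionally `duals` (named by metabolite).
#' @export
#' @examples
#' m <- toy_chain_model()
#' fba(m)$objective_value
fba <- function(model, bound_overrides = NULL, duals = FALSE) {
  p <- .model_lp_parts(model, bound_overrides)
  r <- lp_solve(p$obj, p$S, rep(0, nrow(p$S)), "=", p$lb, p$ub,
                sense = "max", duals = duals)
  sol <- list(objective_value = r$objective,
              fluxes = if (r$status == "optimal")
                stats::setNames(r$x, colnames(p$S)) else NULL,
              status = r$status)
  if (duals && r$status == "optimal")
    sol$duals <- stats::setNames(r$duals, rownames(p$S))
  class(sol) <- "flux_solution"
  sol
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the FBA optimum is computed, then total absolute
#' flux `sum(|v|)` is minimized with the objective flux pinned to that
#' optimum (equality constraint; the flux-splitting formulation
#' `v = p - n`, `p, n >= 0` makes `sum(p + n)` the L1 norm at the
#' optimum). The growth value is never degraded and redundant pathway
#' flux and internal loops are suppressed.
#'
#' @inheritParams fba
#' @return a `flux_solution`; `objective_value` equals the FBA optimum,
#'   `total_flux` holds the minimized `sum(|v|)`.
#' @export
pfba <- function(model, bound_overrides = NULL) {
  p <- .model_lp_parts(model, bound_overrides)
  stage1 <- lp_solve(p$obj, p$S, rep(0, nrow(p$S)), "=", p$lb, p$ub,
                     sense = "max")
  if (stage1$status != "optimal")
    return(structure(list(objective_value = stage1$objective,
                          fluxes = NULL, status = stage1$status),
                     class = "flux_solution"))
  mu <- stage1$objective
  n <- ncol(p$S)
  ## v = pos - neg, with a negative part only for reversible reactions
  rev <- which(p$lb < 0)
  nr <- length(rev)
  A <- rbind(cbind(p$S, -p$S[, rev, drop = FALSE]),
             c(p$obj, -p$obj[rev]))
  b <- c(rep(0, nrow(p$S)), mu)
  lb2 <- c(pmax(0, p$lb), pmax(0, -p$ub[rev]))
  ub2 <- c(pmax(0, p$ub), -p$lb[rev])
  r <- lp_solve(rep(1, n + nr), A, b, "=", lb2, ub2, sense = "min")
  if (r$status != "optimal")
    return(structure(list(objective_value = NA_real_, fluxes = NULL,
                          status = r$status), class = "flux_solution"))
  v <- r$x[seq_len(n)]
  v[rev] <- v[rev] - r$x[n + seq_len(nr)]
  structure(list(objective_value = mu,
                 fluxes = stats::setNames(v, colnames(p$S)),
                 status = "optimal",
                 total_flux = r$objective),
            class = "flux_solution")
}

#' Metabolite shadow prices at the FBA optimum
#'
#' Dual values of the metabolite mass-balance constraints. Sign
#' convention: the returned value is the change of the objective per
#' unit of *forced accumulation* of the metabolite, so a
#' growth-limiting nutrient carries a negative value (withdrawing one
#' unit costs that much growth) and a non-limiting metabolite carries
#' zero. This matches the convention used to infer essential blood
#' compounds for the host model.
#'
#' @inheritParams fba
#' @return named numeric vector, one dual per metabolite.
#' @export
shadow_costs <- function(model, bound_overrides = NULL) {
  sol <- fba(model, bound_overrides, duals = TRUE)
  if (sol$status != "optimal")
    stop("shadow_costs: FBA not optimal (status ", sol$status, ")")
  sol$duals
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (x$status == "optimal")
    cat(", objective =", format(x$objective_value, digits = 8))
  if (!is.null(x$total_flux))
    cat(", sum|v| =", format(x$total_flux, digits = 8))
  cat("\n")
  invisible(x)
}
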