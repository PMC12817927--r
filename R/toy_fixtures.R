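## Hand-sized single-model fixtures with closed-form optima. They back
## the documentation examples and the solver oracle tests.

#' Minimal linear-chain model
#'
#' `A_e -> A_c -> biomass` with uptake bound `-uptake` and biomass
#' yield `yield` per unit of substrate: the FBA optimum is
#' `uptake * yield` in closed form.
#'
#' @param uptake maximal substrate uptake rate (default 10).
#' @param yield biomass per substrate (default 1).
#' @return a [metabolic_model()].
#' @export
toy_chain_model <- function(uptake = 10, yield = 1) {
  mets <- data.frame(id = c("A_e", "A_c"), compartment = c("e", "c"),
                     carbon = c(1, 1))
  S <- matrix(c(-1, 0,
                -1, 1,
                0, -1 / yield),
              nrow = 2,
              dimnames = list(mets$id, c("EX_A_e", "T_A", "BIOMASS")))
  rxns <- data.frame(id = colnames(S),
                     lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
                     objective = c(FALSE, FALSE, TRUE))
  metabolic_model("toy_chain", mets, rxns, S,
                  exchanges = .detect_exchanges(S, mets))
}

#' Redundant parallel-pathway model
#'
#' Substrate can reach biomass through a 1-reaction route or an
#' equivalent 2-reaction detour; FBA is degenerate between them and
#' parsimonious FBA must route all flux through the short path.
#'
#' @param uptake maximal substrate uptake rate.
#' @return a [metabolic_model()].
#' @export
toy_parallel_model <- function(uptake = 10) {
  mets <- data.frame(id = c("S_e", "S_c", "X_c", "B_c"),
                     compartment = c("e", "c", "c", "c"),
                     carbon = c(1, 1, 1, 1))
  rxn_ids <- c("EX_S_e", "T_S", "SHORT", "LONG1", "LONG2", "BIOMASS")
  S <- matrix(0, 4, 6, dimnames = list(mets$id, rxn_ids))
  S["S_e", "EX_S_e"] <- -1
  S["S_e", "T_S"] <- -1; S["S_c", "T_S"] <- 1
  S["S_c", "SHORT"] <- -1; S["B_c", "SHORT"] <- 1
  S["S_c", "LONG1"] <- -1; S["X_c", "LONG1"] <- 1
  S["X_c", "LONG2"] <- -1; S["B_c", "LONG2"] <- 1
  S["B_c", "BIOMASS"] <- -1
  rxns <- data.frame(id = rxn_ids, lb = c(-uptake, rep(0, 5)),
                     ub = rep(1000, 6),
                     objective = c(rep(FALSE, 5), TRUE))
  metabolic_model("toy_parallel", mets, rxns, S,
                  exchanges = .detect_exchanges(S, mets))
}

#' Chain model with a thermodynamically infeasible internal loop
#'
#' Adds a reversible two-reaction cycle `C_c <-> D_c` that can carry
#' arbitrary flux without affecting growth; parsimonious FBA must leave
#' it at zero.
#'
#' @param uptake maximal substrate uptake rate.
#' @return a [metabolic_model()].
#' @export
toy_loop_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_e", "A_c", "C_c", "D_c"),
                     compartment = c("e", "c", "c", "c"),
                     carbon = c(1, 1, 1, 1))
  rxn_ids <- c("EX_A_e", "T_A", "BIOMASS", "LOOP_F", "LOOP_R")
  S <- matrix(0, 4, 5, dimnames = list(mets$id, rxn_ids))
  S["A_e", "EX_A_e"] <- -1
  S["A_e", "T_A"] <- -1; S["A_c", "T_A"] <- 1
  S["A_c", "BIOMASS"] <- -1
  S["C_c", "LOOP_F"] <- -1; S["D_c", "LOOP_F"] <- 1
  S["D_c", "LOOP_R"] <- -1; S["C_c", "LOOP_R"] <- 1
  rxns <- data.frame(id = rxn_ids,
                     lb = c(-uptake, 0, 0, -1000, -1000),
                     ub = rep(1000, 5),
                     objective = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  metabolic_model("toy_loop", mets, rxns, S,
                  exchanges = .detect_exchanges(S, mets))
}
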