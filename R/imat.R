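## --- GPR boolean expression handling -------------------------------
## Grammar: expr := term ('or' term)*, term := factor ('and' factor)*,
## factor := gene | '(' expr ')'. Case-insensitive operators.

.tokenize_gpr <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[toks != ""]
}

.parse_gpr <- function(s) {
  toks <- .tokenize_gpr(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("GPR parse error: unexpected end in '", s, "'")
    if (t == "(") {
      e <- parse_expr()
      if (is.na(peek()) || take() != ")")
        stop("GPR parse error: missing ')' in '", s, "'")
      return(e)
    }
    if (t %in% c(")", "and", "or"))
      stop("GPR parse error: unexpected '", t, "' in '", s, "'")
    t
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing tokens in '", s, "'")
  out
}

.gpr_genes <- function(s) {
  toks <- .tokenize_gpr(s)
  toks[!tolower(toks) %in% c("and", "or", "(", ")")]
}

## AND = min, OR = max over gene expression values; NA for genes
## without measurements propagates through min/max with na.rm = FALSE
.eval_gpr <- function(tree, values) {
  if (is.character(tree)) {
    v <- values[tree]
    return(if (is.null(v) || length(v) == 0L) NA_real_ else unname(v))
  }
  kids <- vapply(tree$args, .eval_gpr, numeric(1), values = values)
  if (tree$op == "and") min(kids) else max(kids)
}

#' Map gene expression onto reactions and classify by quartiles
#'
#' Gene expression is translated to reaction expression through the
#' gene-protein-reaction rules (AND = min, OR = max). Reactions at or
#' below the first quartile of all reaction-expression values are the
#' lowly expressed set; reactions at or above the third quartile are the
#' highly expressed set (inclusive at the quartile itself). Reactions
#' without a GPR or without measured genes stay unclassified.
#'
#' @param gene_expression named numeric vector of expression values, or
#'   a two-column data.frame `(gene_id, value)` as read from a TSV.
#' @param gpr_map named character vector of GPR rules (names = reaction
#'   ids); defaults to `model$gpr`.
#' @param model a [metabolic_model()].
#' @param forced_reactions reactions required to be active in the
#'   context-specific model regardless of expression.
#' @param open_nutrition exchange reaction ids whose uptake is left
#'   unconstrained during extraction.
#' @return an `expression_profile` list: `reaction_expression`, `q1`,
#'   `q3`, `low`, `high`, `forced_reactions`, `open_nutrition`.
#' @export
classify_reaction_expression <- function(gene_expression, gpr_map = NULL,
                                         model,
                                         forced_reactions = character(0),
                                         open_nutrition = character(0)) {
  if (is.data.frame(gene_expression))
    gene_expression <- stats::setNames(gene_expression[[2]],
                                       gene_expression[[1]])
  if (is.null(gpr_map)) gpr_map <- model$gpr
  bad <- setdiff(forced_reactions, model$rxns$id)
  if (length(bad) > 0L)
    stop("classify_reaction_expression: forced reaction(s) not in model: ",
         paste(bad, collapse = ", "))
  rex <- vapply(names(gpr_map), function(rid)
    .eval_gpr(.parse_gpr(gpr_map[[rid]]), gene_expression), numeric(1))
  rex <- rex[!is.na(rex)]
  if (length(rex) == 0L) {
    q1 <- q3 <- NA_real_
    low <- high <- character(0)
  } else {
    q1 <- unname(stats::quantile(rex, 0.25))
    q3 <- unname(stats::quantile(rex, 0.75))
    low <- names(rex)[rex <= q1]
    high <- names(rex)[rex >= q3]
  }
  structure(list(reaction_expression = rex, q1 = q1, q3 = q3,
                 low = low, high = high,
                 forced_reactions = forced_reactions,
                 open_nutrition = open_nutrition),
            class = "expression_profile")
}

#' iMAT-style context-specific model extraction
#'
#' Solves the integrative MILP: maximize the number of highly expressed
#' reactions carrying flux of magnitude at least `v_min` plus the number
#' of lowly expressed reactions carrying zero flux, subject to
#' steady-state mass balance. Forced reactions are required to be active
#' and `open_nutrition` exchanges get unconstrained uptake. The reduced
#' model drops the lowly expressed reactions that are switched off in
#' the MILP optimum; every exchange reaction, the ATP demand reaction
#' and all forced reactions are always retained.
#'
#' @param model a [metabolic_model()].
#' @param profile an [classify_reaction_expression()] result.
#' @param v_min activity threshold in mmol/gDW/h (default 1e-3).
#' @param atp_demand id of the ATP demand reaction kept in every
#'   context-specific model (default `"DM_atp_c"`; ignored if absent).
#' @return the reduced `metabolic_model`, with attribute
#'   `imat_objective` (the MILP optimum) attached.
#' @export
imat <- function(model, profile, v_min = 1e-3, atp_demand = "DM_atp_c") {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(profile, "expression_profile"))
  rids <- model$rxns$id
  high <- intersect(profile$high, rids)
  low <- intersect(profile$low, rids)
  lb <- pmax(model$rxns$lb, -.BIG_BOUND)
  ub <- pmin(model$rxns$ub, .BIG_BOUND)
  names(lb) <- names(ub) <- rids
  for (rid in profile$open_nutrition) {
    i <- match(rid, rids)
    if (!is.na(i)) lb[i] <- -1000
  }
  for (rid in profile$forced_reactions)
    lb[rid] <- max(lb[rid], v_min)

  n <- length(rids); nh <- length(high); nl <- length(low)
  nvar <- n + 2L * nh + nl   # v, y+ (high fwd), y- (high rev), z (low off)
  iv <- seq_len(n)
  iyp <- n + seq_len(nh)
  iym <- n + nh + seq_len(nh)
  iz <- n + 2L * nh + seq_len(nl)

  rows <- list(); rhs <- numeric(0); dirs <- character(0)
  addrow <- function(r, d, v) {
    rows[[length(rows) + 1L]] <<- r
    dirs[length(dirs) + 1L] <<- d
    rhs[length(rhs) + 1L] <<- v
  }
  for (i in seq_len(nrow(model$S))) {
    r <- numeric(nvar); r[iv] <- model$S[i, ]
    addrow(r, "=", 0)
  }
  for (k in seq_along(high)) {
    i <- match(high[k], rids)
    r <- numeric(nvar); r[i] <- 1; r[iyp[k]] <- -(v_min - lb[i])
    addrow(r, ">=", lb[i])                       # y+ = 1 -> v >= v_min
    r <- numeric(nvar); r[i] <- 1; r[iym[k]] <- v_min + ub[i]
    addrow(r, "<=", ub[i])                       # y- = 1 -> v <= -v_min
    r <- numeric(nvar); r[iyp[k]] <- 1; r[iym[k]] <- 1
    addrow(r, "<=", 1)
  }
  for (k in seq_along(low)) {
    i <- match(low[k], rids)
    r <- numeric(nvar); r[i] <- 1; r[iz[k]] <- lb[i]
    addrow(r, ">=", lb[i])                       # z = 1 -> v >= 0
    r <- numeric(nvar); r[i] <- 1; r[iz[k]] <- ub[i]
    addrow(r, "<=", ub[i])                       # z = 1 -> v <= 0
  }
  A <- do.call(rbind, rows)
  objv <- numeric(nvar); objv[c(iyp, iym, iz)] <- 1
  lbv <- c(lb, rep(0, 2L * nh + nl))
  ubv <- c(ub, rep(1, 2L * nh + nl))
  r <- milp_solve(objv, A, rhs, dirs, lbv, ubv, "max",
                  int_idx = c(iyp, iym, iz))
  if (r$status != "optimal")
    stop("imat: MILP infeasible; forced reactions were ",
         if (length(profile$forced_reactions) > 0L)
           paste(profile$forced_reactions, collapse = ", ") else "(none)")
  v <- r$x[iv]

  off_low <- low[abs(v[match(low, rids)]) <= 1e-9]
  keep_always <- unique(c(model$exchanges$rxn_id,
                          intersect(atp_demand, rids),
                          profile$forced_reactions,
                          objective_reaction(model)))
  drop <- setdiff(off_low, keep_always)
  keep <- setdiff(rids, drop)
  out <- .subset_reactions(model, keep)
  attr(out, "imat_objective") <- r$objective
  out
}

## keep a reaction subset plus the metabolites they touch
.subset_reactions <- function(model, keep_rxns) {
  jj <- match(keep_rxns, model$rxns$id)
  S <- model$S[, jj, drop = FALSE]
  used <- rowSums(S != 0) > 0
  S <- S[used, , drop = FALSE]
  mets <- model$mets[used, , drop = FALSE]
  rxns <- model$rxns[jj, , drop = FALSE]
  rownames(mets) <- rownames(rxns) <- NULL
  ex <- model$exchanges[model$exchanges$rxn_id %in% keep_rxns, , drop = FALSE]
  rownames(ex) <- NULL
  gpr <- model$gpr[names(model$gpr) %in% keep_rxns]
  metabolic_model(model$id, mets, rxns, S, exchanges = ex, gpr = gpr,
                  kind = model$kind)
}
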