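#' @title Dense linear programming by the bounded-variable simplex method
#'
#' @description
#' `lp_solve()` solves small dense linear programs
#' \deqn{\max/\min\; c'v \quad s.t.\quad A v \; (=,\le,\ge)\; b,\; lb \le v \le ub}
#' with a two-phase primal simplex using Bland's anti-cycling rule.
#' It exists because the package must run with no external LP library;
#' problems here are tiny (tens of reactions), so a dense tableau-free
#' implementation with a fresh basis factorization per pivot is both fast
#' enough and easy to audit. Row duals are returned on request.
#'
#' @param obj numeric objective coefficients, one per variable.
#' @param A dense constraint matrix (rows = constraints).
#' @param b right-hand side.
#' @param dir character vector of constraint directions, each one of
#'   `"="`, `"<="`, `">="`; recycled if length 1.
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param sense `"max"` or `"min"`.
#' @param duals if `TRUE`, return the dual value of every constraint row.
#'
#' @return a list with elements `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective`, `x` (primal solution in
#'   the original variables) and, when requested, `duals` (one per row of
#'   `A`, sign convention: the change of the *stated* objective per unit
#'   increase of `b`).
#' @keywords internal
lp_solve <- function(obj, A, b, dir = "=", lb, ub, sense = "max",
                     duals = FALSE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (length(dir) == 1L) dir <- rep(dir, m)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  sense <- match.arg(sense, c("max", "min"))
  c0 <- if (sense == "min") -obj else obj

  ## append slack variables for inequality rows
  n_slack <- sum(dir != "=")
  if (n_slack > 0L) {
    S <- matrix(0, m, n_slack)
    k <- 0L
    for (i in seq_len(m)) {
      if (dir[i] != "=") {
        k <- k + 1L
        S[i, k] <- if (dir[i] == "<=") 1 else -1
      }
    }
    A <- cbind(A, S)
    c0 <- c(c0, rep(0, n_slack))
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(Inf, n_slack))
  }
  nt <- n + n_slack

  ## shift to x = v - lb so every variable has lower bound 0
  if (any(!is.finite(lb))) stop("lp_solve: lower bounds must be finite")
  b0 <- b - drop(A %*% lb)
  u <- ub - lb

  res <- .simplex_bounded(c0, A, b0, u)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_,
                x = rep(NA_real_, n)))

  x_full <- res$x + lb
  out <- list(status = "optimal",
              objective = sum(obj * x_full[seq_len(n)]),
              x = x_full[seq_len(n)])
  if (duals) {
    y <- res$y
    out$duals <- if (sense == "min") -y else y
  }
  out
}

## Bounded-variable two-phase primal simplex for
##   max c'x  s.t.  A x = b, 0 <= x <= u   (u may be Inf)
## Bland's rule throughout: guaranteed finite termination, adequate speed
## at the problem sizes used here.
.simplex_bounded <- function(cvec, A, b, u, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  m_orig <- m
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  ## phase 1: artificial variables with identity basis
  Ae <- cbind(A, diag(m))
  ue <- c(u, rep(Inf, m))
  c1 <- c(rep(0, n), rep(-1, m))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)
  x <- rep(0, n + m)
  x[basis] <- b

  st <- .simplex_iterate(c1, Ae, b, ue, basis, at_upper, tol)
  if (st$status != "optimal") return(list(status = "infeasible"))
  if (sum(c1 * st$x) < -1e-7) return(list(status = "infeasible"))
  basis <- st$basis; at_upper <- st$at_upper; x <- st$x

  ## drive remaining (degenerate) artificials out of the basis
  keep_rows <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      Binv_row <- solve(Ae[, basis, drop = FALSE])[i, , drop = FALSE]
      w <- drop(Binv_row %*% Ae[, seq_len(n), drop = FALSE])
      j <- which(abs(w) > 1e-8 & !(seq_len(n) %in% basis))
      if (length(j) > 0L) {
        basis[i] <- j[1L]
      } else {
        keep_rows[i] <- FALSE   # redundant row
      }
    }
  }
  row_map <- which(keep_rows)
  if (!all(keep_rows)) {
    sel <- keep_rows
    Ae <- Ae[sel, , drop = FALSE]
    b <- b[sel]
    basis <- basis[sel]
    m <- sum(sel)
  }

  ## all rows redundant: optimize each variable against its bounds alone
  if (m == 0L) {
    xb <- ifelse(cvec > tol, u, 0)
    if (any(!is.finite(xb))) return(list(status = "unbounded"))
    y <- rep(0, m_orig)
    return(list(status = "optimal", objective = sum(cvec * xb),
                x = xb, y = y))
  }

  ## phase 2
  c2 <- c(cvec, rep(0, ncol(Ae) - n))
  ue2 <- ue
  ue2[seq.int(n + 1L, length(ue))] <- 0  # freeze artificials at zero
  st <- .simplex_iterate(c2, Ae, b, ue2, basis, at_upper, tol)
  if (st$status != "optimal") return(list(status = st$status))

  xb <- st$x[seq_len(n)]
  B <- Ae[, st$basis, drop = FALSE]
  y_kept <- drop(solve(t(B), c2[st$basis]))
  ## re-expand duals to the original rows; undo the sign of negated rows
  y <- rep(0, m_orig)
  y[row_map] <- y_kept
  y[neg] <- -y[neg]
  list(status = "optimal", objective = sum(cvec * xb), x = xb, y = y)
}

## dispatch to the compiled pivot loop; .simplex_iterate_r below is the
## readable reference twin (identical rules), cross-checked in tests
.simplex_iterate <- function(cvec, A, b, u, basis, at_upper, tol,
                             max_iter = 20000L) {
  r <- .simplex_iterate_cpp(cvec, A, b, u, as.integer(basis),
                            as.logical(at_upper), tol,
                            as.integer(max_iter))
  if (r$status == 1L) return(list(status = "unbounded"))
  list(status = "optimal", x = r$x, basis = r$basis,
       at_upper = r$at_upper)
}

.simplex_iterate_r <- function(cvec, A, b, u, basis, at_upper, tol,
                               max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  x <- rep(0, n)
  x[at_upper & is.finite(u)] <- u[at_upper & is.finite(u)]
  B <- A[, basis, drop = FALSE]
  x[basis] <- solve(B, b - drop(A[, -basis, drop = FALSE] %*%
                                  x[-basis]))
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- drop(solve(t(B), cvec[basis]))
    d <- cvec - drop(y %*% A)
    d[basis] <- 0
    nonbasic <- setdiff(seq_len(n), basis)
    enter_lo <- nonbasic[!at_upper[nonbasic] & d[nonbasic] > tol]
    enter_hi <- nonbasic[at_upper[nonbasic] & d[nonbasic] < -tol]
    cand <- sort(c(enter_lo, enter_hi))
    if (length(cand) == 0L)
      return(list(status = "optimal", x = x, basis = basis,
                  at_upper = at_upper))
    j <- cand[1L]                      # Bland: smallest index
    up <- !at_upper[j]                 # TRUE: j increases from 0
    w <- solve(B, A[, j])
    sgn <- if (up) 1 else -1
    ## x_basis changes by -sgn * w * t as x_j moves by sgn * t, t >= 0
    t_best <- if (is.finite(u[j])) u[j] else Inf
    leave <- 0L                        # 0 = bound flip of j itself
    for (i in seq_len(m)) {
      wi <- sgn * w[i]
      bi <- basis[i]
      if (wi > tol) {                  # x_bi decreases toward 0
        ti <- x[bi] / wi
        if (ti < t_best - tol ||
            (ti < t_best + tol && leave > 0L && bi < basis[leave])) {
          t_best <- ti; leave <- i
        }
      } else if (wi < -tol && is.finite(u[bi])) {  # increases toward ub
        ti <- (u[bi] - x[bi]) / (-wi)
        if (ti < t_best - tol ||
            (ti < t_best + tol && leave > 0L && bi < basis[leave])) {
          t_best <- ti; leave <- i
        }
      }
    }
    if (!is.finite(t_best))
      return(list(status = "unbounded"))
    t_best <- max(t_best, 0)
    ## update primal values
    x[j] <- x[j] + sgn * t_best
    x[basis] <- x[basis] - sgn * w * t_best
    if (leave == 0L) {                 # j flips bound, basis unchanged
      at_upper[j] <- !at_upper[j]
    } else {
      bl <- basis[leave]
      wl <- sgn * w[leave]
      at_upper[bl] <- wl < 0           # left at its upper bound?
      x[bl] <- if (at_upper[bl]) u[bl] else 0
      basis[leave] <- j
      at_upper[j] <- FALSE
    }
  }
  stop("simplex: iteration limit reached")
}

#' Branch-and-bound mixed-integer linear programming
#'
#' Depth-first branch and bound over [lp_solve()] relaxations. Intended
#' for the small iMAT MILPs this package builds (tens of binaries).
#'
#' @inheritParams lp_solve
#' @param int_idx indices of variables required to take integer values.
#' @param int_tol integrality tolerance.
#' @return same shape as [lp_solve()]; `status` is `"optimal"` or
#'   `"infeasible"`.
#' @keywords internal
milp_solve <- function(obj, A, b, dir = "=", lb, ub, sense = "max",
                       int_idx = integer(0), int_tol = 1e-6) {
  sense <- match.arg(sense, c("max", "min"))
  sgn <- if (sense == "max") 1 else -1
  best <- list(objective = -Inf, x = NULL)
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_solve(obj, A, b, dir, node$lb, node$ub, sense)
    if (rel$status != "optimal") next
    if (sgn * rel$objective <= best$objective + int_tol) next  # bound
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (length(frac) == 0L || max(frac) <= int_tol) {
      val <- sgn * rel$objective
      if (val > best$objective) {
        best <- list(objective = val,
                     x = replace(rel$x, int_idx, round(rel$x[int_idx])))
      }
      next
    }
    j <- int_idx[which.max(frac)]
    xj <- rel$x[j]
    lo <- node; lo$ub[j] <- floor(xj)
    hi <- node; hi$lb[j] <- ceiling(xj)
    stack <- c(stack, list(lo, hi))
  }
  if (is.null(best$x))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  list(status = "optimal", objective = sgn * best$objective, x = best$x)
}
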