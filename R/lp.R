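#' Solve a bounded-variable linear programme
#'
#' Minimises or maximises `obj %*% x` subject to `A %*% x = b` and
#' `lb <= x <= ub`, using a two-phase revised simplex method with upper and
#' lower variable bounds. This is the work-horse behind every flux balance
#' analysis solve in the package; flux bounds are always finite (unconstrained
#' reactions use the documented sentinel of +/- 1000 umol/min/gDW), which keeps
#' the LP bounded by construction.
#'
#' The implementation maintains an explicit dense basis inverse updated by
#' elementary (product-form) pivots, with periodic refactorisation for
#' numerical hygiene, Dantzig pricing, and a fall-back to Bland's rule when a
#' degenerate stall is detected so that termination is guaranteed.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix (`m x n`), dense or any `Matrix` class.
#' @param b right-hand side, length `m` (defaults to all zeros, the
#'   steady-state case).
#' @param lb,ub numeric bounds, length `n`. Must be finite; use a large
#'   sentinel for practically unconstrained variables.
#' @param sense `"max"` or `"min"`.
#' @param tol primal/dual feasibility tolerance.
#' @param max_iter pivot limit (default scales with problem size).
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (primal solution, `NULL` unless optimal) and
#'   `objval` (objective value in the requested sense).
#' @keywords internal
lp_solve <- function(obj, A, b = NULL, lb, ub, sense = "max",
                     tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite bounds; use a sentinel for 'unbounded'")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  ub <- pmax(ub, lb)  # remove sub-tolerance inversions

  minimize <- identical(sense, "min")
  cvec <- if (minimize) as.numeric(obj) else -as.numeric(obj)

  if (m == 0L) {  # bound-constrained separable problem
    x <- ifelse(cvec >= 0, lb, ub)
    val <- sum(cvec * x)
    return(list(status = "optimal", x = x,
                objval = if (minimize) val else -val))
  }
  if (is.null(max_iter)) max_iter <- max(2000L, 50L * (n + m))

  ## augment with one artificial column per row
  N <- n + m
  lbx <- c(lb, numeric(m))
  ubx <- c(ub, numeric(m))     # artificial upper bounds set below
  x <- numeric(N)

  ## nonbasic structurals start at the bound of smaller magnitude
  at_ub <- abs(ub) < abs(lb)
  x[seq_len(n)] <- ifelse(at_ub, ub, lb)
  vstat <- integer(N)                 # 0 basic, 1 at lb, 2 at ub
  vstat[seq_len(n)] <- ifelse(at_ub, 2L, 1L)

  r <- b - as.vector(A %*% x[seq_len(n)])
  s <- ifelse(r >= 0, 1, -1)
  Aart <- diag(s, nrow = m)
  A2 <- cbind(A, Aart)
  ubx[n + seq_len(m)] <- abs(r)
  x[n + seq_len(m)] <- abs(r)
  basis <- n + seq_len(m)
  Binv <- diag(s, nrow = m)           # inverse of diag(s)

  phase1_c <- c(numeric(n), rep(1, m))
  refactor <- function(basis) {
    Bi <- tryCatch(solve(A2[, basis, drop = FALSE]), error = function(e) NULL)
    Bi
  }
  recompute_basics <- function(basis, Binv) {
    nb <- setdiff(seq_len(N), basis)
    as.vector(Binv %*% (b - A2[, nb, drop = FALSE] %*% x[nb]))
  }

  run_phase <- function(cc, basis, Binv, phase) {
    pivots <- 0L
    stall <- 0L
    bland <- FALSE
    last_obj <- Inf
    repeat {
      if (pivots >= max_iter)
        return(list(status = "iteration_limit", basis = basis, Binv = Binv))
      cB <- cc[basis]
      y <- as.vector(crossprod(Binv, cB))
      d <- cc - as.vector(crossprod(A2, y))
      is_nb <- vstat != 0L
      movable <- is_nb & (ubx - lbx > tol)
      cand_lo <- movable & vstat == 1L & d < -tol
      cand_hi <- movable & vstat == 2L & d > tol
      cand <- which(cand_lo | cand_hi)
      if (!length(cand))
        return(list(status = "optimal", basis = basis, Binv = Binv))
      j <- if (bland) min(cand) else cand[which.max(abs(d[cand]))]
      dir <- if (vstat[j] == 1L) 1 else -1
      w <- as.vector(Binv %*% A2[, j])
      xB <- x[basis]
      delta <- dir * w
      tmax <- ubx[j] - lbx[j]
      piv_tol <- 1e-9
      tl <- rep.int(Inf, m)
      pos <- delta > piv_tol
      neg <- delta < -piv_tol
      if (any(pos)) tl[pos] <- (xB[pos] - lbx[basis[pos]]) / delta[pos]
      if (any(neg)) tl[neg] <- (ubx[basis[neg]] - xB[neg]) / (-delta[neg])
      tl[tl < 0] <- 0
      tlim <- min(tl, tmax)
      leave <- 0L
      if (tlim < tmax - 1e-12) {
        ties <- which(tl <= tlim + 1e-12)
        leave <- if (bland) ties[which.min(basis[ties])]
                 else ties[which.max(abs(w[ties]))]
      }
      if (tlim > 1e29)
        return(list(status = "unbounded", basis = basis, Binv = Binv))
      ## apply step
      x[basis] <<- xB - delta * tlim
      x[j] <<- x[j] + dir * tlim
      if (leave == 0L) {            # bound flip, basis unchanged
        vstat[j] <<- if (vstat[j] == 1L) 2L else 1L
      } else {
        lv <- basis[leave]
        hit_lb <- delta[leave] > 0
        vstat[lv] <<- if (hit_lb) 1L else 2L
        x[lv] <<- if (hit_lb) lbx[lv] else ubx[lv]
        vstat[j] <<- 0L
        basis[leave] <- j
        wl <- w[leave]
        Brow <- Binv[leave, ] / wl
        Binv <- Binv - outer(w, Brow)
        Binv[leave, ] <- Brow
        pivots <- pivots + 1L
        if (pivots %% 64L == 0L) {
          Bi <- refactor(basis)
          if (!is.null(Bi)) {
            Binv <- Bi
            x[basis] <<- recompute_basics(basis, Binv)
          }
        }
      }
      cur <- sum(cc * x)
      if (cur > last_obj - 1e-12) stall <- stall + 1L else stall <- 0L
      last_obj <- cur
      if (stall > 2L * (n + m)) bland <- TRUE
    }
  }

  ## phase 1: drive artificials to zero
  p1 <- run_phase(phase1_c, basis, Binv, 1L)
  if (p1$status == "iteration_limit")
    stop("lp_solve: iteration limit reached in phase 1")
  basis <- p1$basis; Binv <- p1$Binv
  if (sum(x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  ## pin artificials at zero for phase 2
  ubx[n + seq_len(m)] <- 0
  x[n + seq_len(m)] <- 0
  x[basis] <- recompute_basics(basis, Binv)

  p2 <- run_phase(c(cvec, numeric(m)), basis, Binv, 2L)
  if (p2$status == "iteration_limit")
    stop("lp_solve: iteration limit reached in phase 2")
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  basis <- p2$basis; Binv <- p2$Binv

  ## final hygiene: refactorise, recompute basics, clamp round-off
  Bi <- refactor(basis)
  if (!is.null(Bi)) {
    Binv <- Bi
    x[basis] <- recompute_basics(basis, Binv)
  }
  xs <- pmin(pmax(x[seq_len(n)], lb - 1e-7), ub + 1e-7)
  val <- sum(cvec * xs)
  list(status = "optimal", x = xs,
       objval = if (minimize) val else -val)
}
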