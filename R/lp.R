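#' Solve a bounded-variable linear program
#'
#' Solves `max/min c'x` subject to `A x = b` and `lb <= x <= ub` with a dense
#' two-phase primal simplex. All variable bounds must be finite; this is the
#' natural setting for constraint-based metabolic models, where every flux is
#' boxed by the model's (or a big-M) bound.
#'
#' Inequality rows can be supplied via `A_ub x <= b_ub`; they are converted to
#' equalities with slack variables whose upper bounds are derived by interval
#' arithmetic over the variable box.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A equality constraint matrix (m x n), may have zero rows.
#' @param b equality right-hand side (length m).
#' @param lb,ub finite lower/upper variable bounds (length n).
#' @param A_ub,b_ub optional inequality constraints `A_ub x <= b_ub`.
#' @param maximize if `TRUE` (default) maximize the objective.
#' @param tol numerical tolerance for pivoting and feasibility.
#' @return list with `status` ("optimal" or "infeasible"), `x` (length n),
#'   and `objective`.
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, A_ub = NULL, b_ub = NULL,
                     maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  n0 <- n
  stopifnot(is.numeric(lb), is.numeric(ub), length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + tol))
    stop("solve_lp: lower bound exceeds upper bound")
  A <- if (is.null(A)) matrix(0, 0, n) else as.matrix(A)
  if (is.null(b)) b <- numeric(0)

  # fold inequalities in as equalities with box-bounded slacks
  if (!is.null(A_ub) && nrow(A_ub) > 0) {
    A_ub <- as.matrix(A_ub)
    k <- nrow(A_ub)
    # slack s = b_ub - A_ub x; its max over the box gives a finite upper bound
    pos <- pmax(A_ub, 0); neg <- pmin(A_ub, 0)
    ax_min <- as.vector(pos %*% lb + neg %*% ub)
    s_ub <- pmax(b_ub - ax_min, 0)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(A_ub, diag(k)))
    b <- c(b, b_ub)
    obj <- c(obj, numeric(k))
    lb <- c(lb, numeric(k))
    ub <- c(ub, s_ub)
    n <- n + k
  }

  res <- simplex_box(obj, A, b, lb, ub, maximize = maximize, tol = tol)
  if (res$status == "optimal")
    res$x <- res$x[seq_len(n0)]
  res
}

# Two-phase dense tableau simplex for
#   max/min c'x  s.t.  A x = b,  lb <= x <= ub  (finite box).
# Shift y = x - lb so 0 <= y <= u; upper bounds become explicit slack rows.
simplex_box <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  m <- nrow(A)
  u <- ub - lb
  rhs1 <- as.vector(b - A %*% lb)
  # flip equality rows so the rhs is non-negative (artificials start feasible)
  flip <- rhs1 < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs1[flip] <- -rhs1[flip]
  }

  # tableau columns: y (n) | bound slacks s (n) | artificials a (m) | rhs
  M <- m + n
  N <- 2L * n + m
  T <- matrix(0, M, N + 1L)
  if (m > 0) {
    T[seq_len(m), seq_len(n)] <- A
    T[seq_len(m), 2L * n + seq_len(m)] <- diag(m)
    T[seq_len(m), N + 1L] <- rhs1
  }
  T[m + seq_len(n), seq_len(n)] <- diag(n)
  T[m + seq_len(n), n + seq_len(n)] <- diag(n)
  T[m + seq_len(n), N + 1L] <- u

  basis <- c(2L * n + seq_len(m), n + seq_len(n))

  cost <- if (maximize) -obj else obj  # internal: minimize

  # phase-1 reduced costs: minimize sum of artificials (all start basic)
  c1 <- c(numeric(2L * n), rep(1, m))
  art_rows <- which(basis > 2L * n)
  cr <- c(c1, 0)
  if (length(art_rows) > 0)
    cr <- cr - colSums(T[art_rows, , drop = FALSE])

  allowed <- rep(TRUE, N)
  st <- simplex_iterate(T, basis, cr, allowed, tol)
  T <- st$T; basis <- st$basis; cr <- st$cr
  if (st$status != "optimal" || -cr[N + 1L] > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))

  # drive remaining artificials out of the basis (or drop redundant rows)
  art_cols <- 2L * n + seq_len(m)
  drop_rows <- integer(0)
  for (i in which(basis > 2L * n)) {
    piv <- which(abs(T[i, seq_len(2L * n)]) > tol)
    if (length(piv) == 0) { drop_rows <- c(drop_rows, i); next }
    j <- piv[1]
    T <- pivot_tableau(T, i, j)
    basis[i] <- j
  }
  if (length(drop_rows) > 0) {
    keep <- setdiff(seq_len(nrow(T)), drop_rows)
    T <- T[keep, , drop = FALSE]
    basis <- basis[keep]
  }
  allowed[art_cols] <- FALSE

  # phase-2 reduced costs from scratch
  cfull <- c(cost, numeric(n + m))
  cB <- cfull[basis]
  cr2 <- c(cfull, 0)
  if (length(basis) > 0)
    cr2 <- cr2 - as.vector(crossprod(T, cB))

  st <- simplex_iterate(T, basis, cr2, allowed, tol)
  if (st$status != "optimal")
    return(list(status = st$status, x = NULL, objective = NA_real_))
  T <- st$T; basis <- st$basis

  y <- numeric(n)
  in_y <- basis <= n
  y[basis[in_y]] <- T[in_y, ncol(T)]
  x <- y + lb
  obj_val <- sum(obj * x)
  list(status = "optimal", x = x, objective = obj_val)
}

# core pivoting loop; cr is the reduced-cost row (length ncol(T)), with
# cr[rhs] = -current objective value (minimization)
simplex_iterate <- function(T, basis, cr, allowed, tol) {
  M <- nrow(T)
  N <- ncol(T) - 1L
  rhs_col <- N + 1L
  max_iter <- 2000L + 40L * (M + N)
  bland_after <- 500L + 10L * (M + N)
  for (it in seq_len(max_iter)) {
    cand <- which(allowed & cr[seq_len(N)] < -tol)
    if (length(cand) == 0)
      return(list(status = "optimal", T = T, basis = basis, cr = cr))
    j <- if (it > bland_after) cand[1] else cand[which.min(cr[cand])]
    col <- T[, j]
    rows <- which(col > tol)
    if (length(rows) == 0)
      return(list(status = "unbounded", T = T, basis = basis, cr = cr))
    ratio <- T[rows, rhs_col] / col[rows]
    rmin <- min(ratio)
    tie <- rows[ratio <= rmin + tol]
    i <- tie[which.min(basis[tie])]  # lowest basis index on ties (anti-cycling)
    T <- pivot_tableau(T, i, j)
    cr <- cr - cr[j] * T[i, ]
    basis[i] <- j
  }
  stop("simplex did not converge within the iteration limit")
}

pivot_tableau <- function(T, i, j) {
  T[i, ] <- T[i, ] / T[i, j]
  fac <- T[, j]
  fac[i] <- 0
  T <- T - outer(fac, T[i, ])
  T[, j] <- 0
  T[i, j] <- 1
  T
}
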