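#' Warmup flux vectors for the sampler
#'
#' The FVA minimum- and maximum-attaining flux vectors of every reaction
#' (over the unconstrained-objective polytope), deduplicated. Their spread
#' spans the feasible polytope, which is what the hit-and-run direction
#' proposals need.
#'
#' @param model a feasible `metabolic_model`.
#' @param fraction_of_optimum objective constraint carried by the sampled
#'   polytope: the objective reaction's lower bound is raised to this
#'   fraction of the FBA optimum (default 1; use 0 to span the whole
#'   polytope).
#' @return matrix (points x reactions) of feasible flux vectors.
#' @export
warmup_points <- function(model, fraction_of_optimum = 1) {
  S <- stoichiometric_matrix(model)
  bb <- objective_constrained_bounds(model, fraction_of_optimum)
  lb <- bb$lb
  ub <- bb$ub
  b0 <- rep(0, nrow(S))
  n <- length(lb)
  pts <- matrix(NA_real_, 2L * n, n)
  for (j in seq_len(n)) {
    obj <- as.numeric(seq_len(n) == j)
    lo <- solve_lp(obj, S, b0, lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, S, b0, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("warmup_points: model is infeasible")
    pts[2L * j - 1L, ] <- lo$x
    pts[2L * j, ] <- hi$x
  }
  colnames(pts) <- model$reactions$id
  # deduplicate with a tolerance: points closer than 1e-6 are one point
  keep <- integer(0)
  for (i in seq_len(nrow(pts))) {
    dup <- FALSE
    for (k in keep) {
      if (max(abs(pts[i, ] - pts[k, ])) < 1e-6) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  pts[keep, , drop = FALSE]
}

#' Hit-and-run sampling of the feasible flux polytope
#'
#' Artificially-centered hit-and-run over `{v : S v = 0, lb <= v <= ub}`.
#' The chain runs in null-space coordinates (`v = v0 + N t` with `N` an
#' orthonormal basis of `null(S)`), so mass balance holds to machine
#' precision at every step and no drift correction is needed; the box bounds
#' are enforced exactly by the chord-limit computation. Directions are drawn
#' ACHR-style through the running center, which is refreshed every 100
#' steps; one point is recorded every `thinning` steps.
#'
#' @param model a feasible `metabolic_model`.
#' @param n number of samples (default 1000).
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param thinning steps between recorded samples (default 100).
#' @param fraction_of_optimum objective constraint of the sampled polytope
#'   (see [warmup_points()]); default 1.
#' @return object of class `flux_samples`: list with `samples`
#'   (n x reactions matrix), `seed`, `thinning`, `sampler`
#'   (`"achr-nullspace"`).
#' @export
sample_fluxes <- function(model, n = 1000, seed = 1L, thinning = 100L,
                          fraction_of_optimum = 1) {
  if (n < 1) stop("n must be >= 1")
  wp <- warmup_points(model, fraction_of_optimum)
  S <- stoichiometric_matrix(model)
  bb <- objective_constrained_bounds(model, fraction_of_optimum)
  lb <- bb$lb
  ub <- bb$ub
  nr <- ncol(wp)

  # orthonormal null-space basis of S (orthogonal complement of its row space)
  qrt <- qr(t(S))
  rank <- qrt$rank
  Nmat <- if (rank < nr)
    qr.Q(qrt, complete = TRUE)[, (rank + 1L):nr, drop = FALSE] else
    matrix(0, nr, 0)
  dof <- ncol(Nmat)

  v0 <- colMeans(wp)                     # feasible by convexity
  out <- matrix(rep(v0, each = n), n, nr,
                dimnames = list(NULL, colnames(wp)))
  if (dof == 0 || nrow(wp) < 2) {
    return(structure(list(samples = out, seed = as.integer(seed),
                          thinning = as.integer(thinning),
                          sampler = "achr-nullspace"),
                     class = "flux_samples"))
  }

  Twp <- (wp - matrix(v0, nrow(wp), nr, byrow = TRUE)) %*% Nmat  # warmup coords
  out <- with_local_seed(seed, {
  t_cur <- Twp[sample.int(nrow(Twp), 1L), ]
  center_t <- colMeans(Twp)
  visited_sum <- t_cur
  visited_n <- 1L
  got <- 0L
  step <- 0L
  while (got < n) {
    step <- step + 1L
    # ACHR direction: from the running center through a random warmup point
    d <- Twp[sample.int(nrow(Twp), 1L), ] - center_t
    nrm <- sqrt(sum(d^2))
    if (nrm < 1e-12) next
    d <- d / nrm
    dv <- as.vector(Nmat %*% d)
    v_cur <- v0 + as.vector(Nmat %*% t_cur)
    sel <- abs(dv) > 1e-11
    if (!any(sel)) next
    a_lo <- (lb[sel] - v_cur[sel]) / dv[sel]
    a_hi <- (ub[sel] - v_cur[sel]) / dv[sel]
    amin <- max(pmin(a_lo, a_hi))
    amax <- min(pmax(a_lo, a_hi))
    if (amax <= amin) next
    alpha <- stats::runif(1, amin, amax)
    t_cur <- t_cur + alpha * d
    visited_sum <- visited_sum + t_cur
    visited_n <- visited_n + 1L
    if (step %% 100L == 0L)
      center_t <- visited_sum / visited_n
    if (step %% as.integer(thinning) == 0L) {
      got <- got + 1L
      out[got, ] <- v0 + as.vector(Nmat %*% t_cur)
    }
  }
  # clip round-off excursions at the box edge (< 1e-9 by construction)
  pmin(pmax(out, matrix(lb, n, nr, byrow = TRUE)),
       matrix(ub, n, nr, byrow = TRUE))
  })
  structure(list(samples = out, seed = as.integer(seed),
                 thinning = as.integer(thinning),
                 sampler = "achr-nullspace"),
            class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat(sprintf("<flux_samples: %d x %d (%s, seed %d, thinning %d)>\n",
              nrow(x$samples), ncol(x$samples), x$sampler, x$seed, x$thinning))
  invisible(x)
}
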