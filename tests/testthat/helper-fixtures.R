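# Shared fixtures and independent oracles, all built in code.

# linear chain: substrate uptake (<= 10) -> A -> B -> sink (objective)
chain_model <- function(uptake = 10) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(
      id = c("EX_A", "R1", "SINK"),
      lower_bound = c(0, 0, 0), upper_bound = c(uptake, 1000, 1000),
      subsystem = c("boundary", "core", "biomass"),
      gpr = c("", "g1", "")),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                         SINK = c(B = -1)),
    objective = "SINK")
}

# two equivalent parallel paths A -> B, total limited to 10 by uptake
parallel_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(
      id = c("EX_A", "P1", "P2", "SINK"),
      lower_bound = c(0, 0, 0, 0),
      upper_bound = c(10, 1000, 1000, 1000),
      subsystem = c("boundary", "path1", "path2", "biomass"),
      gpr = c("", "g1", "g2", "")),
    stoichiometry = list(EX_A = c(A = 1), P1 = c(A = -1, B = 1),
                         P2 = c(A = -1, B = 1), SINK = c(B = -1)),
    objective = "SINK")
}

# random bounded network; v = 0 is always feasible (lb <= 0 <= ub)
random_network_model <- function(seed, n_rxn = NULL, n_met = NULL) {
  set.seed(seed)
  n_rxn <- if (is.null(n_rxn)) sample(3:8, 1) else n_rxn
  n_met <- if (is.null(n_met)) sample(2:4, 1) else n_met
  mets <- sprintf("m%d", seq_len(n_met))
  sto <- list()
  rxns <- list()
  for (j in seq_len(n_rxn)) {
    repeat {
      coef <- sample(c(-2L, -1L, 0L, 1L, 2L), n_met, replace = TRUE)
      if (any(coef != 0)) break
    }
    nz <- which(coef != 0)
    rid <- sprintf("r%d", j)
    sto[[rid]] <- stats::setNames(as.numeric(coef[nz]), mets[nz])
    rev <- stats::runif(1) < 0.4
    rxns[[j]] <- data.frame(
      id = rid, lower_bound = if (rev) -round(stats::runif(1, 1, 10)) else 0,
      upper_bound = round(stats::runif(1, 1, 10)),
      subsystem = "s", gpr = "")
  }
  metabolic_model(data.frame(id = mets, compartment = "c"),
                  do.call(rbind, rxns), sto,
                  objective = sprintf("r%d", sample(n_rxn, 1)))
}

# vertex enumeration oracle for {S v = 0, lb <= v <= ub}: every vertex has
# n - rank(S) coordinates at a bound; enumerate all choices and bound sides.
enumerate_vertices <- function(S, lb, ub, tol = 1e-8) {
  n <- ncol(S)
  r <- qr(S)$rank
  dof <- n - r
  verts <- list()
  add_vertex <- function(v) {
    if (all(v >= lb - tol) && all(v <= ub + tol) &&
        max(abs(S %*% v)) < tol)
      verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (dof == 0) {
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v)) add_vertex(v)
  } else {
    for (fix in utils::combn(n, dof, simplify = FALSE)) {
      free <- setdiff(seq_len(n), fix)
      Sf <- S[, free, drop = FALSE]
      if (qr(Sf)$rank < length(free)) next
      for (mask in seq_len(2^dof) - 1L) {
        side <- as.logical(bitwAnd(mask, 2^(seq_len(dof) - 1L)))
        vfix <- ifelse(side, ub[fix], lb[fix])
        rhs <- -S[, fix, drop = FALSE] %*% vfix
        vfree <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(vfree)) next
        v <- numeric(n)
        v[fix] <- vfix
        v[free] <- vfree
        add_vertex(v)
      }
    }
  }
  if (length(verts) == 0) return(NULL)
  out <- do.call(rbind, verts)
  colnames(out) <- colnames(S)
  out
}

# brute-force iMAT oracle: enumerate every indicator assignment, check LP
# feasibility of the implied bounds, take the best agreement count
imat_oracle <- function(model, states, eps = 1.0) {
  S <- stoichiometric_matrix(model)
  lb0 <- model$reactions$lower_bound
  ub0 <- model$reactions$upper_bound
  rxn <- model$reactions$id
  st <- stats::setNames(rep(0L, length(rxn)), rxn)
  st[names(states)] <- as.integer(states)
  hi <- which(st == 1L)
  lo <- which(st == -1L)
  hi_opts <- rep(list(c("none", "fwd", "bwd")), length(hi))
  lo_opts <- rep(list(c(FALSE, TRUE)), length(lo))
  grid <- expand.grid(c(hi_opts, lo_opts), stringsAsFactors = FALSE)
  best <- 0L
  feasible <- function(lb, ub) {
    if (any(lb > ub)) return(FALSE)
    r <- solve_lp(numeric(length(lb)), S, rep(0, nrow(S)), lb, ub)
    r$status == "optimal"
  }
  for (k in seq_len(nrow(grid))) {
    lb <- lb0; ub <- ub0
    score <- 0L
    row <- grid[k, ]
    ok <- TRUE
    for (i in seq_along(hi)) {
      o <- row[[i]]
      if (o == "fwd") { lb[hi[i]] <- max(lb[hi[i]], eps); score <- score + 1L }
      if (o == "bwd") { ub[hi[i]] <- min(ub[hi[i]], -eps); score <- score + 1L }
    }
    for (i in seq_along(lo)) {
      if (isTRUE(row[[length(hi) + i]])) {
        lb[lo[i]] <- max(lb[lo[i]], 0); ub[lo[i]] <- min(ub[lo[i]], 0)
        score <- score + 1L
      }
    }
    if (score <= best) next  # cannot improve
    if (feasible(lb, ub)) best <- score
  }
  best
}

# toy-model + simulated-counts bundle used by the pipeline tests
make_pipeline_fixture <- function(seed, n_per_group = 5,
                                  groups = c("control", "dose1", "dose2", "dose3"),
                                  effect = c(pathway_03 = 2),
                                  n_background = 500) {
  tg <- make_toy_gem(seed = seed)
  gene_ss <- unlist(lapply(names(tg$truth), function(s)
    stats::setNames(rep(s, length(tg$truth[[s]]$genes)), tg$truth[[s]]$genes)))
  scaling <- stats::setNames(c(0, 0.5, rep(1, length(groups) - 2)), groups)
  sim <- simulate_counts(tg$model$genes, gene_ss, groups = groups,
                         n_per_group = n_per_group, effects = effect,
                         dose_scaling = scaling, n_background = n_background,
                         seed = seed + 100)
  list(gem = tg, sim = sim)
}
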