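test_that("reaction states compose GPR evaluation over the profile", {
  tg <- make_toy_gem(seed = 4)
  m <- tg$model
  genes <- m$genes
  profile <- matrix(sample(c(-1L, 0L, 1L), length(genes) * 2, replace = TRUE),
                    ncol = 2, dimnames = list(genes, c("s1", "s2")))
  st <- reaction_states(m, profile, "s1")
  for (i in seq_len(nrow(m$reactions))) {
    expect_identical(
      unname(st[m$reactions$id[i]]),
      evaluate_tristate(parse_gpr(m$reactions$gpr[i]), profile[, "s1"]))
  }
  # empty GPR -> moderate
  expect_identical(unname(st["BIOMASS"]), 0L)
})

test_that("a single high reaction on a feasible chain is activated", {
  m <- chain_model()
  sol <- imat_optimize(m, c(R1 = 1L))
  expect_equal(sol$objective, 1L)
  expect_gte(abs(sol$fluxes[["R1"]]), sol$eps - 1e-6)
})

test_that("all-moderate states give objective 0 and identity extraction", {
  m <- parallel_model()
  sol <- imat_optimize(m, stats::setNames(integer(0), character(0)))
  expect_equal(sol$objective, 0L)
  ctx <- extract_context_model(m, sol)
  expect_identical(ctx$reactions$id, m$reactions$id)
})

test_that("high-through-low conflicts resolve to the enumeration optimum", {
  # chain where the high reaction can only carry flux through a low one
  m <- chain_model()
  states <- c(R1 = 1L, EX_A = -1L)
  sol <- imat_optimize(m, states)
  expect_equal(sol$objective, imat_oracle(m, states))
  # indicator invariants
  for (r in names(sol$active))
    if (sol$active[[r]]) expect_gte(abs(sol$fluxes[[r]]), sol$eps - 1e-6)
  for (r in names(sol$off))
    if (sol$off[[r]]) expect_lte(abs(sol$fluxes[[r]]), 1e-6)
})

test_that("MILP objective equals brute-force enumeration on random fixtures", {
  n_fixtures <- 0
  seed <- 0
  while (n_fixtures < 20) {
    seed <- seed + 1
    m <- random_network_model(seed + 300)
    rxn <- m$reactions$id
    set.seed(seed + 1000)
    st <- sample(c(-1L, 0L, 1L), length(rxn), replace = TRUE)
    names(st) <- rxn
    n_ind <- 2L * sum(st == 1L) + sum(st == -1L)
    if (n_ind == 0 || n_ind > 10) next
    n_fixtures <- n_fixtures + 1
    states <- st[st != 0L]
    sol <- imat_optimize(m, states, eps = 0.5)
    expect_equal(sol$objective, imat_oracle(m, states, eps = 0.5),
                 label = sprintf("fixture seed %d", seed))
    # flux respects mass balance and bounds
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  }
})

test_that("promoting a flux-carrying moderate reaction never drops the objective", {
  for (seed in c(21, 22, 23)) {
    m <- random_network_model(seed + 600)
    rxn <- m$reactions$id
    set.seed(seed)
    st <- stats::setNames(sample(c(-1L, 0L, 1L), length(rxn), TRUE), rxn)
    states <- st[st != 0L]
    if (2L * sum(st == 1L) + sum(st == -1L) > 10) next
    sol <- imat_optimize(m, states, eps = 0.5)
    mod <- names(st)[st == 0L & abs(sol$fluxes[names(st)]) >= 0.5]
    if (length(mod) == 0) next
    promoted <- c(states, stats::setNames(1L, mod[1]))
    sol2 <- imat_optimize(m, promoted, eps = 0.5)
    expect_gte(sol2$objective, sol$objective + 1L)
  }
})

test_that("context extraction removes only switched-off low reactions", {
  pm <- parallel_model()
  sol <- imat_optimize(pm, c(P2 = -1L))
  expect_true(sol$off[["P2"]])
  ctx <- extract_context_model(pm, sol)
  expect_false("P2" %in% ctx$reactions$id)
  expect_true(all(ctx$reactions$id %in% pm$reactions$id))
  expect_gt(fba(ctx)$objective_value, 0)
})

test_that("biomass-infeasible prunes are repaired by greedy restoration", {
  m <- chain_model()
  # the only route is low: pruning it would kill biomass
  sol <- imat_optimize(m, c(R1 = -1L))
  ctx <- extract_context_model(m, sol)
  expect_gte(fba(ctx)$objective_value, 1e-6)
  expect_true("R1" %in% ctx$reactions$id)
})

test_that("context models keep positive biomass across pipeline seeds", {
  for (seed in 1:3) {
    fx <- make_pipeline_fixture(seed, n_per_group = 2,
                                groups = c("control", "dose1"),
                                n_background = 100)
    prof <- discretize(normalize_counts(fx$sim$counts))
    sm <- colnames(fx$sim$counts)[3]  # one exposed sample
    st <- reaction_states(fx$gem$model, prof, sm)
    sol <- imat_optimize(fx$gem$model, st)
    ctx <- extract_context_model(fx$gem$model, sol)
    expect_gt(fba(ctx)$objective_value, 0)
  }
})
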