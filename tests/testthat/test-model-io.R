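test_that("a small JSON fixture loads with the expected structure", {
  m <- chain_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_s3_class(m2, "metabolic_model")
  expect_equal(nrow(m2$reactions), 3)
  expect_equal(m2$objective, "SINK")
})

test_that("validation rejects structurally broken models", {
  mets <- data.frame(id = "A", compartment = "c")
  # stoichiometry referencing an undefined metabolite
  expect_error(
    metabolic_model(mets,
                    data.frame(id = "r1", lower_bound = 0, upper_bound = 1),
                    list(r1 = c(X = -1)), objective = "r1"),
    "undefined metabolite")
  # missing objective reaction
  expect_error(
    metabolic_model(mets,
                    data.frame(id = "r1", lower_bound = 0, upper_bound = 1),
                    list(r1 = c(A = -1)), objective = "nope"),
    "objective")
  # inverted bounds
  expect_error(
    metabolic_model(mets,
                    data.frame(id = "r1", lower_bound = 2, upper_bound = 1),
                    list(r1 = c(A = -1)), objective = "r1"),
    "lower_bound exceeds")
  # empty stoichiometry
  expect_error(
    metabolic_model(mets,
                    data.frame(id = "r1", lower_bound = 0, upper_bound = 1),
                    list(r1 = numeric(0)), objective = "r1"),
    "nonzero stoichiometric")
})

test_that("load/save round-trips are the identity in both formats", {
  m <- make_toy_gem(seed = 11)$model
  for (ext in c(".json", ".xml")) {
    path <- withr::local_tempfile(fileext = ext)
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_identical(m2$reactions$gpr, m$reactions$gpr, label = ext)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_identical(m2$reactions$subsystem, m$reactions$subsystem)
    expect_identical(m2$genes, m$genes)
    expect_identical(m2$objective, m$objective)
    expect_equal(m2$stoichiometry[m$reactions$id],
                 m$stoichiometry[m$reactions$id])
    expect_identical(m2$metabolites$id, m$metabolites$id)
  }
})

test_that("empty GPRs round-trip as empty strings, not literal 'None'", {
  m <- chain_model()
  for (ext in c(".json", ".xml")) {
    path <- withr::local_tempfile(fileext = ext)
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(m2$reactions$gpr[m2$reactions$id == "EX_A"], "")
  }
})

test_that("JSON reactions without bounds get convention defaults", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "mini", "objective": "r2",
    "metabolites": [{"id": "A", "compartment": "c"}],
    "reactions": [
      {"id": "r1", "metabolites": {"A": 1}},
      {"id": "r2", "metabolites": {"A": -1}, "reversible": true}
    ]}', path)
  m <- load_model(path)
  expect_equal(m$reactions$lower_bound, c(0, -1000))
  expect_equal(m$reactions$upper_bound, c(1000, 1000))
  expect_identical(unique(m$reactions$subsystem), "unassigned")
})

test_that("unparseable and objective-less files give distinct errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", p)
  expect_error(load_model(p), "unparseable")
  writeLines('{
    "metabolites": [{"id": "A"}],
    "reactions": [{"id": "r1", "metabolites": {"A": 1}}]}', p)
  expect_error(load_model(p), "no objective")
  expect_error(load_model("does/not/exist.json"), "not found")
})

test_that("stoichiometric matrix agrees with per-reaction maps", {
  m <- make_toy_gem(seed = 3)$model
  S <- stoichiometric_matrix(m)
  expect_identical(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  for (r in m$reactions$id) {
    sto <- m$stoichiometry[[r]]
    expect_equal(unname(S[names(sto), r]), unname(sto))
    expect_true(all(S[setdiff(rownames(S), names(sto)), r] == 0))
  }
  # exchange column has a single entry
  expect_equal(sum(S[, "EX_substrate"] != 0), 1)
})
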