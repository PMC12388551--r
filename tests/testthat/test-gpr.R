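test_that("parsing respects precedence and handles empty rules", {
  e <- parse_gpr("g1 and (g2 or g3)")
  expect_equal(e$kind, "and")
  expect_equal(e$children[[2]]$kind, "or")
  expect_equal(parse_gpr("")$kind, "empty")
  expect_equal(parse_gpr("   ")$kind, "empty")
  expect_equal(parse_gpr(NA_character_)$kind, "empty")
  # AND binds tighter than OR
  e2 <- parse_gpr("g1 or g2 and g3")
  expect_equal(e2$kind, "or")
  expect_equal(e2$children[[2]]$kind, "and")
  # case-insensitive operators and symbol forms
  expect_equal(deparse_gpr(parse_gpr("g1 AND g2")), "g1 and g2")
  expect_equal(deparse_gpr(parse_gpr("g1 & g2 | g3")), "g1 and g2 or g3")
})

test_that("malformed rules raise parse errors", {
  expect_error(parse_gpr("g1 and or g2"), "parse error")
  expect_error(parse_gpr("(g1 and g2"), "parenthes")
  expect_error(parse_gpr("g1 and"), "dangling|parse error")
  expect_error(parse_gpr("g1 g2)"), "parse error")
})

test_that("parse -> deparse -> parse is idempotent on canonical strings", {
  for (s in c("g1", "g1 and g2", "g1 or g2 or g3", "g1 and (g2 or g3)",
              "(g1 or g2) and (g3 or g4)", "g1 and g2 and g3")) {
    once <- deparse_gpr(parse_gpr(s))
    twice <- deparse_gpr(parse_gpr(once))
    expect_identical(once, twice)
    expect_identical(once, s)
  }
})

# recursive reference evaluator, deliberately separate from the package's
recursive_eval <- function(expr, levels) {
  if (expr$kind == "empty") return(0L)
  if (expr$kind == "gene") {
    v <- levels[expr$gene]
    return(if (is.na(v)) 0L else as.integer(v))
  }
  vals <- vapply(expr$children, recursive_eval, integer(1), levels = levels)
  if (expr$kind == "and") min(vals) else max(vals)
}

random_gpr <- function(genes) {
  if (length(genes) == 1) return(genes)
  k <- sample(seq_len(length(genes) - 1), 1)
  left <- random_gpr(genes[seq_len(k)])
  right <- random_gpr(genes[-seq_len(k)])
  op <- sample(c("and", "or"), 1)
  sprintf("(%s %s %s)", left, op, right)
}

test_that("tri-state evaluation matches exhaustive enumeration on small trees", {
  set.seed(101)
  for (rep in 1:25) {
    ng <- sample(2:4, 1)
    genes <- sprintf("g%d", seq_len(ng))
    expr <- parse_gpr(random_gpr(sample(genes)))
    grid <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), ng)))
    colnames(grid) <- genes
    for (i in seq_len(nrow(grid))) {
      lv <- grid[i, ]
      expect_identical(evaluate_tristate(expr, lv), recursive_eval(expr, lv))
    }
  }
})

test_that("tri-state evaluation is monotone in every gene level", {
  set.seed(202)
  for (rep in 1:10) {
    ng <- sample(2:4, 1)
    genes <- sprintf("g%d", seq_len(ng))
    expr <- parse_gpr(random_gpr(sample(genes)))
    grid <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), ng)))
    colnames(grid) <- genes
    for (i in seq_len(nrow(grid))) {
      lv <- grid[i, ]
      base <- evaluate_tristate(expr, lv)
      for (g in genes) {
        if (lv[g] < 1L) {
          up <- lv; up[g] <- up[g] + 1L
          expect_gte(evaluate_tristate(expr, up), base)
        }
      }
    }
  }
})

test_that("boolean evaluation agrees with thresholded tri-state", {
  set.seed(303)
  expect_true(evaluate_boolean(parse_gpr("g1 or g2"), "g2"))
  expect_false(evaluate_boolean(parse_gpr("g1 and g2"), "g1"))
  expect_true(evaluate_boolean(parse_gpr(""), character(0)))
  for (rep in 1:20) {
    ng <- sample(2:4, 1)
    genes <- sprintf("g%d", seq_len(ng))
    expr <- parse_gpr(random_gpr(sample(genes)))
    for (mask in seq_len(2^ng) - 1L) {
      present <- genes[as.logical(bitwAnd(mask, 2^(seq_len(ng) - 1L)))]
      lv <- stats::setNames(ifelse(genes %in% present, 1L, -1L), genes)
      expect_identical(evaluate_boolean(expr, present),
                       evaluate_tristate(expr, lv) > 0L)
    }
  }
})

test_that("missing genes evaluate as moderate, not off", {
  expect_identical(evaluate_tristate(parse_gpr("unknown"), c(g1 = 1L)), 0L)
  expect_identical(
    evaluate_tristate(parse_gpr("g1 and unknown"), c(g1 = 1L)), 0L)
})

test_that("knockouts close exactly the reactions whose GPR fails", {
  m <- chain_model()
  km <- apply_knockout(m, "g1")
  expect_equal(km$reactions$upper_bound[km$reactions$id == "R1"], 0)
  expect_equal(km$reactions$lower_bound[km$reactions$id == "R1"], 0)
  # empty-GPR reactions untouched
  expect_equal(km$reactions$upper_bound[km$reactions$id == "EX_A"], 10)
  # isozyme survives a single deletion
  pm <- parallel_model()
  kp <- apply_knockout(pm, "g1")
  expect_equal(kp$reactions$upper_bound[kp$reactions$id == "P2"], 1000)
  expect_warning(apply_knockout(m, "not_a_gene"), "unknown gene")
})

test_that("deleting the only biomass-feeding pathway drives FBA to zero", {
  tg <- make_toy_gem(n_subsystems = 1, seed = 5)
  expect_gt(fba(tg$model)$objective_value, 0)
  km <- apply_knockout(tg$model, tg$truth$pathway_01$genes)
  expect_equal(fba(km)$objective_value, 0, tolerance = 1e-9)
})
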