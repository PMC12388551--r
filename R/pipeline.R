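#' Assemble and validate a pipeline configuration
#'
#' Thresholds default to the analysis' standard settings: |log2FC| > 0.25
#' with BH-adjusted p < 0.05 for differential expression, a 1e-6 flux
#' inactivity threshold, iMAT activation flux eps = 1 with big-M 1000,
#' (0.25, 0.75) discretization quantiles, 1000 flux samples, and raw p <
#' 0.05 for subsystem calls.
#'
#' @param model a `metabolic_model` or path to an SBML/JSON model file.
#' @param counts genes x samples count matrix or path to a counts TSV.
#' @param metadata data.frame (sample, group, ...) or path to a metadata
#'   TSV; `sample` must match the count columns.
#' @param control control group label (must appear in the metadata).
#' @param seed integer seed driving every stochastic stage.
#' @param lfc_threshold,alpha DEG thresholds.
#' @param flux_tol inactivity threshold (mmol/gDW/h).
#' @param imat_eps,big_m iMAT parameters.
#' @param n_samples flux samples per context model (when
#'   `flux_source = "sampling"`).
#' @param q_low,q_high discretization quantiles.
#' @param discretize_by `"gene"` (relative expression across samples,
#'   default) or `"sample"`; see [discretize()].
#' @param use_abs average |flux| in subsystem summaries.
#' @param fva_fraction fraction-of-optimum used by FVA summaries.
#' @param flux_source per-sample flux vector fed into subsystem scoring:
#'   `"fba"` (the FBA optimum of the context model, default) or
#'   `"sampling"` (the mean of `n_samples` hit-and-run samples).
#' @param subsystem_alpha significance threshold for subsystem calls
#'   (default 0.05, uncorrected; see [delta_vs_control()]).
#' @param bh_subsystems apply BH across subsystem calls (default `FALSE`).
#' @param test_subsystems `"genic"` (default) tests only subsystems
#'   containing at least one gene-associated reaction; boundary and
#'   pseudo-reaction groups carry no transcriptomic evidence and are
#'   reported in the means table only. `"all"` tests everything.
#' @param out_dir optional output directory for report files.
#' @return validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(model, counts, metadata, control, seed = 1,
                            lfc_threshold = 0.25, alpha = 0.05,
                            flux_tol = 1e-6, imat_eps = 1.0, big_m = 1000,
                            n_samples = 1000, q_low = 0.25, q_high = 0.75,
                            discretize_by = c("gene", "sample"),
                            use_abs = TRUE, fva_fraction = 1.0,
                            flux_source = c("fba", "sampling"),
                            subsystem_alpha = 0.05, bh_subsystems = FALSE,
                            test_subsystems = c("genic", "all"),
                            out_dir = NULL) {
  flux_source <- match.arg(flux_source)
  discretize_by <- match.arg(discretize_by)
  test_subsystems <- match.arg(test_subsystems)
  if (is.character(model)) model <- load_model(model)
  if (is.character(counts)) counts <- read_counts_tsv(counts)
  if (is.character(metadata))
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  stopifnot(inherits(model, "metabolic_model"),
            lfc_threshold > 0, alpha > 0, flux_tol > 0, imat_eps > 0,
            big_m > 0, n_samples >= 1, q_low < q_high)
  counts <- as.matrix(counts)
  if (!all(c("sample", "group") %in% names(metadata)))
    stop("metadata needs 'sample' and 'group' columns")
  if (!setequal(metadata$sample, colnames(counts)))
    stop("metadata samples and count columns do not match")
  if (!control %in% metadata$group)
    stop("control group label '", control, "' not present in the metadata")
  if (sum(metadata$group == control) < 2)
    stop("control group needs >= 2 samples")
  structure(list(model = model, counts = counts, metadata = metadata,
                 control = control, seed = as.integer(seed),
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 flux_tol = flux_tol, imat_eps = imat_eps, big_m = big_m,
                 n_samples = n_samples, q_low = q_low, q_high = q_high,
                 discretize_by = discretize_by,
                 use_abs = use_abs, fva_fraction = fva_fraction,
                 flux_source = flux_source,
                 subsystem_alpha = subsystem_alpha,
                 bh_subsystems = bh_subsystems,
                 test_subsystems = test_subsystems, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the transcriptome-to-flux pipeline
#'
#' Stage chain: size-factor normalization, per-contrast NB Wald differential
#' expression with BH correction, per-sample tri-state discretization, GPR
#' mapping and iMAT integration into per-sample context-specific models,
#' context-model flux characterization (FBA, optionally hit-and-run
#' sampling), subsystem mean-flux aggregation, and differencing/testing
#' against the control group. Fully deterministic under a fixed config seed.
#'
#' @param config a `pipeline_config`.
#' @return object of class `pipeline_report`: list with `de` (per-contrast
#'   DEG tables and up/down sets), `context_summary` (per-sample model
#'   sizes, iMAT objectives, biomass fluxes), `subsystem_table`
#'   (`subsystem_flux`), `delta_table`, `rescaled` (biproportionally
#'   rescaled subsystem x group matrix, or NULL), and `params`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- config$model
  counts <- config$counts
  meta <- config$metadata
  samples <- colnames(counts)
  meta <- meta[match(samples, meta$sample), , drop = FALSE]
  groups <- stats::setNames(meta$group, meta$sample)

  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)

  contrasts <- setdiff(unique(meta$group), config$control)
  de <- lapply(stats::setNames(contrasts, contrasts), function(g) {
    res <- nb_wald_test(counts, groups, config$control, g,
                        lfc_threshold = config$lfc_threshold,
                        alpha = config$alpha)
    c(list(table = res), call_degs(res, config$lfc_threshold, config$alpha))
  })

  profile <- discretize(norm, config$q_low, config$q_high,
                        by = config$discretize_by)

  subsystem_map <- stats::setNames(model$reactions$subsystem,
                                   model$reactions$id)
  flux_list <- list()
  ctx_rows <- list()
  for (i in seq_along(samples)) {
    sm <- samples[i]
    res <- tryCatch({
      states <- reaction_states(model, profile, sm)
      sol <- imat_optimize(model, states, eps = config$imat_eps,
                           bigM = config$big_m)
      ctx <- extract_context_model(model, sol, min_biomass = config$flux_tol)
      v_fba <- fba(ctx)
      v <- if (config$flux_source == "sampling") {
        smp <- sample_fluxes(ctx, n = config$n_samples,
                             seed = config$seed + i,
                             fraction_of_optimum = config$fva_fraction)
        colMeans(smp$samples)
      } else v_fba$fluxes
      list(v = v, sol = sol, ctx = ctx, biomass = v_fba$objective_value)
    }, error = function(e)
      stop("pipeline stage failed for sample '", sm, "': ",
           conditionMessage(e), call. = FALSE))
    flux_list[[sm]] <- res$v
    ctx_rows[[sm]] <- data.frame(
      sample = sm, group = unname(groups[sm]),
      n_reactions = nrow(res$ctx$reactions),
      n_removed = nrow(model$reactions) - nrow(res$ctx$reactions),
      imat_objective = res$sol$objective,
      biomass_flux = res$biomass, stringsAsFactors = FALSE)
  }
  context_summary <- do.call(rbind, c(ctx_rows, make.row.names = FALSE))

  subsystem_table <- subsystem_means(flux_list, subsystem_map,
                                     use_abs = config$use_abs,
                                     tol = config$flux_tol)
  test_tab <- subsystem_table
  if (config$test_subsystems == "genic") {
    genic <- unique(model$reactions$subsystem[nzchar(model$reactions$gpr)])
    keep <- rownames(test_tab$means) %in% genic
    test_tab$means <- test_tab$means[keep, , drop = FALSE]
    test_tab$n_active <- test_tab$n_active[keep, , drop = FALSE]
  }
  delta_table <- delta_vs_control(test_tab, groups, config$control,
                                  alpha = config$subsystem_alpha,
                                  bh = config$bh_subsystems)

  # group-mean subsystem matrix, rescaled for cross-condition comparability
  gm <- sapply(unique(meta$group), function(g)
    rowMeans(subsystem_table$means[, groups == g, drop = FALSE], na.rm = TRUE))
  gm[is.nan(gm)] <- 0
  rescaled <- tryCatch(
    projective_rescale(gm[rowSums(gm) > 0, colSums(gm) > 0, drop = FALSE]),
    error = function(e) NULL)

  report <- structure(list(
    de = de, context_summary = context_summary,
    subsystem_table = subsystem_table, delta_table = delta_table,
    rescaled = rescaled,
    params = config[setdiff(names(config), c("model", "counts", "metadata"))],
    control = config$control), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  ncalls <- sum(x$delta_table$class != "unchanged")
  cat(sprintf(paste0("<pipeline_report: %d context models, %d contrasts, ",
                     "%d significant subsystem calls>\n"),
              nrow(x$context_summary), length(x$de), ncalls))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' One TSV per table plus a machine-readable `summary.json`; reruns with an
#' identical config produce byte-identical JSON.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (g in names(report$de))
    wt(report$de[[g]]$table, sprintf("de_%s_vs_%s.tsv", g, report$control))
  wt(report$context_summary, "context_models.tsv")
  means <- report$subsystem_table$means
  wt(data.frame(subsystem = rownames(means), means, check.names = FALSE),
     "subsystem_means.tsv")
  wt(report$delta_table, "delta_table.tsv")
  summary <- list(
    n_samples = nrow(report$context_summary),
    contrasts = names(report$de),
    degs = lapply(report$de, function(d)
      list(up = as.list(d$up), down = as.list(d$down))),
    imat_objectives = stats::setNames(
      as.list(report$context_summary$imat_objective),
      report$context_summary$sample),
    significant_subsystems = report$delta_table[
      report$delta_table$class != "unchanged",
      c("subsystem", "group", "delta", "p", "class")],
    params = report$params[c("seed", "lfc_threshold", "alpha", "flux_tol",
                             "imat_eps", "big_m", "n_samples", "q_low",
                             "q_high", "use_abs", "fva_fraction",
                             "flux_source", "subsystem_alpha")])
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           dataframe = "rows", pretty = TRUE, na = "null")
  writeLines(json, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' Score pipeline subsystem calls against simulation truth
#'
#' A subsystem counts as called when any of its exposure-group rows is
#' significant; the call direction is that of its most significant row. A
#' call is correct when the truth lists the subsystem as perturbed and the
#' direction matches the injected effect's sign (positive log2FC ->
#' activated). Subsystems the truth leaves unperturbed count as false
#' positives when called in either direction.
#'
#' @param report a `pipeline_report` (or its `delta_table`).
#' @param truth the `truth` element from [simulate_counts()] (needs
#'   `effects`).
#' @return list with `precision` (NA when nothing was called), `recall`,
#'   `n_called`, `n_correct`, `calls` (per-subsystem call table).
#' @export
score_recovery <- function(report, truth) {
  dt <- if (inherits(report, "pipeline_report")) report$delta_table else report
  known <- unique(dt$subsystem)
  bad <- setdiff(names(truth$effects), known)
  if (length(bad) > 0)
    stop("truth references subsystem(s) absent from the report: ",
         paste(bad, collapse = ", "))
  sig <- dt[dt$class != "unchanged", , drop = FALSE]
  calls <- if (nrow(sig) > 0) {
    do.call(rbind, lapply(split(sig, sig$subsystem), function(d) {
      d <- d[order(d$p), , drop = FALSE]
      data.frame(subsystem = d$subsystem[1], class = d$class[1],
                 p = d$p[1], stringsAsFactors = FALSE)
    }))
  } else data.frame(subsystem = character(0), class = character(0),
                    p = numeric(0), stringsAsFactors = FALSE)
  expected <- ifelse(truth$effects > 0, "activated", "suppressed")
  expected <- expected[truth$effects != 0]
  correct <- calls$subsystem %in% names(expected) &
    calls$class == expected[match(calls$subsystem, names(expected))]
  n_called <- nrow(calls)
  n_correct <- sum(correct)
  list(precision = if (n_called > 0) n_correct / n_called else NA_real_,
       recall = if (length(expected) > 0) n_correct / length(expected) else
         NA_real_,
       n_called = n_called, n_correct = n_correct, calls = calls)
}
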