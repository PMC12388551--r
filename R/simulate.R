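#' Generate a toy genome-scale metabolic model
#'
#' A desk-scale stand-in for a genome-scale reconstruction: a single
#' (non-limiting) substrate exchange feeds `n_subsystems` parallel linear
#' pathways that converge on a biomass precursor consumed by the objective
#' reaction. Each pathway is one subsystem, is capacity-bounded at 10
#' mmol/gDW/h by its entry reaction, and carries GPRs over fresh genes on
#' every internal reaction. The capacity bounds make the biomass optimum
#' `10 * n_intact_pathways`, so each intact pathway saturates at a unique,
#' non-degenerate flux -- pathway usage is identifiable from the FBA
#' solution. The model is always feasible with biomass optimum > 0.
#'
#' @param n_subsystems number of parallel pathways (default 5).
#' @param reactions_per_subsystem reactions per pathway (default 4).
#' @param genes_per_reaction genes per GPR, 1-3 (default 2; combined with a
#'   random `and`/`or`).
#' @param reversible_fraction fraction of internal reactions made reversible
#'   (default 0.2).
#' @param seed integer seed; identical seeds give identical models.
#' @return list with `model` (a `metabolic_model`) and `truth` (per-subsystem
#'   gene and reaction membership, sufficient to score pipeline calls).
#' @export
make_toy_gem <- function(n_subsystems = 5, reactions_per_subsystem = 4,
                         genes_per_reaction = 2, reversible_fraction = 0.2,
                         seed = 1) {
  stopifnot(n_subsystems >= 1, reactions_per_subsystem >= 1,
            genes_per_reaction >= 1, genes_per_reaction <= 3,
            reversible_fraction >= 0, reversible_fraction <= 1)
  with_local_seed(seed, {
    mets <- data.frame(id = c("substrate_c", "precursor_c"),
                       name = c("substrate", "biomass precursor"),
                       compartment = "c", stringsAsFactors = FALSE)
    rxns <- list(data.frame(
      id = "EX_substrate", name = "substrate exchange",
      lower_bound = 0, upper_bound = 1000,
      subsystem = "boundary", gpr = "", stringsAsFactors = FALSE))
    sto <- list(EX_substrate = c(substrate_c = 1))
    truth <- list()
    for (k in seq_len(n_subsystems)) {
      ss <- sprintf("pathway_%02d", k)
      chain <- c("substrate_c",
                 if (reactions_per_subsystem > 1)
                   sprintf("p%02d_m%d_c", k, seq_len(reactions_per_subsystem - 1)),
                 "precursor_c")
      new_mets <- setdiff(chain, mets$id)
      if (length(new_mets) > 0)
        mets <- rbind(mets, data.frame(id = new_mets, name = new_mets,
                                       compartment = "c",
                                       stringsAsFactors = FALSE))
      ss_genes <- character(0); ss_rxns <- character(0)
      for (j in seq_len(reactions_per_subsystem)) {
        rid <- sprintf("P%02d_R%d", k, j)
        genes <- sprintf("g_P%02d_R%d_%d", k, j, seq_len(genes_per_reaction))
        op <- if (genes_per_reaction > 1) sample(c(" and ", " or "), 1) else ""
        gpr <- paste(genes, collapse = op)
        rev <- stats::runif(1) < reversible_fraction
        cap <- if (j == 1) 10 else 1000  # entry reaction caps pathway flux
        rxns[[length(rxns) + 1L]] <- data.frame(
          id = rid, name = rid,
          lower_bound = if (rev) -cap else 0, upper_bound = cap,
          subsystem = ss, gpr = gpr, stringsAsFactors = FALSE)
        sto[[rid]] <- stats::setNames(c(-1, 1), c(chain[j], chain[j + 1]))
        ss_genes <- c(ss_genes, genes); ss_rxns <- c(ss_rxns, rid)
      }
      truth[[ss]] <- list(genes = ss_genes, reactions = ss_rxns)
    }
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = "BIOMASS", name = "biomass sink",
      lower_bound = 0, upper_bound = 1000,
      subsystem = "biomass", gpr = "", stringsAsFactors = FALSE)
    sto$BIOMASS <- c(precursor_c = -1)
    model <- metabolic_model(mets, do.call(rbind, rxns), sto, "BIOMASS",
                             id = sprintf("toy_gem_s%d", seed))
    list(model = model, truth = truth)
  })
}

#' Simulate negative-binomial RNA-seq counts with subsystem perturbations
#'
#' Emulates a multi-dose exposure design: replicate animals per group,
#' log-normal baseline expression, negative-binomial counts with
#' gene-independent dispersion, and condition-dependent fold changes
#' injected only into the genes of chosen subsystems (scaled per group to
#' mimic dose response). The control group (first in `groups`) always has
#' zero effect.
#'
#' @param genes character vector of gene ids (the model's genes).
#' @param gene_subsystems named character vector, gene -> subsystem (genes
#'   absent from it never receive an effect).
#' @param groups ordered group labels, control first.
#' @param n_per_group replicate animals per group (>= 2, default 5).
#' @param effects named numeric, subsystem -> log2 fold change at reference
#'   dose scaling 1.
#' @param dose_scaling named numeric multiplier per group (default: 0 for
#'   the control group, 1 elsewhere); per-gene lfc in group g is
#'   `effects[subsystem] * dose_scaling[g]`.
#' @param doses optional named numeric dose (mg/kg) per group for the
#'   metadata (default 0, 1, 2, ...).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean
#'   parameters (defaults 5 and 1.5, mimicking the dynamic range of bulk
#'   liver RNA-seq).
#' @param dispersion NB dispersion alpha (default 0.1); `Var = mu + alpha mu^2`.
#' @param libsize_sdlog log-normal sd of the per-sample depth factor
#'   (default 0.1).
#' @param n_background unperturbed non-model "background" transcriptome
#'   genes (ids `bg_...`) included in the matrix (default 500). Real count
#'   matrices are normalized genome-wide before subsetting to metabolic
#'   genes; without background genes, a perturbed subsystem is a large
#'   fraction of the panel and composition bias distorts size factors and
#'   discretization thresholds.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return list with `counts` (genes x samples integer matrix), `metadata`
#'   (data.frame: sample, group, dose, sex, genotype), and `truth`
#'   (`perturbed_subsystems`, per-gene `lfc_ref`, per-group `dose_scaling`).
#' @export
simulate_counts <- function(genes, gene_subsystems, groups,
                            n_per_group = 5, effects = numeric(0),
                            dose_scaling = NULL, doses = NULL,
                            baseline_meanlog = 5, baseline_sdlog = 1.5,
                            dispersion = 0.1, libsize_sdlog = 0.1,
                            n_background = 500, seed = 1) {
  stopifnot(n_per_group >= 2, dispersion > 0, length(groups) >= 1,
            !anyDuplicated(groups), n_background >= 0)
  if (n_background > 0)
    genes <- c(genes, sprintf("bg_%04d", seq_len(n_background)))
  if (is.null(dose_scaling))
    dose_scaling <- stats::setNames(c(0, rep(1, length(groups) - 1)), groups)
  stopifnot(setequal(names(dose_scaling), groups))
  if (abs(dose_scaling[[groups[1]]]) > 0)
    stop("the control group (first in 'groups') must have zero dose scaling")
  if (is.null(doses))
    doses <- stats::setNames(seq_along(groups) - 1, groups)

  lfc_ref <- stats::setNames(rep(0, length(genes)), genes)
  in_eff <- names(gene_subsystems)[gene_subsystems %in% names(effects)]
  lfc_ref[intersect(genes, in_eff)] <-
    unname(effects[gene_subsystems[intersect(genes, in_eff)]])

  with_local_seed(seed, {
    base <- stats::setNames(stats::rlnorm(length(genes), baseline_meanlog,
                                          baseline_sdlog), genes)
    samples <- as.vector(t(outer(groups, seq_len(n_per_group),
                                 function(g, r) sprintf("%s_rep%d", g, r))))
    grp <- rep(groups, each = n_per_group)
    sf <- stats::rlnorm(length(samples), 0, libsize_sdlog)
    counts <- matrix(0L, length(genes), length(samples),
                     dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      lfc_j <- lfc_ref * dose_scaling[[grp[j]]]
      mu <- sf[j] * base * 2^lfc_j
      counts[, j] <- stats::rnbinom(length(genes), mu = mu,
                                    size = 1 / dispersion)
    }
    metadata <- data.frame(
      sample = samples, group = grp,
      dose = unname(doses[grp]),
      sex = rep(c("F", "M"), length.out = length(samples)),
      genotype = "WT", stringsAsFactors = FALSE)
    truth <- list(
      perturbed_subsystems = names(effects)[effects != 0],
      effects = effects,
      lfc_ref = lfc_ref,
      dose_scaling = dose_scaling)
    list(counts = counts, metadata = metadata, truth = truth)
  })
}
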