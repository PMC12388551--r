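#!/usr/bin/env Rscript
# Stage 1: build the study inputs.
#
# A toy genome-scale model (5 parallel pathways = 5 subsystems, 4 reactions
# each) and a multi-dose exposure count matrix: control + three dose groups,
# 5 animals each, with a log2FC = 2 perturbation injected into the genes of
# pathway_03 (half-strength at the lowest dose). This mirrors a multi-dose
# liver RNA-seq design: replicate animals, negative-binomial counts, and
# condition-dependent fold changes concentrated in one subsystem.

suppressMessages(library(contextflux))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tg <- make_toy_gem(n_subsystems = 5, reactions_per_subsystem = 4, seed = seed)
print(tg$model)
save_model(tg$model, file.path(out, "toy_gem.json"))
save_model(tg$model, file.path(out, "toy_gem.xml"))

gene_ss <- unlist(lapply(names(tg$truth), function(s)
  stats::setNames(rep(s, length(tg$truth[[s]]$genes)), tg$truth[[s]]$genes)))

groups <- c("control", "dose1", "dose2", "dose3")
sim <- simulate_counts(
  tg$model$genes, gene_ss, groups = groups, n_per_group = 5,
  effects = c(pathway_03 = 2),
  dose_scaling = stats::setNames(c(0, 0.5, 1, 1), groups),
  doses = stats::setNames(c(0, 0.03, 0.3, 3.0), groups),
  seed = seed + 100)

write_counts_tsv(sim$counts, file.path(out, "counts.tsv"))
write.table(sim$metadata, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(perturbed_subsystems = sim$truth$perturbed_subsystems,
       effects = as.list(sim$truth$effects),
       dose_scaling = as.list(sim$truth$dose_scaling),
       lfc_ref = as.list(sim$truth$lfc_ref[sim$truth$lfc_ref != 0])),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote model (%d reactions), counts (%d genes x %d samples), truth\n",
            nrow(tg$model$reactions), nrow(sim$counts), ncol(sim$counts)))
cat("perturbed subsystem:", sim$truth$perturbed_subsystems, "\n")
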