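#!/usr/bin/env Rscript
# Stage 5: subsystem-level differential flux and recovery scoring.
#
# Per-sample FBA fluxes are aggregated into subsystem mean |flux| (inactive
# reactions excluded at the 1e-6 threshold), differenced against the
# control group, tested with unpaired two-tailed t-tests, and classified
# activated/suppressed at p < 0.05. The biproportionally rescaled
# subsystem x group matrix is written for cross-condition comparison, and
# the calls are scored against the simulation truth.

suppressMessages(library(contextflux))

meta <- read.delim("results/data/metadata.tsv", stringsAsFactors = FALSE)
model <- load_model("results/data/toy_gem.json")
truth <- jsonlite::fromJSON("results/data/truth.json")
out <- "results/subsystems"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

flux_list <- lapply(stats::setNames(meta$sample, meta$sample), function(sm) {
  tab <- read.delim(sprintf("results/flux/%s_flux.tsv", sm))
  stats::setNames(tab$fba_flux, tab$reaction)
})
subsystem_map <- stats::setNames(model$reactions$subsystem,
                                 model$reactions$id)
tab <- subsystem_means(flux_list, subsystem_map)
write.table(data.frame(subsystem = rownames(tab$means), tab$means,
                       check.names = FALSE),
            file.path(out, "subsystem_means.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

groups <- stats::setNames(meta$group, meta$sample)
genic <- unique(model$reactions$subsystem[nzchar(model$reactions$gpr)])
keep <- rownames(tab$means) %in% genic
tab$means <- tab$means[keep, , drop = FALSE]
tab$n_active <- tab$n_active[keep, , drop = FALSE]
dt <- delta_vs_control(tab, groups, "control")
write.table(dt, file.path(out, "delta_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(dt, digits = 4)

gm <- sapply(unique(meta$group), function(g)
  rowMeans(tab$means[, groups == g, drop = FALSE], na.rm = TRUE))
gm[is.nan(gm)] <- 0
ok <- rowSums(gm) > 0
if (any(ok)) {
  rs <- projective_rescale(gm[ok, , drop = FALSE])
  write.table(data.frame(subsystem = rownames(rs$rescaled), rs$rescaled,
                         check.names = FALSE),
              file.path(out, "subsystem_rescaled.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

sc <- score_recovery(dt, list(effects = unlist(truth$effects)))
cat(sprintf("\nrecovery vs truth: recall %.2f, precision %s (%d called, %d correct)\n",
            sc$recall,
            ifelse(is.na(sc$precision), "NA", sprintf("%.2f", sc$precision)),
            sc$n_called, sc$n_correct))
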