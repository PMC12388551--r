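#!/usr/bin/env Rscript
# Stage 2: differential expression, one contrast per dose group vs control.
#
# NB Wald test on median-of-ratios-normalized counts, BH correction, and the
# standard DEG thresholds (|log2FC| > 0.25, adjusted p < 0.05), followed by
# hypergeometric over-representation of the per-subsystem gene sets.

suppressMessages(library(contextflux))

counts <- read_counts_tsv("results/data/counts.tsv")
meta <- read.delim("results/data/metadata.tsv", stringsAsFactors = FALSE)
model <- load_model("results/data/toy_gem.json")
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups <- stats::setNames(meta$group, meta$sample)[colnames(counts)]
gene_sets <- lapply(
  split(model$reactions$gpr, model$reactions$subsystem),
  function(g) unique(unlist(lapply(g, function(x) gpr_genes(parse_gpr(x))))))
gene_sets <- gene_sets[lengths(gene_sets) > 0]

for (g in setdiff(unique(groups), "control")) {
  res <- nb_wald_test(counts, groups, "control", g)
  deg <- call_degs(res)
  write.table(res, file.path(out, sprintf("de_%s_vs_control.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s vs control: %d up, %d down (of %d genes)\n",
              g, length(deg$up), length(deg$down), nrow(res)))
  hits <- c(deg$up, deg$down)
  if (length(hits) > 0) {
    ora <- ora_hypergeometric(hits, gene_sets, rownames(counts))
    write.table(ora, file.path(out, sprintf("ora_%s_vs_control.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    top <- ora[which.min(ora$p), ]
    cat(sprintf("  top enriched subsystem: %s (overlap %d, padj %.3g)\n",
                top$set, top$overlap, top$padj))
  }
}
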