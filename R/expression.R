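#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against a geometric-mean
#' reference profile: genes with a zero count in any sample are excluded from
#' the reference, and each sample's factor is the median of its count ratios
#' to the reference.
#'
#' @param counts genes x samples matrix of non-negative raw counts.
#' @return positive numeric vector of per-sample factors (named if `counts`
#'   has column names); normalized counts are `counts / factor`.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  qual <- rowSums(counts > 0) == ncol(counts)
  if (!any(qual))
    stop("no gene has strictly positive counts in every sample; ",
         "median-of-ratios size factors are undefined ",
         "(pseudo-reference fallback is not provided)")
  ref <- exp(rowMeans(log(counts[qual, , drop = FALSE])))
  sf <- apply(counts[qual, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#' @param counts genes x samples count matrix.
#' @param sf size factors from [size_factors()] (recomputed when `NULL`).
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  sf <- sf %||% size_factors(counts)
  sweep(as.matrix(counts), 2, sf, "/")
}

#' Negative-binomial Wald differential-expression test
#'
#' A deliberately simple NB Wald test: counts are normalized by
#' median-of-ratios size factors, per-gene log2 fold changes are computed
#' from group means with a 0.5 pseudocount, gene-wise dispersion is
#' estimated by the method of moments (floored at 1e-8, no shrinkage), the
#' standard error of the log2 fold change comes from the delta method, and
#' the p-value is the two-sided normal tail of the Wald statistic. There is
#' no Cook's-distance filtering or independent filtering.
#'
#' @param counts genes x samples matrix of raw counts.
#' @param groups factor/character vector of group labels, one per column.
#' @param reference label of the reference (control) group.
#' @param test label of the test group.
#' @param lfc_threshold,alpha thresholds used to fill the `call` column
#'   (|log2FC| > 0.25 and BH-adjusted p < 0.05 by default).
#' @return data.frame with one row per gene: `gene`, `base_mean`, `log2fc`
#'   (test vs reference), `se`, `p`, `padj`, `call` in `up`/`down`/`ns`.
#' @export
nb_wald_test <- function(counts, groups, reference, test,
                         lfc_threshold = 0.25, alpha = 0.05) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  ir <- which(groups == reference)
  it <- which(groups == test)
  if (length(ir) < 2 || length(it) < 2)
    stop("both groups need >= 2 samples (reference: ", length(ir),
         ", test: ", length(it), ")")
  keep <- c(ir, it)
  sf <- size_factors(counts[, keep, drop = FALSE])
  y <- sweep(counts[, keep, drop = FALSE], 2, sf, "/")
  ir2 <- seq_along(ir)
  it2 <- length(ir) + seq_along(it)

  mean_r <- rowMeans(y[, ir2, drop = FALSE])
  mean_t <- rowMeans(y[, it2, drop = FALSE])
  var_r <- apply(y[, ir2, drop = FALSE], 1, stats::var)
  var_t <- apply(y[, it2, drop = FALSE], 1, stats::var)

  # method-of-moments NB dispersion pooled over both groups:
  # within-group Var(y) ~ mu + alpha mu^2  =>  alpha = (s2 - mu) / mu^2
  nr <- length(ir); nt <- length(it)
  num <- (nr - 1) * (var_r - mean_r) + (nt - 1) * (var_t - mean_t)
  den <- (nr - 1) * mean_r^2 + (nt - 1) * mean_t^2
  disp <- ifelse(den > 0, num / den, 0)
  disp <- pmax(disp, 1e-8)

  pc <- 0.5
  log2fc <- log2((mean_t + pc) / (mean_r + pc))

  # delta method on log2 of group means; Var(count_ij / sf_j) =
  # (mu_ij + alpha mu_ij^2) / sf_j^2 with mu_ij = sf_j q_g
  v_group <- function(q, idx_sf) {
    sapply(seq_along(q), function(i)
      sum(q[i] / sf[idx_sf] + disp[i] * q[i]^2) / length(idx_sf)^2)
  }
  var_mean_r <- v_group(mean_r, ir2)
  var_mean_t <- v_group(mean_t, it2)
  se <- sqrt((var_mean_t / (mean_t + pc)^2 + var_mean_r / (mean_r + pc)^2)) /
    log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0 | log2fc != 0, 2 * stats::pnorm(-abs(z)), 1)
  p[se == 0 & log2fc != 0] <- 0
  padj <- bh_adjust(p)

  res <- data.frame(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = (mean_r * nr + mean_t * nt) / (nr + nt),
    log2fc = log2fc, se = se, p = p, padj = padj,
    stringsAsFactors = FALSE)
  res$call <- ifelse(res$padj < alpha & res$log2fc > lfc_threshold, "up",
              ifelse(res$padj < alpha & res$log2fc < -lfc_threshold, "down",
                     "ns"))
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (capped at 1, order preserving).
#' Thin validating wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] and contain no NA")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is `up` iff log2FC exceeds the threshold with BH-adjusted p below
#' alpha, `down` for the mirrored condition (strict inequalities).
#'
#' @param results data.frame from [nb_wald_test()] (needs `gene`, `log2fc`,
#'   `padj`).
#' @param lfc_threshold absolute log2 fold-change threshold (default 0.25).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
call_degs <- function(results, lfc_threshold = 0.25, alpha = 0.05) {
  sig <- results$padj < alpha
  list(up = results$gene[sig & results$log2fc > lfc_threshold],
       down = results$gene[sig & results$log2fc < -lfc_threshold])
}

#' Discretize expression into tri-state levels
#'
#' With `by = "gene"` (default), each gene is discretized against its own
#' distribution across samples: +1 (high) strictly above the gene's `q_high`
#' quantile, -1 (low) strictly below its `q_low` quantile, else 0. This is
#' the relative-expression reading of the iMAT input -- a gene is "highly
#' expressed" in the contexts where it runs above its typical level -- and
#' it is what lets condition contrasts reach the flux side.
#'
#' With `by = "sample"`, quantiles are taken across genes within each
#' sample instead (absolute expression tiers within a transcriptome).
#' Values tied with a threshold are moderate in both modes; degenerate
#' distributions (all values equal) yield all zeros with a warning.
#'
#' @param norm_counts genes x samples matrix of normalized expression.
#' @param q_low,q_high quantile cutpoints (defaults 0.25 and 0.75).
#' @param by `"gene"` (per gene across samples, default) or `"sample"`
#'   (per sample across genes).
#' @return integer matrix (genes x samples) with values in `{-1, 0, 1}`.
#' @export
discretize <- function(norm_counts, q_low = 0.25, q_high = 0.75,
                       by = c("gene", "sample")) {
  stopifnot(q_low < q_high)
  by <- match.arg(by)
  x <- as.matrix(norm_counts)
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  tri <- function(v, what) {
    qs <- stats::quantile(v, c(q_low, q_high), names = FALSE)
    if (qs[1] == qs[2]) {
      if (stats::var(v) == 0)
        warning(what, " has a degenerate expression distribution; ",
                "all levels set to 0")
      return(ifelse(v > qs[2], 1L, ifelse(v < qs[1], -1L, 0L)))
    }
    ifelse(v > qs[2], 1L, ifelse(v < qs[1], -1L, 0L))
  }
  if (by == "sample") {
    for (j in seq_len(ncol(x)))
      out[, j] <- tri(x[, j], paste("sample", colnames(x)[j] %||% j))
  } else {
    for (i in seq_len(nrow(x)))
      out[i, ] <- tri(x[i, ], paste("gene", rownames(x)[i] %||% i))
  }
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and each
#' named gene set, with BH correction across sets. A generic
#' over-representation test against user-supplied gene sets.
#'
#' @param deg character vector of hit genes (must be within `universe`).
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all testable genes.
#' @return data.frame with `set`, `size` (set within universe), `overlap`,
#'   `p`, `padj`, ordered as `gene_sets`.
#' @export
ora_hypergeometric <- function(deg, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  deg <- unique(deg)
  if (!all(deg %in% universe))
    stop("all hit genes must be contained in the universe")
  N <- length(universe)
  n <- length(deg)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    q <- length(intersect(deg, set))
    p <- if (q == 0) 1 else stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, size = K, overlap = q, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
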