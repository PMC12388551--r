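#' Subsystem-level mean fluxes per sample model
#'
#' Groups each sample's reaction fluxes by subsystem and averages over the
#' reactions that carry flux (|flux| >= `tol`; reactions below the 1e-6
#' inactivity threshold are excluded from the analysis). Cells whose
#' subsystem has no active reaction in a sample are `NA` (missing, not
#' zero).
#'
#' @param flux_list named list (by sample) of named flux vectors, each from
#'   a context model whose reactions map into `subsystem_map`.
#' @param subsystem_map named character vector, reaction id -> subsystem
#'   label (normally from the parent model).
#' @param use_abs average |flux| (default) rather than signed flux; signed
#'   means cancel across reversible reactions, so magnitude is the default
#'   reading of pathway usage.
#' @param tol inactivity threshold (default 1e-6).
#' @return object of class `subsystem_flux`: list with `means` (subsystem x
#'   sample matrix, `NA` = missing) and `n_active` (contributing reaction
#'   counts).
#' @export
subsystem_means <- function(flux_list, subsystem_map, use_abs = TRUE,
                            tol = 1e-6) {
  stopifnot(length(flux_list) > 0, !is.null(names(subsystem_map)))
  subsystems <- sort(unique(unname(subsystem_map)))
  samples <- names(flux_list) %||% as.character(seq_along(flux_list))
  means <- matrix(NA_real_, length(subsystems), length(flux_list),
                  dimnames = list(subsystems, samples))
  n_active <- matrix(0L, length(subsystems), length(flux_list),
                     dimnames = list(subsystems, samples))
  for (j in seq_along(flux_list)) {
    v <- flux_list[[j]]
    if (inherits(v, "flux_vector")) v <- v$fluxes
    unknown <- setdiff(names(v), names(subsystem_map))
    if (length(unknown) > 0)
      stop("flux vector ", samples[j], " has reaction(s) without a ",
           "subsystem: ", paste(unknown, collapse = ", "))
    act <- abs(v) >= tol
    if (!any(act)) next
    vals <- if (use_abs) abs(v[act]) else v[act]
    ss <- subsystem_map[names(v)[act]]
    agg <- tapply(vals, ss, mean)
    cnt <- tapply(vals, ss, length)
    means[names(agg), j] <- agg
    n_active[names(cnt), j] <- as.integer(cnt)
  }
  structure(list(means = means, n_active = n_active, use_abs = use_abs,
                 tol = tol), class = "subsystem_flux")
}

#' Unpaired two-tailed pooled-variance t-test
#'
#' Student's t-test with pooled variance. When both samples are constant and
#' equal the p-value is 1 by convention (no evidence of difference); constant
#' but different samples give p = 0.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @return two-tailed p-value.
#' @export
ttest_two_tailed <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need >= 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Classify subsystem flux changes
#'
#' `activated` iff the mean difference versus control is positive with
#' p < alpha; `suppressed` iff negative with p < alpha; `unchanged`
#' otherwise (including zero deltas and untestable `NA` p-values).
#'
#' @param delta numeric vector of mean differences (exposed - control).
#' @param p numeric vector of t-test p-values (may contain `NA`).
#' @param alpha significance threshold (default 0.05, uncorrected).
#' @return character vector over `activated`/`suppressed`/`unchanged`.
#' @export
classify <- function(delta, p, alpha = 0.05) {
  sig <- !is.na(p) & p < alpha & !is.na(delta)
  ifelse(sig & delta > 0, "activated",
         ifelse(sig & delta < 0, "suppressed", "unchanged"))
}

#' Subsystem flux differences versus control
#'
#' For every subsystem and exposure group, the difference of group-mean
#' subsystem flux from the control-group mean (positive = higher than
#' control), an unpaired two-tailed t-test over the per-sample values, and
#' the activated/suppressed/unchanged call. The per-animal context model is
#' the sampling unit. P-values are uncorrected by default (`bh = TRUE`
#' applies BH across all rows).
#'
#' Missing cells (a sample whose context model keeps no active reaction in
#' the subsystem) are treated as zero flux by default: a subsystem pruned
#' from a context model genuinely carries nothing, and activation from
#' silence / suppression to silence would otherwise be untestable. Set
#' `missing_as_zero = FALSE` to drop missing cells instead.
#'
#' @param tab a `subsystem_flux` from [subsystem_means()].
#' @param group_assignment named character vector, sample -> group label.
#' @param control control group label.
#' @param alpha significance threshold (default 0.05).
#' @param bh apply BH correction across subsystem-group pairs (default
#'   `FALSE`).
#' @param missing_as_zero treat missing cells as zero flux (default `TRUE`).
#' @return data.frame with `subsystem`, `group`, `delta`, `p`, `class`.
#' @export
delta_vs_control <- function(tab, group_assignment, control, alpha = 0.05,
                             bh = FALSE, missing_as_zero = TRUE) {
  stopifnot(inherits(tab, "subsystem_flux"))
  samples <- colnames(tab$means)
  if (!all(samples %in% names(group_assignment)))
    stop("group assignment missing for sample(s): ",
         paste(setdiff(samples, names(group_assignment)), collapse = ", "))
  ga <- group_assignment[samples]
  if (!control %in% ga)
    stop("control group label '", control, "' not present among samples")
  ctrl_idx <- which(ga == control)
  if (length(ctrl_idx) < 2) stop("control group needs >= 2 sample models")
  groups <- setdiff(unique(ga), control)
  vals_mat <- tab$means
  if (missing_as_zero) vals_mat[is.na(vals_mat)] <- 0
  rows <- list()
  for (s in rownames(vals_mat)) {
    ctrl_vals <- vals_mat[s, ctrl_idx]
    for (g in groups) {
      gvals <- vals_mat[s, ga == g]
      delta <- if (sum(!is.na(gvals)) > 0 && sum(!is.na(ctrl_vals)) > 0)
        mean(gvals, na.rm = TRUE) - mean(ctrl_vals, na.rm = TRUE) else NA_real_
      p <- if (sum(!is.na(gvals)) >= 2 && sum(!is.na(ctrl_vals)) >= 2)
        ttest_two_tailed(gvals, ctrl_vals) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subsystem = s, group = g, delta = delta, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) {
    ok <- !is.na(out$p)
    out$p[ok] <- bh_adjust(out$p[ok])
  }
  out$class <- classify(out$delta, out$p, alpha)
  rownames(out) <- NULL
  out
}

#' Scale-invariant biproportional rescaling of a flux matrix
#'
#' Alternating row/column scaling of a non-negative matrix until every row
#' and column has root-mean-square 1 over its nonzero entries (zeros are
#' masked throughout). Subsystems and conditions then become comparable in
#' magnitude without distorting within-row or within-column patterns; the
#' result is invariant to any independent positive row/column scaling of the
#' input. This is a deliberately simple RMS biproportional normalization,
#' not a re-derivation of the projective-decomposition method it is inspired
#' by.
#'
#' @param mat non-negative matrix with no all-zero row or column.
#' @param tol convergence tolerance on `max(|RMS - 1|)` (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list with `rescaled`, `row_scale`, `col_scale` such that
#'   `mat = diag(row_scale) %*% rescaled %*% diag(col_scale)`.
#' @export
projective_rescale <- function(mat, tol = 1e-8, max_iter = 1000) {
  mat <- as.matrix(mat)
  if (any(mat < 0, na.rm = TRUE)) stop("matrix must be non-negative")
  mat[is.na(mat)] <- 0
  mask <- mat > 0
  if (any(rowSums(mask) == 0) || any(colSums(mask) == 0))
    stop("matrix has an all-zero row or column")
  X <- mat
  r <- rep(1, nrow(mat)); cs <- rep(1, ncol(mat))
  rms_rows <- function(X) sqrt(rowSums(X^2 * mask) / rowSums(mask))
  rms_cols <- function(X) sqrt(colSums(X^2 * mask) / colSums(mask))
  for (it in seq_len(max_iter)) {
    rr <- rms_rows(X)
    X <- X / rr
    r <- r * rr
    cc <- rms_cols(X)
    X <- sweep(X, 2, cc, "/")
    cs <- cs * cc
    resid <- max(abs(rms_rows(X) - 1), abs(rms_cols(X) - 1))
    if (resid <= tol)
      return(list(rescaled = X, row_scale = r, col_scale = cs,
                  iterations = it))
  }
  stop(sprintf("projective_rescale did not converge in %d iterations ",
               max_iter), sprintf("(residual %.3g)", resid))
}
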