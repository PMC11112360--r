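#' Absolute fold change between two tPODs
#'
#' `max(a/b, b/a)`, always at least 1 and symmetric in its arguments.
#'
#' @param a,b positive tPOD values (vectorized).
#' @return numeric fold change(s).
#' @export
abs_fold_change <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("tPOD values must be positive")
  pmax(a / b, b / a)
}

#' Proportion of molecules within a k-fold difference
#'
#' The fraction of paired tPODs whose absolute fold change is below `k`
#' (strict inequality by default; set `ties_within = TRUE` to count pairs at
#' exactly k-fold as within). The denominator is the number of molecules with
#' a tPOD from both methods.
#'
#' @param a,b paired positive tPOD vectors (same molecules, same order).
#' @param k fold threshold (>= 1).
#' @param ties_within count fold changes exactly equal to `k` as within.
#' @return fraction in `[0, 1]`; `NA` when no pairs are supplied.
#' @export
prop_within <- function(a, b, k, ties_within = FALSE) {
  stopifnot(k >= 1, length(a) == length(b))
  if (length(a) == 0) return(NA_real_)
  fc <- abs_fold_change(a, b)
  if (ties_within) mean(fc <= k) else mean(fc < k)
}

#' Root-mean-square difference on the log10 scale
#'
#' Values are log10-transformed before the RMSD so that studies whose dose
#' ranges span different orders of magnitude are compared on relative
#' agreement: `sqrt(mean((log10(x) - log10(y))^2))`.
#'
#' @param xs,ys positive tPOD vectors of equal length.
#' @return the RMSD in log10 mg/kg/d.
#' @export
rmsd_log10 <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("length mismatch")
  if (any(xs <= 0) || any(ys <= 0)) stop("tPOD values must be positive")
  sqrt(mean((log10(xs) - log10(ys))^2))
}

#' Method sensitivity
#'
#' The number and fraction of molecules for which a method produced a tPOD.
#'
#' @param results data frame of tPOD results for one method (columns
#'   `molecule_id`, `tpod`; one row per molecule).
#' @return list with `n_molecules`, `n_with_tpod`, `fraction`.
#' @export
sensitivity <- function(results) {
  if (anyDuplicated(results$molecule_id))
    stop("duplicate molecule entries")
  n <- nrow(results)
  k <- sum(!is.na(results$tpod))
  list(n_molecules = n, n_with_tpod = k,
       fraction = if (n > 0) k / n else NA_real_)
}

#' Pairwise concordance report for two methods
#'
#' Pairs the two result sets by molecule, restricts every concordance metric
#' to the molecules where both methods report a tPOD (molecules where only
#' one method reports still count toward sensitivity, never toward
#' concordance), and computes the median absolute fold change, the proportion
#' within each fold threshold in `k`, and the log10 RMSD.
#'
#' @param results_a,results_b tPOD result data frames (columns `molecule_id`,
#'   `method`, `tpod`).
#' @param k fold-change thresholds for [prop_within()].
#' @return list of class `concordance_report` with fields `method_a`,
#'   `method_b`, `n_common`, `median_abs_fc`, `prop_within` (named by k),
#'   `rmsd_log10`, `per_molecule_fc` (named ratio a/b per common molecule).
#' @export
concordance_report <- function(results_a, results_b, k = c(2, 4, 10)) {
  m <- merge(results_a[, c("molecule_id", "tpod")],
             results_b[, c("molecule_id", "tpod")],
             by = "molecule_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$tpod_a) & !is.na(m$tpod_b), , drop = FALSE]
  out <- list(
    method_a = results_a$method[1], method_b = results_b$method[1],
    n_common = nrow(m),
    median_abs_fc = if (nrow(m))
      stats::median(abs_fold_change(m$tpod_a, m$tpod_b)) else NA_real_,
    prop_within = stats::setNames(
      vapply(k, function(kk) prop_within(m$tpod_a, m$tpod_b, kk),
             numeric(1)), paste0("k", k)),
    rmsd_log10 = if (nrow(m)) rmsd_log10(m$tpod_a, m$tpod_b) else NA_real_,
    per_molecule_fc = stats::setNames(m$tpod_a / m$tpod_b, m$molecule_id))
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance %s vs %s (n = %d common molecules)\n",
              x$method_a, x$method_b, x$n_common))
  cat(sprintf("  median |FC| = %.3g, RMSD(log10) = %.3g\n",
              x$median_abs_fc, x$rmsd_log10))
  pw <- paste(sprintf("%s: %.0f%%", names(x$prop_within),
                      100 * x$prop_within), collapse = ", ")
  cat("  within-fold:", pw, "\n")
  invisible(x)
}
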