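#' Benjamini-Hochberg adjustment with input validation
#'
#' Thin wrapper around [stats::p.adjust()] (`method = "BH"`) that enforces the
#' \[0, 1\] domain instead of silently propagating invalid p-values.
#'
#' @param pvalues Numeric vector of raw p-values, all in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  # exact tests can exceed 1 by floating-point error; clamp within tolerance
  pvalues[pvalues > 1 & pvalues <= 1 + 1e-8] <- 1
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Percentage helpers for prevalence and seed coverage
#'
#' `prevalence_pct()` expresses a case count as a percentage of a cohort
#' (e.g. index-disease prevalence among hospitalized patients);
#' `seed_coverage_pct()` expresses the number of index-trait SNPs recovered as
#' spatial eQTLs as a percentage of the index-trait SNP set.
#'
#' @param n_cases Number of patients carrying the index diagnosis.
#' @param n_total Total number of patients in the cohort.
#' @return Percentage on the 0-100 scale (not rounded).
#' @export
#' @examples
#' prevalence_pct(5, 400)
prevalence_pct <- function(n_cases, n_total) {
  stopifnot(n_total > 0, n_cases >= 0, n_cases <= n_total)
  100 * n_cases / n_total
}

#' @rdname prevalence_pct
#' @param n_seed_eqtls Number of index-trait SNPs that are spatial eQTLs in the
#'   GRN.
#' @param n_seed_snps Total number of index-trait SNPs queried.
#' @export
seed_coverage_pct <- function(n_seed_eqtls, n_seed_snps) {
  stopifnot(n_seed_snps > 0, n_seed_eqtls >= 0)
  100 * n_seed_eqtls / n_seed_snps
}

# internal: stop with a named-column message if any required column is missing
.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
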