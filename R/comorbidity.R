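#' Load long-format diagnosis records into per-patient code sets
#'
#' Applies the cohort rules: patients strictly over `max_age` are excluded,
#' codes are deduplicated per patient, and malformed rows (missing id, code,
#' or non-numeric age) are logged and skipped.
#'
#' @param records Data frame (`patient_id`, `age`, `sex`, `code`) or TSV
#'   path.
#' @param max_age Age cutoff; patients with age > `max_age` are removed
#'   (default 100, so a 100-year-old is retained).
#' @return List with `sets` (named list patient -> unique code vector), `n`
#'   (patient count after exclusions), `n_excluded_age`, `n_malformed`.
#' @export
patient_code_sets <- function(records, max_age = 100) {
  records <- read_patients(records)
  age <- suppressWarnings(as.numeric(records$age))
  bad <- is.na(age) | is.na(records$patient_id) | records$patient_id == "" |
    is.na(records$code) | records$code == ""
  n_malformed <- sum(bad)
  records <- records[!bad, , drop = FALSE]
  age <- age[!bad]
  pat_age <- tapply(age, records$patient_id, max)
  over <- names(pat_age)[pat_age > max_age]
  n_excluded_age <- length(over)
  records <- records[!(records$patient_id %in% over), , drop = FALSE]
  sets <- lapply(split(records$code, records$patient_id), unique)
  list(sets = sets, n = length(sets), n_excluded_age = n_excluded_age,
       n_malformed = n_malformed)
}

#' 2x2 co-diagnosis counts for one candidate disease
#'
#' Partitions the cohort by index and candidate diagnosis with exclusive
#' semantics: `C_A` index only, `C_B` candidate only, `C_AB` both, `H`
#' neither; `C_A + C_B + C_AB + H = N`. Prevalences are
#' `P_A = (C_A + C_AB)/N` and `P_B = (C_B + C_AB)/N`.
#'
#' @param patients Output of [patient_code_sets()].
#' @param index_code Index diagnosis code.
#' @param candidate_code Candidate diagnosis code (must differ from the
#'   index).
#' @return Object of class `comorbidity_counts`.
#' @export
count_2x2 <- function(patients, index_code, candidate_code) {
  if (identical(index_code, candidate_code)) {
    stop("candidate code equals the index code", call. = FALSE)
  }
  has_a <- vapply(patients$sets, function(s) index_code %in% s, logical(1))
  if (!any(has_a)) stop("index code absent from the records", call. = FALSE)
  has_b <- vapply(patients$sets, function(s) candidate_code %in% s,
                  logical(1))
  N <- patients$n
  counts <- list(code = candidate_code,
                 C_A = sum(has_a & !has_b), C_B = sum(!has_a & has_b),
                 C_AB = sum(has_a & has_b), H = sum(!has_a & !has_b),
                 N = N)
  counts$P_A <- (counts$C_A + counts$C_AB) / N
  counts$P_B <- (counts$C_B + counts$C_AB) / N
  structure(counts, class = "comorbidity_counts")
}

#' Odds ratio with 95% confidence interval
#'
#' OR = (C_AB * H) / (C_A * C_B) on the exclusive 2x2 partition, with the
#' log-OR normal-approximation interval
#' exp(ln OR +/- 1.96 * sqrt(1/C_AB + 1/C_A + 1/C_B + 1/H)). When any cell is
#' zero the Haldane correction (+0.5 to all four cells) is applied.
#'
#' @param counts A `comorbidity_counts` object.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(counts) {
  cells <- c(counts$C_AB, counts$C_A, counts$C_B, counts$H)
  if (all(cells == 0)) stop("all-zero table: odds ratio undefined",
                            call. = FALSE)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

#' Relative risk of co-diagnosis
#'
#' RR = C_AB / (N * P_A * P_B): observed co-diagnoses over the independence
#' expectation.
#'
#' @param counts A `comorbidity_counts` object.
#' @return Relative risk (scalar); undefined (error) when either prevalence
#'   is zero.
#' @export
relative_risk <- function(counts) {
  denom <- counts$N * counts$P_A * counts$P_B
  if (denom == 0) stop("zero prevalence: relative risk undefined",
                       call. = FALSE)
  counts$C_AB / denom
}

#' Comorbidity score
#'
#' log2((C_AB + 1) / (expected + 1)) with expected = P_A * P_B * N; the +1
#' smoothing makes the score total, and it is 0 when observed equals
#' expected.
#'
#' @param counts A `comorbidity_counts` object.
#' @return Score in log2 units.
#' @export
comorbidity_score <- function(counts) {
  expected <- counts$P_A * counts$P_B * counts$N
  log2((counts$C_AB + 1) / (expected + 1))
}

#' Full comorbidity screen against an index diagnosis
#'
#' For every candidate code in the records: builds the exclusive 2x2
#' partition, computes OR (with CI), RR, comorbidity score and a two-sided
#' Fisher's exact p-value, then BH q-values across the tested codes.
#' Candidate codes carried by fewer than `min_patients` patients
#' (C_B + C_AB) are excluded before testing; codes whose log-OR 95% CI
#' contains 0 (OR CI contains 1) are excluded from the final table after the
#' BH family is formed.
#'
#' @param records Long-format diagnosis records (or TSV path).
#' @param index_code Index diagnosis code.
#' @param min_patients Minimum patients carrying the candidate code
#'   (default 6).
#' @param max_age Age exclusion passed to [patient_code_sets()].
#' @param alpha q-value significance threshold reported by `summary()`.
#' @return Object of class `comorbidity`: list with `table` (one row per
#'   retained code: `code`, `C_A`, `C_B`, `C_AB`, `H`, `or`, `ci_low`,
#'   `ci_high`, `rr`, `score`, `pvalue`, `qvalue`), `n_patients`,
#'   `index_code`, `prevalence_index` (fraction), plus exclusion counts.
#' @export
comorbidity <- function(records, index_code, min_patients = 6L,
                        max_age = 100, alpha = 0.05) {
  patients <- if (is.list(records) && !is.data.frame(records) &&
                  !is.null(records$sets)) records
              else patient_code_sets(records, max_age = max_age)
  codes <- sort(unique(unlist(patients$sets, use.names = FALSE)))
  codes <- setdiff(codes, index_code)
  if (!any(vapply(patients$sets, function(s) index_code %in% s,
                  logical(1)))) {
    stop("index code absent from the records", call. = FALSE)
  }
  rows <- lapply(codes, function(cd) {
    ct <- count_2x2(patients, index_code, cd)
    if (ct$C_B + ct$C_AB < min_patients) return(NULL)
    or <- odds_ratio(ct)
    p <- stats::fisher.test(matrix(c(ct$C_AB, ct$C_A, ct$C_B, ct$H), 2))$p.value
    data.frame(code = cd, C_A = ct$C_A, C_B = ct$C_B, C_AB = ct$C_AB,
               H = ct$H, or = or$or, ci_low = or$ci_low,
               ci_high = or$ci_high, rr = relative_risk(ct),
               score = comorbidity_score(ct), pvalue = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_small <- length(codes) - (if (is.null(tab)) 0L else nrow(tab))
  if (is.null(tab)) {
    tab <- data.frame(code = character(0), C_A = integer(0),
                      C_B = integer(0), C_AB = integer(0), H = integer(0),
                      or = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), rr = numeric(0),
                      score = numeric(0), pvalue = numeric(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE)
    n_ci <- 0L
  } else {
    tab$qvalue <- bh_adjust(tab$pvalue)
    keep_ci <- tab$ci_low > 1 | tab$ci_high < 1
    n_ci <- sum(!keep_ci)
    tab <- tab[keep_ci, , drop = FALSE]
    tab <- tab[order(tab$qvalue, tab$code), , drop = FALSE]
    rownames(tab) <- NULL
  }
  n_index <- sum(vapply(patients$sets, function(s) index_code %in% s,
                        logical(1)))
  structure(list(table = tab, n_patients = patients$n,
                 index_code = index_code,
                 n_index = n_index,
                 prevalence_index = n_index / patients$n,
                 alpha = alpha,
                 n_excluded_small = n_small, n_excluded_ci = n_ci,
                 n_excluded_age = patients$n_excluded_age,
                 n_malformed = patients$n_malformed),
            class = "comorbidity")
}

#' @export
print.comorbidity <- function(x, ...) {
  cat(sprintf("Comorbidity screen vs %s: %d patients (prevalence %.3f%%)\n",
              x$index_code, x$n_patients,
              100 * x$prevalence_index))
  cat(sprintf("  %d codes retained; %d significant at q < %g\n",
              nrow(x$table), sum(x$table$qvalue < x$alpha), x$alpha))
  invisible(x)
}

#' @export
summary.comorbidity <- function(object, ...) {
  sig <- object$table[object$table$qvalue < object$alpha, , drop = FALSE]
  out <- list(index_code = object$index_code,
              n_patients = object$n_patients,
              n_index = object$n_index,
              prevalence_pct = 100 * object$prevalence_index,
              n_tested = nrow(object$table),
              significant = sig,
              n_excluded_small = object$n_excluded_small,
              n_excluded_ci = object$n_excluded_ci,
              n_excluded_age = object$n_excluded_age)
  class(out) <- "summary.comorbidity"
  out
}

#' @export
print.summary.comorbidity <- function(x, ...) {
  cat(sprintf("Index %s: %d of %d patients (prevalence %.3f%%)\n",
              x$index_code, x$n_index, x$n_patients, x$prevalence_pct))
  cat(sprintf("  codes tested: %d; significant: %d\n", x$n_tested,
              nrow(x$significant)))
  cat(sprintf("  excluded: %d (<min patients), %d (OR CI spans 1), %d (age)\n",
              x$n_excluded_small, x$n_excluded_ci, x$n_excluded_age))
  if (nrow(x$significant) > 0L) {
    print(utils::head(x$significant[, c("code", "C_AB", "or", "rr", "score",
                                        "qvalue")], 10))
  }
  invisible(x)
}

#' Overlap between comorbid terms and mapped gene-disease terms
#'
#' Intersects the two term sets at the configured code level and tests
#' over-representation with a one-sided Fisher's exact test over a stated
#' universe of disease terms.
#'
#' @param comorbid_terms Character vector of comorbidity-significant codes.
#' @param gda_terms Character vector of gene-disease ICD-10-AM codes.
#' @param universe_size Size of the disease-term universe.
#' @param code_level `"3"` (category, default) or `"full"`.
#' @return List with `overlap` (shared codes), `n_a`, `n_b`, `p` (one-sided
#'   Fisher p for over-representation).
#' @export
overlap_test <- function(comorbid_terms, gda_terms, universe_size,
                         code_level = "3") {
  a <- unique(normalize_code(comorbid_terms, code_level))
  b <- unique(normalize_code(gda_terms, code_level))
  if (universe_size < length(union(a, b))) {
    stop("universe smaller than the union of the term sets", call. = FALSE)
  }
  ov <- intersect(a, b)
  x <- length(ov)
  m <- matrix(c(x, length(a) - x, length(b) - x,
                universe_size - length(a) - length(b) + x), 2)
  p <- stats::fisher.test(m, alternative = "greater")$p.value
  list(overlap = sort(ov), n_a = length(a), n_b = length(b), p = p)
}
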