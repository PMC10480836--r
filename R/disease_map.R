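#' Curated gene-disease association sources
#'
#' The curation databases whose gene-disease associations are retained by
#' default; text-mined sources (e.g. BEFREE) are excluded to limit false
#' positives.
#'
#' @export
CURATED_GDA_SOURCES <- c("CGI", "PsyGeNET", "ClinGen", "CTD_human",
                         "UniProt", "Orphanet", "GenomicsEnglandPanelApp")

.norm_source <- function(x) tolower(gsub("[[:space:]_]+", "", x))

#' Filter gene-disease associations to curated sources
#'
#' Keeps records whose source is in the allowed set (source labels are
#' compared case- and whitespace-insensitively, since database exports vary)
#' and deduplicates on (gene, CUI), joining the contributing sources with a
#' comma.
#'
#' @param gdas Data frame (`gene_id`, `umls_cui`, `source`) or TSV path.
#' @param allowed_sources Character vector of source labels (default
#'   [CURATED_GDA_SOURCES]).
#' @return Deduplicated data frame (`gene_id`, `umls_cui`, `source`).
#' @export
filter_curated <- function(gdas, allowed_sources = CURATED_GDA_SOURCES) {
  gdas <- read_gda(gdas)
  if (nrow(gdas) == 0L) return(gdas)
  keep <- .norm_source(gdas$source) %in% .norm_source(allowed_sources)
  g <- gdas[keep, , drop = FALSE]
  if (nrow(g) == 0L) return(g)
  key <- paste(g$gene_id, g$umls_cui, sep = "\r")
  src <- tapply(g$source, key, function(s) paste(sort(unique(s)),
                                                 collapse = ","))
  parts <- do.call(rbind, strsplit(names(src), "\r", fixed = TRUE))
  out <- data.frame(gene_id = parts[, 1], umls_cui = parts[, 2],
                    source = as.character(src), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id, out$umls_cui), , drop = FALSE]
}

#' Map per-level genes to ICD-10-AM disease terms
#'
#' Relational composition gene -> UMLS CUI -> ICD-10 -> ICD-10-AM: a CUI with
#' k ICD-10 codes, each mapping to m ICD-10-AM codes, yields k*m rows.
#' Nothing is silently dropped: CUIs without an ICD-10 mapping and ICD-10
#' codes without an ICD-10-AM mapping are reported separately.
#'
#' @param genes_by_level Data frame (`level`, `gene`) or named list of gene
#'   vectors keyed by level.
#' @param gdas Curated GDA data frame (see [filter_curated()]).
#' @param cui2icd10 Data frame (`cui`, `icd10`) or TSV path.
#' @param icd10_2_icd10am Data frame (`icd10`, `icd10am`) or TSV path.
#' @return Object of class `disease_map`: list with `table` (`level`, `gene`,
#'   `cui`, `icd10`, `icd10am`) and `unmapped` (list of `cui` and `icd10`
#'   identifiers that found no mapping).
#' @export
genes_to_icd10am <- function(genes_by_level, gdas, cui2icd10,
                             icd10_2_icd10am) {
  if (!is.data.frame(genes_by_level)) {
    genes_by_level <- data.frame(
      level = rep(as.integer(names(genes_by_level)),
                  lengths(genes_by_level)),
      gene = unlist(genes_by_level, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  cui_map <- read_code_mapping(cui2icd10, "cui", "icd10")
  am_map <- read_code_mapping(icd10_2_icd10am, "icd10", "icd10am")

  step1 <- merge(genes_by_level, gdas, by.x = "gene", by.y = "gene_id")
  names(step1)[names(step1) == "umls_cui"] <- "cui"
  step2 <- merge(step1, cui_map, by = "cui")
  unmapped_cui <- sort(setdiff(unique(step1$cui), unique(cui_map$cui)))
  step3 <- merge(step2, am_map, by = "icd10")
  unmapped_icd10 <- sort(setdiff(unique(step2$icd10), unique(am_map$icd10)))
  out <- unique(step3[, c("level", "gene", "cui", "icd10", "icd10am")])
  out <- out[order(out$level, out$gene, out$cui, out$icd10, out$icd10am), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(list(table = out,
                 unmapped = list(cui = unmapped_cui,
                                 icd10 = unmapped_icd10)),
            class = "disease_map")
}

#' @export
print.disease_map <- function(x, ...) {
  cat(sprintf("Gene-disease mapping: %d rows (%d genes, %d CUIs, %d ICD-10-AM terms)\n",
              nrow(x$table), length(unique(x$table$gene)),
              length(unique(x$table$cui)),
              length(unique(x$table$icd10am))))
  cat(sprintf("  unmapped: %d CUIs, %d ICD-10 codes\n",
              length(x$unmapped$cui), length(x$unmapped$icd10)))
  invisible(x)
}

#' Truncate diagnosis codes to the 3-character ICD category
#'
#' Hospital records code at full ICD-10-AM depth (e.g. C9240) while mapped
#' disease terms are often category level (C92); comparisons therefore
#' default to the 3-character category.
#'
#' @param codes Character vector of ICD codes ('.' separators are removed
#'   first).
#' @param code_level `"3"` (category) or `"full"`.
#' @return Normalized codes.
#' @export
normalize_code <- function(codes, code_level = c("3", "full")) {
  code_level <- match.arg(as.character(code_level), c("3", "full"))
  codes <- gsub(".", "", codes, fixed = TRUE)
  if (code_level == "3") codes <- substr(codes, 1L, 3L)
  codes
}
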