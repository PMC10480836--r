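#' Schema-validated TSV readers shared by all pipeline stages
#'
#' Each reader accepts either a file path or an already-loaded data frame,
#' checks the required columns, and converts genomic coordinates from the
#' 1-based inclusive convention used on disk (GTF-like) to the 0-based
#' half-open convention used internally. Errors name the offending file and
#' column so a malformed input fails fast.
#'
#' @param x File path or data frame.
#' @return A validated data frame (coordinates 0-based half-open where
#'   applicable).
#' @name readers
NULL

.read_tsv <- function(x, what) {
  if (is.data.frame(x)) return(x)
  if (!is.character(x) || length(x) != 1L || !file.exists(x)) {
    stop(sprintf("%s: file not found: %s", what, as.character(x)[1]),
         call. = FALSE)
  }
  utils::read.delim(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

#' @rdname readers
#' @export
read_genes <- function(x) {
  df <- .read_tsv(x, "genes")
  .check_columns(df, c("gene_id", "chrom", "start", "end", "biotype"), "genes")
  # 1-based inclusive on disk -> 0-based half-open internally
  df$start <- as.integer(df$start) - 1L
  df$end <- as.integer(df$end)
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("genes: invalid interval (require 1 <= start <= end)", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_variants <- function(x) {
  df <- .read_tsv(x, "variants")
  .check_columns(df, c("rsid", "chrom", "pos", "maf"), "variants")
  df$pos <- as.integer(df$pos) - 1L
  if (any(df$pos < 0)) stop("variants: pos must be >= 1", call. = FALSE)
  if (any(df$maf < 0 | df$maf > 0.5)) {
    stop("variants: maf must be in [0, 0.5]", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_contacts <- function(x) {
  df <- .read_tsv(x, "contacts")
  .check_columns(df, c("chrom1", "frag1_idx", "chrom2", "frag2_idx",
                       "cell_line", "replicate"), "contacts")
  df$frag1_idx <- as.integer(df$frag1_idx)
  df$frag2_idx <- as.integer(df$frag2_idx)
  df
}

#' @rdname readers
#' @export
read_matrix_tsv <- function(x) {
  df <- .read_tsv(x, "matrix")
  if (ncol(df) < 2L) stop("matrix: need sample id column plus data", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname readers
#' @export
read_gwas <- function(x) {
  df <- .read_tsv(x, "gwas")
  .check_columns(df, c("rsid", "trait", "pvalue"), "gwas")
  df$pvalue <- as.numeric(df$pvalue)
  if (any(!is.finite(df$pvalue)) || any(df$pvalue <= 0 | df$pvalue > 1)) {
    stop("gwas: pvalue must be in (0, 1]", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_string_edges <- function(x) {
  df <- .read_tsv(x, "ppin_string")
  .check_columns(df, c("protein_a", "protein_b", "score"), "ppin_string")
  if (any(df$score < 0 | df$score > 1)) {
    stop("ppin_string: score must be in [0, 1]", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_proper_edges <- function(x) {
  df <- .read_tsv(x, "ppin_proper")
  .check_columns(df, c("protein_a", "protein_b"), "ppin_proper")
  df
}

#' @rdname readers
#' @export
read_gda <- function(x) {
  df <- .read_tsv(x, "gda")
  .check_columns(df, c("gene_id", "umls_cui", "source"), "gda")
  df
}

#' @rdname readers
#' @export
read_code_mapping <- function(x, from, to) {
  df <- .read_tsv(x, "code mapping")
  .check_columns(df, c(from, to), "code mapping")
  df
}

#' @rdname readers
#' @export
read_patients <- function(x) {
  df <- .read_tsv(x, "patients")
  .check_columns(df, c("patient_id", "age", "sex", "code"), "patients")
  df
}

#' Read a FASTA genome as a named character vector
#'
#' Uses Biostrings for parsing; sequences are returned as uppercase strings
#' keyed by chromosome name.
#'
#' @param path FASTA file path.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  seqs
}

#' Write a data frame as a strict TSV
#'
#' Fixed dialect shared by every stage: header row, tab separated, UTF-8,
#' '.' decimal, no quoting, no row names. Keeping the dialect fixed makes
#' output hashes stable across reruns.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
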