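#' In-silico restriction digestion
#'
#' Cuts a chromosome sequence at every occurrence of the enzyme's recognition
#' site and returns the resulting fragments, which tile the chromosome without
#' gaps or overlaps. Cut placement follows the recognition-site chemistry:
#' HindIII (AAGCTT) cuts after offset 1 (A^AGCTT); MboI (GATC) cuts before the
#' site (^GATC). Recognition sites are located by a left-to-right scan.
#'
#' @param sequence Single chromosome sequence (uppercase A/C/G/T/N string).
#' @param enzyme `"HindIII"` or `"MboI"`.
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `index` (0-based ordinal within the chromosome).
#' @export
#' @examples
#' digest_sequence("TTGATCTT", "MboI")  # fragments [0,2) and [2,8)
digest_sequence <- function(sequence, enzyme) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence must contain only A/C/G/T/N", call. = FALSE)
  }
  spec <- .enzyme_spec(enzyme)
  len <- nchar(sequence)
  hits <- gregexpr(spec$site, sequence, fixed = TRUE)[[1]]
  cuts <- integer(0)
  if (hits[1] != -1L) {
    # gregexpr positions are 1-based starts; convert to 0-based cut coords
    cuts <- as.integer(hits) - 1L + spec$offset
    cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
  }
  starts <- c(0L, cuts)
  ends <- c(cuts, len)
  data.frame(start = starts, end = ends, index = seq_along(starts) - 1L)
}

.enzyme_spec <- function(enzyme) {
  switch(enzyme,
    HindIII = list(site = "AAGCTT", offset = 1L),
    MboI = list(site = "GATC", offset = 0L),
    stop(sprintf("unknown enzyme: %s", enzyme), call. = FALSE)
  )
}

#' Digest every chromosome of a genome
#'
#' @param genome Named character vector of chromosome sequences (or a FASTA
#'   path, read via [read_genome()]).
#' @param enzyme Enzyme label passed to [digest_sequence()].
#' @return Named list of per-chromosome fragment data frames.
#' @export
digest_genome <- function(genome, enzyme) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  stopifnot(!is.null(names(genome)))
  lapply(genome, digest_sequence, enzyme = enzyme)
}

#' Locate positions and intervals on a fragment tiling
#'
#' `locate_position()` maps a point (e.g. a SNP) to the unique fragment
#' containing it; a position equal to a fragment start belongs to that
#' fragment (half-open convention). `locate_interval()` returns every fragment
#' overlapping a half-open interval (e.g. a gene body), so a gene spanning a
#' cut site maps to several fragments.
#'
#' @param pos 0-based position.
#' @param fragments Fragment data frame from [digest_sequence()].
#' @return `locate_position()`: the fragment `index` (scalar integer);
#'   `locate_interval()`: integer vector of overlapping fragment indices.
#' @export
locate_position <- function(pos, fragments) {
  len <- fragments$end[nrow(fragments)]
  if (pos < 0 || pos >= len) {
    stop(sprintf("position %d outside [0, %d)", pos, len), call. = FALSE)
  }
  fragments$index[findInterval(pos, fragments$start)]
}

#' @rdname locate_position
#' @param start,end 0-based half-open interval bounds.
#' @export
locate_interval <- function(start, end, fragments) {
  stopifnot(start < end)
  fragments$index[fragments$start < end & fragments$end > start]
}
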