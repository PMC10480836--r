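#' Hypergeometric survival probability
#'
#' P(X >= x) where X counts trait-associated SNPs among the eQTLs of a level,
#' drawn without replacement: population of `M` unique catalog SNPs, `n` of
#' which carry the trait, with `N` draws (the level's eQTLs). Computed by
#' summing probability masses in log space via `lchoose`, which stays
#' accurate for large inputs; `x = 0` returns exactly 1.
#'
#' @param x Observed trait-associated eQTL count at the level.
#' @param N Total eQTLs at the level (number of draws).
#' @param n Catalog SNPs associated with the trait (successes in the
#'   population).
#' @param M Unique SNPs in the catalog (population size).
#' @return Tail probability in \[0, 1\]. `x > min(n, N)` returns 0 with a
#'   warning (an impossible observation); negative inputs are an error.
#' @export
#' @examples
#' hypergeom_sf(2, N = 5, n = 4, M = 10)  # 186/252
hypergeom_sf <- function(x, N, n, M) {
  vals <- c(x = x, N = N, n = n, M = M)
  if (any(vals != floor(vals))) stop("arguments must be integers")
  if (any(vals < 0)) stop("arguments must be non-negative")
  if (n > M || N > M) stop("n and N cannot exceed M")
  # at or below the smallest attainable success count the tail is exactly 1
  if (x <= max(0, N - (M - n))) return(1)
  upper <- min(n, N)
  if (x > upper) {
    warning("x exceeds min(n, N); returning 0")
    return(0)
  }
  i <- x:upper
  # draws with too few failures available are impossible; drop them
  i <- i[N - i <= M - n]
  if (length(i) == 0L) return(0)
  logp <- lchoose(n, i) + lchoose(M - n, N - i) - lchoose(M, N)
  min(1, sum(exp(logp)))
}

#' Per-level GWAS-trait enrichment
#'
#' For every trait with at least one associated eQTL at the level, computes
#' the hypergeometric survival probability with N = number of level eQTLs,
#' x = level eQTLs carrying the trait, and n, M taken from the catalog, then
#' corrects across the traits tested within the level. Level eQTLs absent
#' from the catalog still count toward N (they can never contribute to x).
#'
#' @param level_eqtls Character vector of the level's eQTL rsids.
#' @param catalog A `gwas_catalog`.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @param level Level label carried through to the output.
#' @return Data frame (`trait`, `level`, `x`, `N`, `n`, `M`, `pvalue`,
#'   `adj_pvalue`), one row per trait observed at the level; empty level
#'   gives an empty data frame.
#' @export
enrich_level <- function(level_eqtls, catalog,
                         correction = c("BH", "bonferroni"), level = NA) {
  correction <- match.arg(correction)
  empty <- data.frame(trait = character(0), level = integer(0),
                      x = integer(0), N = integer(0), n = integer(0),
                      M = integer(0), pvalue = numeric(0),
                      adj_pvalue = numeric(0), stringsAsFactors = FALSE)
  level_eqtls <- unique(level_eqtls)
  N <- length(level_eqtls)
  if (N == 0L) return(empty)
  r <- catalog$records
  M <- catalog$M
  hit <- unique(r[r$rsid %in% level_eqtls, c("rsid", "trait")])
  if (nrow(hit) == 0L) return(empty)
  x_tab <- table(hit$trait)
  traits <- sort(names(x_tab))
  n_tab <- tapply(r$rsid, r$trait, function(s) length(unique(s)))
  x <- as.integer(x_tab[traits])
  n <- as.integer(n_tab[traits])
  p <- mapply(hypergeom_sf, x = x, N = N, n = n, M = M)
  adj <- if (correction == "BH") bh_adjust(p) else pmin(1, p * length(p))
  data.frame(trait = traits, level = level, x = x, N = N, n = n, M = M,
             pvalue = p, adj_pvalue = adj, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Enrichment across all levels of an expansion
#'
#' @param levels A `level_sets` object.
#' @inheritParams enrich_level
#' @return Row-bound per-level enrichment data frame.
#' @export
enrich_levels <- function(levels, catalog, correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  out <- lapply(levels, function(lv)
    enrich_level(lv$eqtls, catalog, correction, level = lv$level))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Monte Carlo null over random gene sets
#'
#' Estimates, per (trait, level), how often the trait comes out significant
#' when the level-0 gene set is replaced by a uniformly drawn random set of
#' the same size from the GRN's gene universe. Each iteration rebuilds levels
#' 0..`depth` from the random seed genes (the scored edges are filtered
#' once and cached), recomputes the per-level enrichment, and records which
#' (trait, level) pairs reach `adj_pvalue < alpha`. The returned frequency is
#' the direct estimate of a trait's topology-generic significance rate, used
#' to veto traits whose enrichment reflects network topology rather than the
#' index condition.
#'
#' @param grn A `grn` object; its gene universe is sampled.
#' @param string_edges Raw scored edges (filtered internally with `top_k`,
#'   `min_score`).
#' @param proper_edges Unscored curated pairs.
#' @param catalog A `gwas_catalog`.
#' @param set_size Number of genes drawn each iteration (the level-0 size).
#' @param n_iter Iterations (default 1000).
#' @param seed RNG seed; results are reproducible bit-for-bit given the seed.
#' @param depth Expansion depth (default 4).
#' @param alpha Per-iteration significance cutoff (default 0.05).
#' @param correction Correction passed to [enrich_level()].
#' @param top_k,min_score Scored-edge filter parameters.
#' @return Data frame (`trait`, `level`, `mc_frequency`) covering every
#'   (trait, level) pair significant in at least one iteration.
#' @export
monte_carlo_null <- function(grn, string_edges, proper_edges, catalog,
                             set_size, n_iter = 1000L, seed = 1L,
                             depth = 4L, alpha = 0.05,
                             correction = c("BH", "bonferroni"),
                             top_k = 5L, min_score = 0.700) {
  correction <- match.arg(correction)
  universe <- sort(unique(grn$edges$gene))
  if (set_size > length(universe)) {
    stop("set_size exceeds the GRN gene universe", call. = FALSE)
  }
  fs <- filter_string_edges(string_edges, top_k = top_k,
                            min_score = min_score)
  counts <- new.env(parent = emptyenv())
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    genes <- sample(universe, set_size)
    lev0 <- list(level = 0L, genes = genes,
                 eqtls = unique(grn$edges$snp[grn$edges$gene %in% genes]))
    levels <- expand_levels(lev0, fs, proper_edges, depth = depth, grn = grn)
    enr <- enrich_levels(levels, catalog, correction)
    sig <- enr[enr$adj_pvalue < alpha, , drop = FALSE]
    if (nrow(sig) > 0L) {
      keys <- paste(sig$trait, sig$level, sep = "\r")
      for (k in keys) {
        counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    return(data.frame(trait = character(0), level = integer(0),
                      mc_frequency = numeric(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(trait = parts[, 1], level = as.integer(parts[, 2]),
                    mc_frequency = vapply(keys, function(k) counts[[k]],
                                          integer(1)) / n_iter,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$trait, out$level), , drop = FALSE]
}

#' Final trait verdict: enrichment plus Monte Carlo veto
#'
#' A (trait, level) passes when its corrected enrichment p-value is below
#' `alpha` *and* its Monte Carlo frequency (how often random gene sets make
#' it significant) is below `mc_alpha`. Pairs absent from the Monte Carlo
#' table have frequency 0.
#'
#' @param enrichments Data frame from [enrich_levels()].
#' @param mc_table Data frame from [monte_carlo_null()].
#' @param mc_alpha Monte Carlo veto threshold (default 0.05).
#' @param alpha Enrichment significance threshold (default 0.05).
#' @param levels,grn,catalog Optional; when all are supplied, the
#'   contributing trait-eQTL-gene triples of passing traits are attached as
#'   attribute `"triples"`.
#' @return The passing rows of `enrichments` with `mc_frequency` and
#'   `passes` columns appended.
#' @export
final_verdict <- function(enrichments, mc_table, mc_alpha = 0.05,
                          alpha = 0.05, levels = NULL, grn = NULL,
                          catalog = NULL) {
  if (nrow(enrichments) == 0L) {
    enrichments$mc_frequency <- numeric(0)
    enrichments$passes <- logical(0)
    return(enrichments)
  }
  key <- paste(enrichments$trait, enrichments$level, sep = "\r")
  mkey <- paste(mc_table$trait, mc_table$level, sep = "\r")
  freq <- mc_table$mc_frequency[match(key, mkey)]
  freq[is.na(freq)] <- 0
  enrichments$mc_frequency <- freq
  enrichments$passes <- enrichments$adj_pvalue < alpha & freq < mc_alpha
  out <- enrichments[enrichments$passes, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(levels) && !is.null(grn) && !is.null(catalog)) {
    attr(out, "triples") <- trait_triples(out, levels, grn, catalog)
  }
  out
}

#' Contributing trait-eQTL-gene triples
#'
#' For each passing (trait, level), lists the level eQTLs associated with the
#' trait in the catalog together with the level genes they regulate in the
#' GRN.
#'
#' @param verdict Data frame of passing rows (`trait`, `level`).
#' @param levels A `level_sets` object.
#' @param grn A `grn` object.
#' @param catalog A `gwas_catalog`.
#' @return Data frame (`trait`, `rsid`, `gene`, `level`).
#' @export
trait_triples <- function(verdict, levels, grn, catalog) {
  r <- catalog$records
  rows <- lapply(seq_len(nrow(verdict)), function(i) {
    lv <- levels[[verdict$level[i] + 1L]]
    trait_snps <- unique(r$rsid[r$trait == verdict$trait[i]])
    eq <- intersect(lv$eqtls, trait_snps)
    if (length(eq) == 0L) return(NULL)
    e <- grn$edges[grn$edges$snp %in% eq & grn$edges$gene %in% lv$genes, ,
                   drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    data.frame(trait = verdict$trait[i], rsid = e$snp, gene = e$gene,
               level = verdict$level[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trait = character(0), rsid = character(0),
                      gene = character(0), level = integer(0))
  }
  rownames(out) <- NULL
  out
}
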