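#' GWAS catalog container
#'
#' Wraps an association table (`rsid`, `trait`, `pvalue`) and records the
#' number of unique SNPs across the whole table, the population size used by
#' the enrichment test.
#'
#' @param x Data frame or TSV path with columns `rsid`, `trait`, `pvalue`.
#' @return Object of class `gwas_catalog`: list with `records` and `M`.
#' @export
gwas_catalog <- function(x) {
  records <- read_gwas(x)
  structure(list(records = records,
                 M = length(unique(records$rsid))),
            class = "gwas_catalog")
}

#' @export
print.gwas_catalog <- function(x, ...) {
  cat(sprintf("GWAS catalog: %d records, %d unique SNPs, %d traits\n",
              nrow(x$records), x$M, length(unique(x$records$trait))))
  invisible(x)
}

#' Select index-trait seed SNPs from a GWAS catalog
#'
#' Exact (case-sensitive, full-string) trait label match with an association
#' p-value threshold; duplicated rows collapse to a single rsid.
#'
#' @param catalog A `gwas_catalog`.
#' @param term Trait label to match exactly.
#' @param p_max Association p-value cutoff (default 1e-5).
#' @return Character vector of unique rsids (possibly empty).
#' @export
select_seed_snps <- function(catalog, term, p_max = 1e-5) {
  stopifnot(inherits(catalog, "gwas_catalog"), nzchar(term))
  r <- catalog$records
  sort(unique(r$rsid[r$trait == term & r$pvalue <= p_max]))
}

#' Index-condition GRN (level 0)
#'
#' Level-0 genes are the GRN targets of the seed SNPs; level-0 eQTLs are
#' *all* GRN SNPs regulating those genes (a superset of the seed eQTLs,
#' including eQTLs associated with other traits).
#'
#' @param grn A `grn` object.
#' @param seeds Character vector of seed rsids.
#' @return A level-set list: `level` (0), `genes`, `eqtls`, `seed_eqtls`
#'   (seeds that are GRN eQTLs).
#' @export
grn_level0 <- function(grn, seeds) {
  e <- grn$edges
  seed_eqtls <- sort(intersect(seeds, e$snp))
  genes <- sort(unique(e$gene[e$snp %in% seed_eqtls]))
  if (length(genes) == 0L) {
    warning("no seed SNP is a GRN eQTL; level 0 is empty")
  }
  eqtls <- sort(unique(e$snp[e$gene %in% genes]))
  list(level = 0L, genes = genes, eqtls = eqtls, seed_eqtls = seed_eqtls)
}

#' Filter scored protein-interaction edges
#'
#' Per query protein, keep its `top_k` highest-scoring partners (ties at the
#' rank boundary broken by score descending then partner id ascending), then
#' drop survivors scoring below `min_score`. The result is the union over
#' query proteins, deduplicated as undirected edges keeping the maximum
#' score.
#'
#' @param edges Data frame `protein_a`, `protein_b`, `score` (scores in
#'   \[0, 1\]).
#' @param top_k Partners retained per protein (default 5).
#' @param min_score Confidence cutoff (default 0.700).
#' @return Filtered undirected edge data frame (`protein_a`, `protein_b`,
#'   `score`), one row per unordered pair.
#' @export
filter_string_edges <- function(edges, top_k = 5L, min_score = 0.700) {
  if (nrow(edges) == 0L) return(edges[0, , drop = FALSE])
  stopifnot(all(edges$score >= 0 & edges$score <= 1))
  # the table is read as (query protein, partner, score): the top-k rule is
  # applied to each query protein's full partner list, as in database
  # exports where each row answers one protein's query
  directed <- data.frame(from = edges$protein_a, to = edges$protein_b,
                         score = edges$score, stringsAsFactors = FALSE)
  kept <- lapply(split(directed, directed$from), function(d) {
    d <- d[order(-d$score, d$to), , drop = FALSE]
    d <- d[seq_len(min(top_k, nrow(d))), , drop = FALSE]
    d[d$score >= min_score, , drop = FALSE]
  })
  kept <- do.call(rbind, kept)
  if (is.null(kept) || nrow(kept) == 0L) {
    return(edges[0, , drop = FALSE])
  }
  a <- pmin(kept$from, kept$to)
  b <- pmax(kept$from, kept$to)
  key <- paste(a, b, sep = "\r")
  score <- tapply(kept$score, key, max)
  parts <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  out <- data.frame(protein_a = parts[, 1], protein_b = parts[, 2],
                    score = as.numeric(score), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Expand a level-0 gene set through protein-interaction edges
#'
#' Builds the undirected union of the filtered scored edges and the unscored
#' curated pairs, and assigns every reachable protein its shortest-path
#' distance from the level-0 gene set: level k comprises the genes exactly k
#' edges away (k = 1..`depth`), so each gene belongs to at most one level and
#' a level-0 gene reachable again at a larger distance stays at level 0.
#' Each level's eQTLs are fetched from the GRN (genes without GRN edges
#' contribute no eQTLs). Gene and protein identifiers are taken as one shared
#' namespace.
#'
#' @param level0 Level-0 list from [grn_level0()] (or any list with `genes`).
#' @param string_edges Filtered scored edge data frame (see
#'   [filter_string_edges()]); pass raw edges through the filter first.
#' @param proper_edges Unscored curated pair data frame (`protein_a`,
#'   `protein_b`); these bypass the score filter.
#' @param depth Maximum expansion level (default 4).
#' @param grn A `grn` object supplying each level's eQTLs (optional; without
#'   it eQTL sets are empty).
#' @return Object of class `level_sets`: list of per-level lists (`level`,
#'   `genes`, `eqtls`, `provenance` data frame gene/db) for levels 0..depth,
#'   plus attributes `depth` and `seed_eqtls`.
#' @export
expand_levels <- function(level0, string_edges, proper_edges, depth = 4L,
                          grn = NULL) {
  stopifnot(depth >= 1L, length(level0$genes) > 0L)
  edf <- rbind(
    if (nrow(string_edges) > 0L)
      data.frame(a = string_edges$protein_a, b = string_edges$protein_b,
                 db = "STRING", stringsAsFactors = FALSE),
    if (nrow(proper_edges) > 0L)
      data.frame(a = proper_edges$protein_a, b = proper_edges$protein_b,
                 db = "PROPER", stringsAsFactors = FALSE))
  eqtls_of <- function(genes) {
    if (is.null(grn) || length(genes) == 0L) return(character(0))
    sort(unique(grn$edges$snp[grn$edges$gene %in% genes]))
  }
  lev0 <- list(level = 0L, genes = sort(level0$genes),
               eqtls = if (!is.null(level0$eqtls)) level0$eqtls
                       else eqtls_of(level0$genes),
               provenance = NULL)
  levels <- vector("list", depth + 1L)
  levels[[1L]] <- lev0
  if (is.null(edf) || nrow(edf) == 0L) {
    for (k in seq_len(depth)) {
      levels[[k + 1L]] <- list(level = k, genes = character(0),
                               eqtls = character(0), provenance = NULL)
    }
  } else {
    g <- igraph::graph_from_data_frame(edf, directed = FALSE)
    verts <- igraph::V(g)$name
    src <- intersect(lev0$genes, verts)
    dist <- rep(Inf, length(verts))
    names(dist) <- verts
    if (length(src) > 0L) {
      dm <- igraph::distances(g, v = src, to = verts)
      dist <- apply(dm, 2, min)
    }
    dist[names(dist) %in% lev0$genes] <- 0
    for (k in seq_len(depth)) {
      genes_k <- sort(names(dist)[is.finite(dist) & dist == k])
      prov <- NULL
      if (length(genes_k) > 0L) {
        prev <- if (k == 1L) lev0$genes else levels[[k]]$genes
        hit <- edf[(edf$a %in% genes_k & edf$b %in% prev) |
                     (edf$b %in% genes_k & edf$a %in% prev), , drop = FALSE]
        gn <- ifelse(hit$a %in% genes_k, hit$a, hit$b)
        prov <- data.frame(
          gene = genes_k,
          db = vapply(genes_k, function(x)
            paste(sort(unique(hit$db[gn == x])), collapse = ","),
            character(1), USE.NAMES = FALSE),
          stringsAsFactors = FALSE)
      }
      levels[[k + 1L]] <- list(level = k, genes = genes_k,
                               eqtls = eqtls_of(genes_k), provenance = prov)
    }
  }
  structure(levels, class = "level_sets", depth = depth,
            seed_eqtls = level0$seed_eqtls)
}

#' @export
print.level_sets <- function(x, ...) {
  cat("PPIN expansion levels:\n")
  for (lv in x) {
    cat(sprintf("  level %d: %d genes, %d eQTLs\n",
                lv$level, length(lv$genes), length(lv$eqtls)))
  }
  invisible(x)
}

#' Flatten level sets to a long table
#'
#' @param levels A `level_sets` object.
#' @param grn Optional `grn` object; when supplied, each gene row is expanded
#'   to one row per regulating eQTL.
#' @return Data frame (`level`, `gene`, `rsid`, `provenance_db`); genes
#'   without GRN eQTLs get a single `NA`-rsid row.
#' @export
level_table <- function(levels, grn = NULL) {
  rows <- lapply(levels, function(lv) {
    if (length(lv$genes) == 0L) return(NULL)
    prov <- lv$provenance
    db_of <- function(g) {
      if (is.null(prov)) return(NA_character_)
      i <- match(g, prov$gene)
      if (is.na(i)) NA_character_ else prov$db[i]
    }
    do.call(rbind, lapply(lv$genes, function(g) {
      rs <- if (is.null(grn)) character(0)
            else sort(unique(grn$edges$snp[grn$edges$gene == g]))
      if (length(rs) == 0L) rs <- NA_character_
      data.frame(level = lv$level, gene = g, rsid = rs,
                 provenance_db = db_of(g), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(level = integer(0), gene = character(0),
                      rsid = character(0), provenance_db = character(0))
  }
  rownames(out) <- NULL
  out
}
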