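#' Spatial SNP-gene pairs supported by chromatin contacts
#'
#' Filters raw fragment-level contact records down to SNP-gene pairs with
#' spatial support: a pair is kept when its SNP-fragment/gene-fragment contact
#' is captured in at least two replicates within at least one cell line.
#' Contacts between adjacent fragments of the same chromosome (|index
#' difference| < 2, which includes self-contacts) are ignored, and no maximum
#' interaction distance is applied. A gene overlapping several fragments is
#' supported by a contact on any one of them.
#'
#' @param contacts Contact data frame (`chrom1`, `frag1_idx`, `chrom2`,
#'   `frag2_idx`, `cell_line`, `replicate`).
#' @param snp_loc Named list (by enzyme) of data frames `rsid`, `chrom`,
#'   `frag_idx` giving each SNP's fragment under that enzyme's digestion.
#' @param gene_loc Named list (by enzyme) of data frames `gene_id`, `chrom`,
#'   `frag_idx`, one row per fragment a gene overlaps.
#' @param cell_line_enzymes Named character vector mapping cell line to
#'   enzyme.
#' @param min_replicates Minimum distinct replicates within one cell line
#'   (default 2, i.e. "more than one replicate").
#' @return Data frame of unique pairs (`snp`, `gene`) with a `support` column
#'   listing the supporting cell line/replicate evidence.
#' @export
spatial_pairs <- function(contacts, snp_loc, gene_loc, cell_line_enzymes,
                          min_replicates = 2L) {
  empty <- data.frame(snp = character(0), gene = character(0),
                      support = character(0), stringsAsFactors = FALSE)
  if (nrow(contacts) == 0L) return(empty)
  unknown <- setdiff(unique(contacts$cell_line), names(cell_line_enzymes))
  if (length(unknown) > 0L) {
    stop(sprintf("no enzyme mapping for cell line(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  # adjacency filter: same chromosome and |delta index| < 2
  adj <- contacts$chrom1 == contacts$chrom2 &
    abs(contacts$frag1_idx - contacts$frag2_idx) < 2L
  contacts <- contacts[!adj, , drop = FALSE]
  if (nrow(contacts) == 0L) return(empty)

  out <- list()
  for (enz in unique(cell_line_enzymes)) {
    cls <- names(cell_line_enzymes)[cell_line_enzymes == enz]
    cc <- contacts[contacts$cell_line %in% cls, , drop = FALSE]
    if (nrow(cc) == 0L) next
    sl <- snp_loc[[enz]]
    gl <- gene_loc[[enz]]
    skey <- paste(sl$chrom, sl$frag_idx)
    gkey <- paste(gl$chrom, gl$frag_idx)
    k1 <- paste(cc$chrom1, cc$frag1_idx)
    k2 <- paste(cc$chrom2, cc$frag2_idx)
    match_side <- function(snp_key, gene_key) {
      si <- lapply(snp_key, function(k) which(skey == k))
      gi <- lapply(gene_key, function(k) which(gkey == k))
      rows <- which(lengths(si) > 0L & lengths(gi) > 0L)
      if (length(rows) == 0L) return(NULL)
      do.call(rbind, lapply(rows, function(r) {
        expand.grid(snp = sl$rsid[si[[r]]], gene = gl$gene_id[gi[[r]]],
                    cell_line = cc$cell_line[r], replicate = cc$replicate[r],
                    stringsAsFactors = FALSE)
      }))
    }
    out[[length(out) + 1L]] <- match_side(k1, k2)
    out[[length(out) + 1L]] <- match_side(k2, k1)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- unique(hits)
  key <- paste(hits$snp, hits$gene, hits$cell_line, sep = "\r")
  reps <- tapply(hits$replicate, key, function(r) length(unique(r)))
  ok_key <- names(reps)[reps >= min_replicates]
  if (length(ok_key) == 0L) return(empty)
  parts <- do.call(rbind, strsplit(ok_key, "\r", fixed = TRUE))
  pairs <- unique(data.frame(snp = parts[, 1], gene = parts[, 2],
                             stringsAsFactors = FALSE))
  sup_key <- paste(hits$snp, hits$gene, sep = "\r")
  support <- vapply(paste(pairs$snp, pairs$gene, sep = "\r"), function(k) {
    h <- hits[sup_key == k, , drop = FALSE]
    paste(sort(unique(paste0(h$cell_line, ":", h$replicate))), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  pairs$support <- support
  pairs[order(pairs$snp, pairs$gene), , drop = FALSE]
}

#' Single SNP-gene eQTL regression
#'
#' Ordinary least squares of expression on allele dosage plus optional
#' covariate columns, with a two-sided t-test on the dosage coefficient.
#' Pairs with a constant dosage vector (or zero-variance expression) are
#' untestable and flagged rather than fitted.
#'
#' @param dosage Numeric vector of allele dosages (0/1/2).
#' @param expression Numeric expression vector, same length.
#' @param covariates Optional numeric matrix of covariate columns.
#' @return List with `ok` (logical), and when `ok`: `beta` (slope, expression
#'   units per allele) and `pvalue`.
#' @export
eqtl_test <- function(dosage, expression, covariates = NULL) {
  n <- length(dosage)
  stopifnot(length(expression) == n)
  p <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < p + 3L) stop("need at least p + 3 samples", call. = FALSE)
  if (stats::var(dosage) == 0 || stats::var(expression) == 0) {
    return(list(ok = FALSE, reason = "constant input"))
  }
  X <- cbind(intercept = 1, dosage = dosage)
  if (p > 0L) X <- cbind(X, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # rank-deficient design (e.g. dosage collinear with a covariate)
    return(list(ok = FALSE, reason = "rank-deficient design"))
  }
  coefs <- qr.coef(qx, expression)
  res <- expression - X %*% coefs
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- unname(coefs[2])
  tval <- beta / se
  list(ok = TRUE, beta = beta, se = se,
       pvalue = 2 * stats::pt(-abs(tval), df))
}

#' Classify eQTL-gene interaction type
#'
#' Same chromosome and distance < 1 Mb: `cis`; same chromosome otherwise:
#' `trans-intra`; different chromosomes: `trans-inter`. The gene anchor is the
#' annotated interval start (the annotation carries no strand, so the start is
#' used as the transcription start proxy). Vectorized.
#'
#' @param snp_pos,gene_tss 0-based positions.
#' @param snp_chrom,gene_chrom Chromosome labels.
#' @param cis_window Distance threshold in bp (default 1e6).
#' @return Data frame with `interaction_type` and `distance` (NA iff
#'   `trans-inter`).
#' @export
classify_interaction <- function(snp_pos, snp_chrom, gene_tss, gene_chrom,
                                 cis_window = 1e6) {
  same <- snp_chrom == gene_chrom
  dist <- ifelse(same, abs(snp_pos - gene_tss), NA_real_)
  type <- ifelse(!same, "trans-inter",
                 ifelse(dist < cis_window, "cis", "trans-intra"))
  data.frame(interaction_type = type, distance = dist,
             stringsAsFactors = FALSE)
}

#' Build a tissue-specific spatial eQTL gene regulatory network
#'
#' Full GRN construction: digest the genome with each enzyme used by the
#' contact libraries, map SNPs and genes to restriction fragments, retain
#' SNP-gene pairs with replicated non-adjacent contact support, regress
#' expression on dosage (plus covariates) for each pair, BH-adjust all tested
#' pairs jointly, keep edges with adjusted p <= `fdr`, and classify each edge
#' as cis / trans-intra / trans-inter.
#'
#' @param genome Named character vector of chromosome sequences or FASTA path.
#' @param genes,variants,contacts Data frames or TSV paths (see the readers).
#' @param genotypes Samples x SNPs dosage matrix (or matrix TSV path).
#' @param expression Samples x genes expression matrix (or matrix TSV path).
#' @param covariates Optional samples x covariates matrix (or path).
#' @param cell_line_enzymes Named character vector cell line -> enzyme; when
#'   NULL, inferred from cell line names containing "HindIII"/"MboI".
#' @param fdr BH-adjusted p-value cutoff (default 0.05).
#' @param tissue Label stored on the network.
#' @return An object of class `grn`: list with `edges` (data frame `snp`,
#'   `gene`, `beta`, `pvalue`, `adj_pvalue`, `interaction_type`, `distance`),
#'   `tissue`, `n_tested`, `n_untestable`.
#' @export
build_grn <- function(genome, genes, variants, contacts, genotypes,
                      expression, covariates = NULL,
                      cell_line_enzymes = NULL, fdr = 0.05,
                      tissue = "tissue") {
  if (is.character(genome) && length(genome) == 1L) genome <- read_genome(genome)
  genes <- read_genes(genes)
  variants <- read_variants(variants)
  contacts <- read_contacts(contacts)
  if (is.character(genotypes)) genotypes <- read_matrix_tsv(genotypes)
  if (is.character(expression)) expression <- read_matrix_tsv(expression)
  if (is.character(covariates)) covariates <- read_matrix_tsv(covariates)

  if (is.null(cell_line_enzymes)) {
    cls <- unique(contacts$cell_line)
    enz <- ifelse(grepl("hindiii", cls, ignore.case = TRUE), "HindIII",
                  ifelse(grepl("mboi", cls, ignore.case = TRUE), "MboI", NA))
    if (anyNA(enz)) {
      stop("cannot infer enzyme from cell line names; pass cell_line_enzymes",
           call. = FALSE)
    }
    cell_line_enzymes <- stats::setNames(enz, cls)
  }

  enzymes <- unique(cell_line_enzymes)
  frags <- lapply(stats::setNames(enzymes, enzymes),
                  function(e) digest_genome(genome, e))
  snp_loc <- lapply(frags, function(fr) {
    data.frame(rsid = variants$rsid, chrom = variants$chrom,
               frag_idx = mapply(function(ch, p) locate_position(p, fr[[ch]]),
                                 variants$chrom, variants$pos),
               stringsAsFactors = FALSE)
  })
  gene_loc <- lapply(frags, function(fr) {
    res <- mapply(function(ch, s, e) locate_interval(s, e, fr[[ch]]),
                  genes$chrom, genes$start, genes$end, SIMPLIFY = FALSE)
    data.frame(gene_id = rep(genes$gene_id, lengths(res)),
               chrom = rep(genes$chrom, lengths(res)),
               frag_idx = unlist(res, use.names = FALSE),
               stringsAsFactors = FALSE)
  })

  pairs <- spatial_pairs(contacts, snp_loc, gene_loc, cell_line_enzymes)
  edges <- .test_pairs(pairs, genotypes, expression, covariates,
                       genes, variants, fdr)
  structure(list(edges = edges$kept, tissue = tissue,
                 n_tested = edges$n_tested,
                 n_untestable = edges$n_untestable),
            class = "grn")
}

.test_pairs <- function(pairs, genotypes, expression, covariates,
                        genes, variants, fdr) {
  empty <- data.frame(snp = character(0), gene = character(0),
                      beta = numeric(0), pvalue = numeric(0),
                      adj_pvalue = numeric(0), interaction_type = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    return(list(kept = empty, n_tested = 0L, n_untestable = 0L))
  }
  testable <- pairs$snp %in% colnames(genotypes) &
    pairs$gene %in% colnames(expression)
  pairs <- pairs[testable, , drop = FALSE]
  beta <- pval <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    fit <- eqtl_test(genotypes[, pairs$snp[i]], expression[, pairs$gene[i]],
                     covariates)
    if (fit$ok) {
      beta[i] <- fit$beta
      pval[i] <- fit$pvalue
    }
  }
  ok <- !is.na(pval)
  n_untestable <- sum(!ok)
  tested <- pairs[ok, , drop = FALSE]
  beta <- beta[ok]; pval <- pval[ok]
  if (nrow(tested) == 0L) {
    return(list(kept = empty, n_tested = 0L, n_untestable = n_untestable))
  }
  adj <- bh_adjust(pval)
  keep <- adj <= fdr
  kept <- tested[keep, c("snp", "gene"), drop = FALSE]
  kept$beta <- beta[keep]
  kept$pvalue <- pval[keep]
  kept$adj_pvalue <- adj[keep]
  si <- match(kept$snp, variants$rsid)
  gi <- match(kept$gene, genes$gene_id)
  cls <- classify_interaction(variants$pos[si], variants$chrom[si],
                              genes$start[gi], genes$chrom[gi])
  kept$interaction_type <- cls$interaction_type
  kept$distance <- cls$distance
  rownames(kept) <- NULL
  list(kept = kept, n_tested = nrow(tested), n_untestable = n_untestable)
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("Spatial eQTL GRN (%s): %d edges (%d SNPs, %d genes); %d pairs tested\n",
              x$tissue, nrow(x$edges), length(unique(x$edges$snp)),
              length(unique(x$edges$gene)), x$n_tested))
  invisible(x)
}

#' @export
summary.grn <- function(object, ...) {
  tab <- table(factor(object$edges$interaction_type,
                      levels = c("cis", "trans-intra", "trans-inter")))
  out <- list(tissue = object$tissue, n_edges = nrow(object$edges),
              n_snps = length(unique(object$edges$snp)),
              n_genes = length(unique(object$edges$gene)),
              by_type = tab, n_tested = object$n_tested,
              n_untestable = object$n_untestable)
  class(out) <- "summary.grn"
  out
}

#' @export
print.summary.grn <- function(x, ...) {
  cat(sprintf("Spatial eQTL GRN: %s\n", x$tissue))
  cat(sprintf("  edges: %d (%d SNPs regulating %d genes)\n",
              x$n_edges, x$n_snps, x$n_genes))
  cat(sprintf("  cis: %d  trans-intra: %d  trans-inter: %d\n",
              x$by_type["cis"], x$by_type["trans-intra"],
              x$by_type["trans-inter"]))
  cat(sprintf("  pairs tested: %d (untestable: %d)\n",
              x$n_tested, x$n_untestable))
  invisible(x)
}

#' Edge index maps of a GRN
#'
#' Split the edge table by SNP or by gene; the union over either index
#' reproduces the edge set exactly.
#'
#' @param grn A `grn` object.
#' @return Named list of edge data frames.
#' @export
grn_by_snp <- function(grn) split(grn$edges, grn$edges$snp)

#' @rdname grn_by_snp
#' @export
grn_by_gene <- function(grn) split(grn$edges, grn$edges$gene)

#' Write / read a GRN edge table
#'
#' The TSV carries the edge columns; a JSON summary (edge counts by
#' interaction type) is written alongside.
#'
#' @param grn A `grn` object.
#' @param path Output TSV path (`.summary.json` appended for the summary).
#' @export
write_grn <- function(grn, path) {
  write_tsv_strict(grn$edges, path)
  s <- summary(grn)
  jsonlite::write_json(
    list(tissue = s$tissue, n_edges = s$n_edges, n_snps = s$n_snps,
         n_genes = s$n_genes, by_type = as.list(s$by_type),
         n_tested = s$n_tested, n_untestable = s$n_untestable),
    paste0(path, ".summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grn
#' @param tissue Tissue label for the reconstructed object.
#' @export
read_grn <- function(path, tissue = "tissue") {
  edges <- .read_tsv(path, "grn")
  .check_columns(edges, c("snp", "gene", "beta", "pvalue", "adj_pvalue",
                          "interaction_type", "distance"), "grn")
  structure(list(edges = edges, tissue = tissue,
                 n_tested = NA_integer_, n_untestable = NA_integer_),
            class = "grn")
}
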