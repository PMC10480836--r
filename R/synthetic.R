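#' Configuration for the synthetic-data generator
#'
#' A single seeded configuration drives every generated input: genome,
#' annotation, variants, genotype/expression matrices, chromatin contacts,
#' GWAS catalog, protein-interaction tables, gene-disease and code-mapping
#' tables, and patient diagnosis records. All randomness flows from `seed`
#' through one pseudo-random stream consumed in a fixed order, so the same
#' configuration reproduces byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp (>= 50).
#' @param n_genes,n_snps,n_samples Counts of genes, variants and samples
#'   (`n_samples >= 30` for stable regressions).
#' @param n_true_eqtls Number of planted SNP-gene effects.
#' @param eqtl_beta Planted effect size (expression units per allele).
#' @param noise_sd Expression noise SD.
#' @param n_replicates_per_cellline Contact replicates per cell line.
#' @param contact_noise_rate Background contact rate in \[0, 1).
#' @param n_traits Number of GWAS traits (>= 4; three are planted:
#'   the index trait, a level-0-specific trait and a hub-biased confounder).
#' @param ppin_depth Protein-interaction expansion depth (1-4).
#' @param n_patients Patient count for the diagnosis records.
#' @param planted_or Odds ratio planted for the comorbid code pairs.
#' @param site_density Restriction sites per kb per enzyme (0 = none).
#' @param n_index_genes Genes targeted by the planted index-trait SNPs
#'   (level 0).
#' @param n_hub_neighbors Partner count of the hub protein used to plant the
#'   topology-generic confounder trait.
#' @param n_background_snps Catalog SNPs outside the GRN (sets the
#'   population size M).
#' @param index_prevalence Index-diagnosis prevalence among patients.
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 2500000L,
                         n_genes = 200L, n_snps = 400L, n_samples = 200L,
                         n_true_eqtls = 150L, eqtl_beta = 2,
                         noise_sd = 0.5, n_replicates_per_cellline = 3L,
                         contact_noise_rate = 0.1, n_traits = 8L,
                         ppin_depth = 4L, n_patients = 20000L,
                         planted_or = 5, site_density = 1,
                         n_index_genes = 5L, n_hub_neighbors = 30L,
                         n_background_snps = 1600L,
                         index_prevalence = 0.05) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = as.integer(chrom_len),
              n_genes = as.integer(n_genes), n_snps = as.integer(n_snps),
              n_samples = as.integer(n_samples),
              n_true_eqtls = as.integer(n_true_eqtls),
              eqtl_beta = eqtl_beta, noise_sd = noise_sd,
              n_replicates_per_cellline = as.integer(n_replicates_per_cellline),
              contact_noise_rate = contact_noise_rate,
              n_traits = as.integer(n_traits),
              ppin_depth = as.integer(ppin_depth),
              n_patients = as.integer(n_patients),
              planted_or = planted_or, site_density = site_density,
              n_index_genes = as.integer(n_index_genes),
              n_hub_neighbors = as.integer(n_hub_neighbors),
              n_background_snps = as.integer(n_background_snps),
              index_prevalence = index_prevalence)
  counts <- c("n_chrom", "chrom_len", "n_genes", "n_snps", "n_samples",
              "n_true_eqtls", "n_replicates_per_cellline", "n_traits",
              "n_patients", "n_index_genes", "n_hub_neighbors",
              "n_background_snps")
  for (f in counts) {
    if (cfg[[f]] <= 0L) stop(sprintf("configuration error: %s must be > 0", f))
  }
  if (cfg$chrom_len < 50L) stop("configuration error: chrom_len < 50 bp")
  if (cfg$contact_noise_rate < 0 || cfg$contact_noise_rate >= 1) {
    stop("configuration error: contact_noise_rate must be in [0, 1)")
  }
  if (!cfg$ppin_depth %in% 1:4) {
    stop("configuration error: ppin_depth must be 1..4")
  }
  if (cfg$planted_or <= 0) stop("configuration error: planted_or must be > 0")
  if (cfg$n_true_eqtls > cfg$n_snps) {
    stop("configuration error: n_true_eqtls > n_snps")
  }
  if (cfg$n_samples < 30L) {
    stop("configuration error: n_samples must be >= 30")
  }
  if (cfg$n_traits < 4L) stop("configuration error: n_traits must be >= 4")
  if (cfg$n_index_genes < 4L) {
    stop("configuration error: n_index_genes must be >= 4 (chain roots)")
  }
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  n_singles <- cfg$n_true_eqtls - 2L * cfg$n_index_genes
  n_chain_genes <- 4L * cfg$ppin_depth
  if (n_singles < cfg$n_hub_neighbors + n_chain_genes) {
    stop("configuration error: ppin_depth/hub layout unreachable with the requested eQTL count")
  }
  if (cfg$n_genes < cfg$n_index_genes + n_singles + 10L) {
    stop("configuration error: not enough genes for the planted layout")
  }
  structure(cfg, class = "synth_config")
}

.chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chrom))

.split_count <- function(total, k) {
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0L) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

#' Generate a synthetic genome with planted restriction sites
#'
#' Builds a random A/C/G/T background scrubbed of both recognition sites,
#' then overwrites site-free positions with AAGCTT (HindIII) and GATC (MboI)
#' occurrences at `site_density` sites per kb per enzyme. Insertions are kept
#' at least 12 bp apart, so they cannot create additional occurrences of
#' either motif (neither motif self-overlaps or contains the other).
#'
#' @param config A `synth_config`. The caller controls the RNG state
#'   ([synth_generate()] seeds it once).
#' @return List with `genome` (named character vector) and `site_counts`
#'   (per-chromosome naive-scan counts of each motif).
#' @export
synth_genome <- function(config) {
  cfg <- config
  genome <- character(cfg$n_chrom)
  names(genome) <- .chrom_names(cfg)
  site_counts <- list()
  n_sites <- round(cfg$site_density * cfg$chrom_len / 1000)
  for (ch in names(genome)) {
    s <- paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
               collapse = "")
    while (grepl("GATC", s, fixed = TRUE) || grepl("AAGCTT", s, fixed = TRUE)) {
      s <- gsub("GATC", "GAAC", s, fixed = TRUE)
      s <- gsub("AAGCTT", "AAGATT", s, fixed = TRUE)
    }
    if (n_sites > 0L && cfg$chrom_len >= 24L * n_sites + 60L) {
      grid <- seq(20L, cfg$chrom_len - 30L, by = 12L)
      pos <- sort(sample(grid, 2L * n_sites))
      pos <- sample(pos)  # random enzyme assignment over the spaced grid
      hind <- sort(pos[seq_len(n_sites)])
      mbo <- sort(pos[n_sites + seq_len(n_sites)])
      v <- strsplit(s, "", fixed = TRUE)[[1]]
      hoff <- rep(hind, each = 6L) + rep(0:5, times = length(hind))
      v[hoff + 1L] <- rep(c("A", "A", "G", "C", "T", "T"), length(hind))
      moff <- rep(mbo, each = 4L) + rep(0:3, times = length(mbo))
      v[moff + 1L] <- rep(c("G", "A", "T", "C"), length(mbo))
      s <- paste(v, collapse = "")
    }
    genome[ch] <- s
    cnt <- function(site) {
      h <- gregexpr(site, s, fixed = TRUE)[[1]]
      if (h[1] == -1L) 0L else length(h)
    }
    site_counts[[ch]] <- list(AAGCTT = cnt("AAGCTT"), GATC = cnt("GATC"))
  }
  list(genome = genome, site_counts = site_counts)
}

# gene and variant tables (0-based internal coordinates)
.synth_genes_variants <- function(cfg) {
  chroms <- .chrom_names(cfg)
  per_chrom_g <- .split_count(cfg$n_genes, cfg$n_chrom)
  per_chrom_s <- .split_count(cfg$n_snps, cfg$n_chrom)
  gene_len <- 600L
  genes <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    slots <- seq(0L, cfg$chrom_len - gene_len - 100L, by = 700L)
    if (length(slots) < per_chrom_g[i]) {
      stop("configuration error: chromosome too short for requested genes")
    }
    starts <- sort(sample(slots, per_chrom_g[i]))
    data.frame(chrom = chroms[i], start = starts, end = starts + gene_len,
               stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("GENE%04d", seq_len(nrow(genes)))
  genes$biotype <- "protein_coding"
  genes <- genes[, c("gene_id", "chrom", "start", "end", "biotype")]
  variants <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(chrom = chroms[i],
               pos = sort(sample.int(cfg$chrom_len, per_chrom_s[i]) - 1L),
               stringsAsFactors = FALSE)
  }))
  variants$rsid <- sprintf("rs%05d", seq_len(nrow(variants)))
  variants$maf <- round(stats::runif(nrow(variants), 0.05, 0.5), 4)
  variants <- variants[, c("rsid", "chrom", "pos", "maf")]
  list(genes = genes, variants = variants)
}

# plant the eQTL pairs and the PPIN/trait layout over them
.synth_plant <- function(cfg, genome, genes, variants) {
  enzymes <- c("HindIII", "MboI")
  frags <- lapply(stats::setNames(enzymes, enzymes),
                  function(e) digest_genome(genome, e))
  snp_frag <- lapply(frags, function(fr)
    mapply(function(ch, p) locate_position(p, fr[[ch]]),
           variants$chrom, variants$pos))
  gene_frags <- lapply(frags, function(fr)
    mapply(function(ch, s, e) locate_interval(s, e, fr[[ch]]),
           genes$chrom, genes$start, genes$end, SIMPLIFY = FALSE))
  ok_enzymes <- function(si, gi) {
    ok <- character(0)
    for (e in enzymes) {
      if (variants$chrom[si] != genes$chrom[gi]) {
        ok <- c(ok, e)
      } else if (min(abs(gene_frags[[e]][[gi]] - snp_frag[[e]][si])) >= 2L) {
        ok <- c(ok, e)
      }
    }
    ok
  }
  snp_order <- sample.int(nrow(variants))
  gene_order <- sample.int(nrow(genes))
  n_singles <- cfg$n_true_eqtls - 2L * cfg$n_index_genes
  index_gi <- gene_order[seq_len(cfg$n_index_genes)]
  single_gi <- gene_order[cfg$n_index_genes + seq_len(n_singles)]
  spare_gi <- gene_order[(cfg$n_index_genes + n_singles + 1L):nrow(genes)]

  take_snp <- local({
    ptr <- 0L
    function(gi) {
      repeat {
        ptr <<- ptr + 1L
        if (ptr > length(snp_order)) {
          stop("configuration error: could not place planted eQTLs on non-adjacent fragments")
        }
        si <- snp_order[ptr]
        if (length(ok_enzymes(si, gi)) > 0L) return(si)
      }
    }
  })
  pairs <- list()
  asthma_si <- specific_si <- integer(cfg$n_index_genes)
  for (j in seq_len(cfg$n_index_genes)) {
    asthma_si[j] <- take_snp(index_gi[j])
    specific_si[j] <- take_snp(index_gi[j])
    pairs[[length(pairs) + 1L]] <- c(asthma_si[j], index_gi[j])
    pairs[[length(pairs) + 1L]] <- c(specific_si[j], index_gi[j])
  }
  single_si <- integer(n_singles)
  for (j in seq_len(n_singles)) {
    single_si[j] <- take_snp(single_gi[j])
    pairs[[length(pairs) + 1L]] <- c(single_si[j], single_gi[j])
  }
  pm <- do.call(rbind, pairs)
  beta <- sample(c(-1, 1), nrow(pm), replace = TRUE) * cfg$eqtl_beta
  true_eqtls <- data.frame(snp = variants$rsid[pm[, 1]],
                           gene = genes$gene_id[pm[, 2]], beta = beta,
                           stringsAsFactors = FALSE)

  # PPIN layout: chains (levels 1..depth), hub + neighbors (confounder)
  hub_gi <- spare_gi[1L]
  sel <- sample.int(n_singles)
  nb_idx <- sel[seq_len(cfg$n_hub_neighbors)]
  chain_idx <- sel[cfg$n_hub_neighbors + seq_len(4L * cfg$ppin_depth)]
  neighbors_gi <- single_gi[nb_idx]
  chains_gi <- matrix(single_gi[chain_idx], nrow = 4L)  # 4 chains x depth
  list(frags = frags, snp_frag = snp_frag, gene_frags = gene_frags,
       true_eqtls = true_eqtls,
       index_genes = genes$gene_id[index_gi],
       asthma_snps = variants$rsid[asthma_si],
       specific_snps = variants$rsid[specific_si],
       single_snps = variants$rsid[single_si],
       single_genes = genes$gene_id[single_gi],
       hub_gene = genes$gene_id[hub_gi],
       hub_neighbors = genes$gene_id[neighbors_gi],
       hub_trait_snps = variants$rsid[single_si[nb_idx[seq_len(min(15L, cfg$n_hub_neighbors))]]],
       chain_genes = matrix(genes$gene_id[chains_gi], nrow = 4L))
}

#' Generate genotype and expression matrices with planted effects
#'
#' Genotypes follow Hardy-Weinberg at each variant's MAF; expression is a
#' log-normal per-gene baseline plus `beta * dosage` for every planted pair,
#' a sex effect that scales with `noise_sd` (so the zero-noise limit is
#' exact), and Normal(0, `noise_sd`) noise.
#'
#' @param config A `synth_config`.
#' @param variants Variant table (`rsid`, `maf`).
#' @param gene_ids Gene identifiers.
#' @param true_eqtls Data frame (`snp`, `gene`, `beta`) of planted effects.
#' @return List with `genotypes`, `expression`, `covariates` matrices
#'   (samples in rows).
#' @export
synth_genotypes_expression <- function(config, variants, gene_ids,
                                       true_eqtls) {
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  G <- vapply(seq_len(nrow(variants)), function(i) {
    repeat {
      d <- stats::rbinom(n, 2L, variants$maf[i])
      if (stats::var(d) > 0) return(as.double(d))
    }
  }, numeric(n))
  dimnames(G) <- list(samples, variants$rsid)
  sex <- stats::rbinom(n, 1L, 0.5)
  pc1 <- stats::rnorm(n)
  pc2 <- stats::rnorm(n)
  baseline <- stats::rlnorm(length(gene_ids), meanlog = 3, sdlog = 1)
  E <- matrix(rep(baseline, each = n), nrow = n,
              dimnames = list(samples, gene_ids))
  E <- E + 0.6 * config$noise_sd * sex
  E <- E + matrix(stats::rnorm(n * length(gene_ids), 0, config$noise_sd),
                  nrow = n)
  for (i in seq_len(nrow(true_eqtls))) {
    E[, true_eqtls$gene[i]] <- E[, true_eqtls$gene[i]] +
      true_eqtls$beta[i] * G[, true_eqtls$snp[i]]
  }
  cov <- cbind(sex = sex, pc1 = pc1, pc2 = pc2)
  rownames(cov) <- samples
  list(genotypes = G, expression = E, covariates = cov)
}

#' Generate contact records supporting the planted pairs
#'
#' Every planted SNP-gene pair receives contact rows in all replicates of
#' each cell line whose enzyme puts the pair on non-adjacent fragments
#' (guaranteed for at least one cell line by construction). Background
#' contacts are added at `contact_noise_rate`: null SNP-gene pairs emitted in
#' exactly two replicates (so they enter the eQTL test as true negatives),
#' single-replicate junk rows, and a few adjacent-fragment rows exercising
#' the adjacency filter. All background pairs are flagged in the truth
#' ledger.
#'
#' @param config A `synth_config`.
#' @param plant Internal layout from the planting step.
#' @param genes,variants Annotation tables.
#' @return List with `contacts` (data frame), `cell_line_enzymes`, and
#'   `noise_pairs`.
#' @export
synth_contacts <- function(config, plant, genes, variants) {
  cfg <- config
  cls <- c(CL1_HindIII = "HindIII", CL2_MboI = "MboI")
  reps <- seq_len(cfg$n_replicates_per_cellline)
  rows <- list()
  emit <- function(si, gi, cl, replicates) {
    e <- cls[[cl]]
    sf <- plant$snp_frag[[e]][si]
    gfs <- plant$gene_frags[[e]][[gi]]
    same <- variants$chrom[si] == genes$chrom[gi]
    if (same) {
      gfs <- gfs[abs(gfs - sf) >= 2L]
      if (length(gfs) == 0L) return(FALSE)
    }
    gf <- gfs[which.max(abs(gfs - sf))]
    for (r in replicates) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom1 = variants$chrom[si], frag1_idx = sf,
        chrom2 = genes$chrom[gi], frag2_idx = gf,
        cell_line = cl, replicate = r, stringsAsFactors = FALSE,
        row.names = NULL)
    }
    TRUE
  }
  si_of <- match(plant$true_eqtls$snp, variants$rsid)
  gi_of <- match(plant$true_eqtls$gene, genes$gene_id)
  for (k in seq_along(si_of)) {
    placed <- FALSE
    for (cl in names(cls)) {
      placed <- emit(si_of[k], gi_of[k], cl, reps) || placed
    }
    if (!placed) stop("internal: planted pair has no non-adjacent placement")
  }
  n_noise <- round(cfg$contact_noise_rate * cfg$n_snps)
  planted_key <- paste(plant$true_eqtls$snp, plant$true_eqtls$gene)
  noise_pairs <- data.frame(snp = character(0), gene = character(0),
                            kind = character(0), stringsAsFactors = FALSE)
  draw_null <- function() {
    for (try in 1:200) {
      si <- sample.int(nrow(variants), 1L)
      gi <- sample.int(nrow(genes), 1L)
      if (!paste(variants$rsid[si], genes$gene_id[gi]) %in% planted_key) {
        return(c(si, gi))
      }
    }
    stop("internal: could not draw a null pair")
  }
  if (n_noise > 0L) {
    for (k in seq_len(n_noise)) {  # tested nulls: two replicates
      repeat {
        p <- draw_null()
        cl <- sample(names(cls), 1L)
        if (emit(p[1], p[2], cl, reps[1:2])) break
      }
      noise_pairs <- rbind(noise_pairs, data.frame(
        snp = variants$rsid[p[1]], gene = genes$gene_id[p[2]],
        kind = "tested_null", stringsAsFactors = FALSE))
    }
    for (k in seq_len(n_noise)) {  # single-replicate junk
      repeat {
        p <- draw_null()
        cl <- sample(names(cls), 1L)
        if (emit(p[1], p[2], cl, reps[1])) break
      }
      noise_pairs <- rbind(noise_pairs, data.frame(
        snp = variants$rsid[p[1]], gene = genes$gene_id[p[2]],
        kind = "single_replicate", stringsAsFactors = FALSE))
    }
    for (k in seq_len(min(5L, n_noise))) {  # adjacent-fragment rows
      si <- sample.int(nrow(variants), 1L)
      e <- cls[[1]]
      sf <- plant$snp_frag[[e]][si]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = variants$chrom[si], frag1_idx = sf,
        chrom2 = variants$chrom[si], frag2_idx = sf + 1L,
        cell_line = names(cls)[1], replicate = reps, stringsAsFactors = FALSE,
        row.names = NULL)
    }
  }
  contacts <- do.call(rbind, rows)
  rownames(contacts) <- NULL
  list(contacts = contacts, cell_line_enzymes = cls,
       noise_pairs = noise_pairs)
}

#' Generate a GWAS-catalog-style association table
#'
#' Three planted traits ride on the GRN: the index trait (seed SNPs
#' targeting the index genes, plus catalog-only SNPs so seed coverage is
#' below 100%), a level-0-specific trait (one eQTL per index gene), and a
#' hub-biased confounder trait (eQTLs regulating the hub protein's
#' neighbors). The remaining traits are background, drawn over catalog-only
#' SNPs. All planted associations have p <= 1e-5.
#'
#' @param config A `synth_config`.
#' @param plant Internal layout from the planting step.
#' @return List with `gwas` (data frame `rsid`, `trait`, `pvalue`) and
#'   `trait_of_snp` (named list for planted traits).
#' @export
synth_gwas <- function(config, plant) {
  cfg <- config
  bg <- sprintf("rsB%04d", seq_len(cfg$n_background_snps))
  n_bg_traits <- cfg$n_traits - 3L
  bg_trait <- sprintf("Background trait %02d", seq_len(n_bg_traits))
  assign <- rep(bg_trait, length.out = length(bg))
  rows <- data.frame(rsid = bg, trait = assign,
                     pvalue = 10^-stats::runif(length(bg), 6, 12),
                     stringsAsFactors = FALSE)
  planted <- rbind(
    data.frame(rsid = c(plant$asthma_snps, bg[seq_len(5L)]),
               trait = "Asthma", pvalue = 1e-8, stringsAsFactors = FALSE),
    data.frame(rsid = c(plant$specific_snps, bg[6:40]),
               trait = "Eosinophil count", pvalue = 1e-8,
               stringsAsFactors = FALSE),
    data.frame(rsid = c(plant$hub_trait_snps, bg[41:65]),
               trait = "Body mass index", pvalue = 1e-8,
               stringsAsFactors = FALSE))
  gwas <- rbind(rows, planted)
  gwas <- gwas[order(gwas$trait, gwas$rsid), , drop = FALSE]
  gwas$pvalue <- signif(gwas$pvalue, 6)
  rownames(gwas) <- NULL
  list(gwas = gwas,
       trait_of_snp = list(Asthma = plant$asthma_snps,
                           `Eosinophil count` = plant$specific_snps,
                           `Body mass index` = plant$hub_trait_snps))
}

#' Generate protein-interaction edge tables with planted levels
#'
#' Scored (STRING-like) edges carry four chains of length `ppin_depth`
#' rooted at distinct index genes (scores 0.95 down in 0.05 steps, all above
#' the 0.700 cutoff and within the top-5 rule), plus low-scoring decoy edges
#' that the filter must drop. Unscored (PROPER-like) edges connect a hub
#' protein to one index gene and to `n_hub_neighbors` GRN genes, making the
#' hub's neighborhood reachable from most random gene sets - the planted
#' topology-generic confounder.
#'
#' @param config A `synth_config`.
#' @param plant Internal layout from the planting step.
#' @param genes Gene table (spare genes supply decoy proteins).
#' @return List with `string` (scored edges), `proper` (unscored edges) and
#'   `ppin_level_of_gene` (named integer vector of planted levels).
#' @export
synth_ppin <- function(config, plant, genes) {
  cfg <- config
  chain_scores <- 0.95 - 0.05 * (seq_len(cfg$ppin_depth) - 1L)
  string <- list()
  for (j in 1:4) {
    prev <- plant$index_genes[j]
    for (k in seq_len(cfg$ppin_depth)) {
      g <- plant$chain_genes[j, k]
      string[[length(string) + 1L]] <- data.frame(
        protein_a = prev, protein_b = g, score = chain_scores[k],
        stringsAsFactors = FALSE)
      prev <- g
    }
  }
  spare <- setdiff(genes$gene_id,
                   c(plant$index_genes, plant$single_genes, plant$hub_gene))
  # decoy below the confidence cutoff: must not leak into the expansion
  string[[length(string) + 1L]] <- data.frame(
    protein_a = plant$index_genes[min(5L, cfg$n_index_genes)],
    protein_b = spare[1L], score = 0.5, stringsAsFactors = FALSE)
  # six-partner protein exercising the top-5 rule, disconnected from level 0
  topk_hub <- spare[2L]
  topk_partners <- spare[3:8]
  topk_scores <- c(0.95, 0.9, 0.85, 0.8, 0.75, 0.71)
  for (i in seq_along(topk_partners)) {
    string[[length(string) + 1L]] <- data.frame(
      protein_a = topk_hub, protein_b = topk_partners[i],
      score = topk_scores[i], stringsAsFactors = FALSE)
  }
  string <- do.call(rbind, string)
  proper <- rbind(
    data.frame(protein_a = plant$hub_gene, protein_b = plant$index_genes[1L],
               stringsAsFactors = FALSE),
    data.frame(protein_a = plant$hub_gene, protein_b = plant$hub_neighbors,
               stringsAsFactors = FALSE))
  lev <- c(stats::setNames(rep(0L, length(plant$index_genes)),
                           plant$index_genes),
           stats::setNames(rep(seq_len(cfg$ppin_depth), each = 4L),
                           as.vector(plant$chain_genes)),
           stats::setNames(1L, plant$hub_gene),
           stats::setNames(rep(2L, length(plant$hub_neighbors)),
                           plant$hub_neighbors))
  list(string = string, proper = proper, ppin_level_of_gene = lev)
}

#' Generate gene-disease associations and code-mapping tables
#'
#' Eight chain genes at levels 2..depth carry curated disease associations
#' whose CUIs map through ICD-10 to the planted comorbid patient codes;
#' additional rows exercise the source filter (a text-mined BEFREE record),
#' an unmapped CUI, and a CUI whose ICD-10 category fans out to two
#' ICD-10-AM codes.
#'
#' @param config A `synth_config`.
#' @param plant Internal layout from the planting step.
#' @return List with `gda`, `cui2icd10`, `icd10_2_icd10am`,
#'   `disease_genes`, and `planted_codes` (ICD-10-AM codes of the planted
#'   comorbid pairs).
#' @export
synth_gda_mappings <- function(config, plant) {
  cfg <- config
  depth_cols <- 2:cfg$ppin_depth
  pool <- as.vector(plant$chain_genes[, depth_cols, drop = FALSE])
  disease_genes <- pool[seq_len(min(8L, length(pool)))]
  planted_codes <- c("J41.0", "L20.9")
  gda <- data.frame(
    gene_id = c(disease_genes[1:4], disease_genes[5:8],
                disease_genes[1], disease_genes[2], disease_genes[3]),
    umls_cui = c(rep("C0000101", 4), rep("C0000102", 4),
                 "C0000103", "C0000104", "C0000105"),
    source = c("ClinGen", "Orphanet", "UniProt", "CTD_human",
               "GenomicsEnglandPanelApp", "CGI", "PsyGeNET", "ClinGen",
               "Orphanet", "UniProt", "BEFREE"),
    stringsAsFactors = FALSE)
  cui2icd10 <- data.frame(
    cui = c("C0000101", "C0000102", "C0000103", "C0000105", "C0000199"),
    icd10 = c("J41", "L20", "C92", "E11", "A00"),
    stringsAsFactors = FALSE)  # C0000104 deliberately unmapped
  icd10_2_icd10am <- data.frame(
    icd10 = c("J41", "L20", "C92", "C92", "E11"),
    icd10am = c("J41.0", "L20.9", "C92.40", "C92.41", "E11.9"),
    stringsAsFactors = FALSE)
  list(gda = gda, cui2icd10 = cui2icd10, icd10_2_icd10am = icd10_2_icd10am,
       disease_genes = disease_genes, planted_codes = planted_codes)
}

#' Generate long-format patient diagnosis records
#'
#' Each patient gets an age uniform on \[0, 110\] (so the over-100 exclusion
#' is exercised), a sex, an index-diagnosis indicator at
#' `index_prevalence`, planted comorbid codes whose conditional rates
#' realize `planted_or` against the index diagnosis, independent background
#' codes, a rare code carried by 3 patients (below the minimum-patient
#' filter), and a filler wellness code for patients with no other
#' diagnosis.
#'
#' @param config A `synth_config`.
#' @param index_code Index diagnosis code (default "J45.9").
#' @param comorbid_codes Codes receiving the planted odds ratio.
#' @return List with `patients` (data frame `patient_id`, `age`, `sex`,
#'   `code`) and `comorbid_code_pairs` (data frame `code_a`, `code_b`,
#'   `planted_or`).
#' @export
synth_patients <- function(config, index_code = "J45.9",
                           comorbid_codes = c("J41.0", "L20.9")) {
  cfg <- config
  n <- cfg$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  age <- floor(stats::runif(n, 0, 111))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  has <- list()
  has[[index_code]] <- stats::runif(n) < cfg$index_prevalence
  p0 <- 0.04
  odds1 <- cfg$planted_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  for (cd in comorbid_codes) {
    has[[cd]] <- stats::runif(n) <
      ifelse(has[[index_code]], p1, p0)
  }
  background <- c("E11.9", "I10", "K21.0", "M54.5", "N39.0", "R07.4",
                  "S72.0", "F32.9", "G40.9", "H25.1", "B34.9", "C92.40")
  for (cd in background) {
    has[[cd]] <- stats::runif(n) < stats::runif(1, 0.005, 0.05)
  }
  rare_idx <- sample.int(n, 3L)
  has[["Q87.1"]] <- seq_len(n) %in% rare_idx
  any_code <- Reduce(`|`, has)
  has[["Z00.0"]] <- !any_code
  rows <- lapply(names(has), function(cd) {
    idx <- which(has[[cd]])
    if (length(idx) == 0L) return(NULL)
    data.frame(patient_id = ids[idx], age = age[idx], sex = sex[idx],
               code = cd, stringsAsFactors = FALSE)
  })
  patients <- do.call(rbind, rows)
  patients <- patients[order(patients$patient_id, patients$code), ,
                       drop = FALSE]
  rownames(patients) <- NULL
  list(patients = patients,
       comorbid_code_pairs = data.frame(code_a = index_code,
                                        code_b = comorbid_codes,
                                        planted_or = cfg$planted_or,
                                        stringsAsFactors = FALSE))
}

#' Generate every pipeline input with a truth ledger
#'
#' Runs all generators in a fixed order from a single seeded stream and
#' writes the complete input set to `dir`: FASTA genome, annotation and
#' variant TSVs, contact records, genotype/expression/covariate matrices,
#' GWAS catalog, scored and unscored protein-interaction tables,
#' gene-disease and code-mapping tables, patient records, and a JSON truth
#' ledger recording every planted signal (eQTL pairs, PPIN levels, trait
#' SNP sets, comorbid code pairs, background contact pairs, site counts).
#' The same configuration yields byte-identical files.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `paths` (named file paths), `truth` (the
#'   ledger), and in-memory copies of the generated tables.
#' @export
synth_generate <- function(config, dir) {
  cfg <- config
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  gen <- synth_genome(cfg)
  gv <- .synth_genes_variants(cfg)
  plant <- .synth_plant(cfg, gen$genome, gv$genes, gv$variants)
  mats <- synth_genotypes_expression(cfg, gv$variants, gv$genes$gene_id,
                                     plant$true_eqtls)
  con <- synth_contacts(cfg, plant, gv$genes, gv$variants)
  gw <- synth_gwas(cfg, plant)
  pp <- synth_ppin(cfg, plant, gv$genes)
  gm <- synth_gda_mappings(cfg, plant)
  pat <- synth_patients(cfg)

  paths <- c(genome = "genome.fa", genes = "genes.tsv",
             variants = "variants.tsv", contacts = "contacts.tsv",
             genotypes = "genotypes.tsv", expression = "expression.tsv",
             covariates = "covariates.tsv", gwas = "gwas.tsv",
             ppin_string = "ppin_string.tsv", ppin_proper = "ppin_proper.tsv",
             gda = "gda.tsv", cui2icd10 = "cui2icd10.tsv",
             icd10_2_icd10am = "icd10_2_icd10am.tsv",
             patients = "patients.tsv", truth = "truth.json")
  paths <- stats::setNames(file.path(dir, paths), names(paths))

  dss <- Biostrings::DNAStringSet(gen$genome)
  Biostrings::writeXStringSet(dss, paths["genome"], width = 80L)
  genes_out <- gv$genes
  genes_out$start <- genes_out$start + 1L  # 1-based inclusive on disk
  write_tsv_strict(genes_out, paths["genes"])
  variants_out <- gv$variants
  variants_out$pos <- variants_out$pos + 1L
  write_tsv_strict(variants_out, paths["variants"])
  write_tsv_strict(con$contacts, paths["contacts"])
  write_matrix <- function(m, path) {
    df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_strict(df, path)
  }
  write_matrix(mats$genotypes, paths["genotypes"])
  write_matrix(round(mats$expression, 6), paths["expression"])
  write_matrix(mats$covariates, paths["covariates"])
  write_tsv_strict(gw$gwas, paths["gwas"])
  write_tsv_strict(pp$string, paths["ppin_string"])
  write_tsv_strict(pp$proper, paths["ppin_proper"])
  write_tsv_strict(gm$gda, paths["gda"])
  write_tsv_strict(gm$cui2icd10, paths["cui2icd10"])
  write_tsv_strict(gm$icd10_2_icd10am, paths["icd10_2_icd10am"])
  write_tsv_strict(pat$patients, paths["patients"])

  truth <- list(
    config = unclass(cfg),
    site_counts = gen$site_counts,
    true_eqtl_pairs = plant$true_eqtls,
    index_genes = plant$index_genes,
    seed_snps = plant$asthma_snps,
    trait_of_snp = gw$trait_of_snp,
    planted_traits = list(index = "Asthma",
                          level0_specific = "Eosinophil count",
                          hub_confounder = "Body mass index"),
    hub_gene = plant$hub_gene,
    hub_neighbors = plant$hub_neighbors,
    ppin_level_of_gene = as.list(pp$ppin_level_of_gene),
    cell_line_enzymes = as.list(con$cell_line_enzymes),
    noise_contact_pairs = con$noise_pairs,
    disease_genes = gm$disease_genes,
    planted_icd10am_codes = gm$planted_codes,
    comorbid_code_pairs = pat$comorbid_code_pairs)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, config = cfg,
                 tables = list(genes = gv$genes, variants = gv$variants,
                               contacts = con$contacts,
                               genotypes = mats$genotypes,
                               expression = mats$expression,
                               covariates = mats$covariates,
                               gwas = gw$gwas, string = pp$string,
                               proper = pp$proper, gda = gm$gda,
                               patients = pat$patients)))
}
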