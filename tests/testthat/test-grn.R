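test_that("eqtl_test equals the textbook simple-regression closed form", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    d <- stats::rbinom(n, 2, 0.3)
    if (stats::var(d) == 0) next
    y <- 0.5 * d + stats::rnorm(n)
    fit <- eqtl_test(d, y)
    # oracle: closed-form slope and SE
    b <- sum((d - mean(d)) * (y - mean(y))) / sum((d - mean(d))^2)
    res <- y - mean(y) - b * (d - mean(d))
    se <- sqrt(sum(res^2) / (n - 2) / sum((d - mean(d))^2))
    p <- 2 * stats::pt(-abs(b / se), n - 2)
    expect_equal(fit$beta, b, tolerance = 1e-12)
    expect_equal(fit$pvalue, p, tolerance = 1e-12)
  }
})

test_that("eqtl_test recovers the effect in the noiseless limit", {
  d <- rep(0:2, each = 20)
  y <- 5 + 1 * d
  fit <- eqtl_test(d, y + stats::rnorm(60, 0, 1e-10))
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_lt(fit$pvalue, 1e-200)
})

test_that("constant dosage or expression is flagged untestable", {
  expect_false(eqtl_test(rep(1, 40), stats::rnorm(40))$ok)
  expect_false(eqtl_test(stats::rbinom(40, 2, 0.5), rep(2, 40))$ok)
  expect_error(eqtl_test(0:1, 0:1), "samples")
})

test_that("under the null the raw p-values are uniform at the 5% level", {
  set.seed(31)
  n <- 60
  p <- replicate(1000, {
    d <- stats::rbinom(n, 2, 0.3)
    while (stats::var(d) == 0) d <- stats::rbinom(n, 2, 0.3)
    eqtl_test(d, stats::rnorm(n))$pvalue
  })
  frac <- mean(p < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(frac, 0.05 - tol)
  expect_lt(frac, 0.05 + tol)
})

test_that("covariate adjustment removes a confounded covariate effect", {
  set.seed(41)
  n <- 100
  sex <- stats::rbinom(n, 1, 0.5)
  d <- stats::rbinom(n, 2, 0.4)
  y <- 3 * sex + stats::rnorm(n)
  fit <- eqtl_test(d, y, covariates = cbind(sex = sex))
  fit0 <- eqtl_test(d, y)
  expect_true(fit$ok && fit0$ok)
  expect_lt(fit$se, fit0$se)  # adjusting for the real effect tightens SE
})

test_that("bh_adjust matches the step-up calculation and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(5)
  p <- stats::runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("interaction classification partitions all pairs", {
  expect_equal(classify_interaction(0, "chr1", 500000, "chr1")$interaction_type,
               "cis")
  expect_equal(classify_interaction(0, "chr1", 2000000, "chr1")$interaction_type,
               "trans-intra")
  expect_equal(classify_interaction(0, "chr1", 10, "chr2")$interaction_type,
               "trans-inter")
  # exactly 1 Mb is not < 1 Mb: trans-intra
  expect_equal(classify_interaction(0, "chr1", 1000000, "chr1")$interaction_type,
               "trans-intra")
  set.seed(13)
  cls <- classify_interaction(sample(1:5e6, 200), sample(c("chr1", "chr2"), 200, TRUE),
                              sample(1:5e6, 200), sample(c("chr1", "chr2"), 200, TRUE))
  expect_true(all(cls$interaction_type %in% c("cis", "trans-intra", "trans-inter")))
  expect_true(all(is.na(cls$distance) == (cls$interaction_type == "trans-inter")))
})

test_that("spatial pair support rules: replicates within one cell line, non-adjacency", {
  snp_loc <- list(MboI = data.frame(rsid = "rs1", chrom = "chr1",
                                    frag_idx = 10L))
  gene_loc <- list(MboI = data.frame(gene_id = "g1", chrom = "chr1",
                                     frag_idx = c(20L, 21L)))
  enz <- c(CLA = "MboI", CLB = "MboI")
  contact <- function(f2, cl, reps) {
    data.frame(chrom1 = "chr1", frag1_idx = 10L, chrom2 = "chr1",
               frag2_idx = f2, cell_line = cl, replicate = reps)
  }
  # one replicate only: absent
  expect_equal(nrow(spatial_pairs(contact(20L, "CLA", 1L), snp_loc, gene_loc, enz)), 0L)
  # two replicates in one cell line: present
  got <- spatial_pairs(contact(20L, "CLA", 1:2), snp_loc, gene_loc, enz)
  expect_equal(got$snp, "rs1")
  expect_equal(got$gene, "g1")
  # one replicate in each of two cell lines: absent (support must be internal)
  cc <- rbind(contact(20L, "CLA", 1L), contact(20L, "CLB", 1L))
  expect_equal(nrow(spatial_pairs(cc, snp_loc, gene_loc, enz)), 0L)
  # adjacent fragments, three replicates: absent
  snp_adj <- list(MboI = data.frame(rsid = "rs1", chrom = "chr1",
                                    frag_idx = 19L))
  expect_equal(nrow(spatial_pairs(contact(20L, "CLA", 1:3), snp_adj, gene_loc, enz)), 0L)
  # same fragments on different chromosomes are not adjacent
  gene_chr2 <- list(MboI = data.frame(gene_id = "g1", chrom = "chr2",
                                      frag_idx = 10L))
  cc2 <- data.frame(chrom1 = "chr1", frag1_idx = 10L, chrom2 = "chr2",
                    frag2_idx = 10L, cell_line = "CLA", replicate = 1:2)
  expect_equal(nrow(spatial_pairs(cc2, snp_loc, gene_chr2, enz)), 1L)
  # gene supported through either of its overlapping fragments
  got <- spatial_pairs(contact(21L, "CLA", 1:2), snp_loc, gene_loc, enz)
  expect_equal(got$gene, "g1")
})

test_that("GRN recovers planted eQTLs with controlled false edges", {
  sim <- synth_fixture()
  grn <- grn_fixture()
  truth_key <- paste(sim$truth$true_eqtl_pairs$snp,
                     sim$truth$true_eqtl_pairs$gene)
  edge_key <- paste(grn$edges$snp, grn$edges$gene)
  recovered <- mean(truth_key %in% edge_key)
  expect_gte(recovered, 0.95)
  false_edges <- sum(!edge_key %in% truth_key)
  expect_lte(false_edges / grn$n_tested, 0.05)
  # every stored edge is significant and classified consistently
  expect_true(all(grn$edges$adj_pvalue <= 0.05))
  expect_true(all(grn$edges$adj_pvalue >= grn$edges$pvalue))
  expect_true(all(is.na(grn$edges$distance) ==
                    (grn$edges$interaction_type == "trans-inter")))
  expect_false(any(duplicated(edge_key)))
})

test_that("edge index maps round-trip the edge set", {
  grn <- grn_fixture()
  for (ix in list(grn_by_snp(grn), grn_by_gene(grn))) {
    back <- do.call(rbind, unname(ix))
    back <- back[order(back$snp, back$gene), ]
    ed <- grn$edges[order(grn$edges$snp, grn$edges$gene), ]
    rownames(back) <- rownames(ed) <- NULL
    expect_equal(back, ed)
  }
})

test_that("empty contacts give an empty GRN and replicate loss deletes an edge", {
  sim <- synth_fixture()
  p <- sim$paths
  contacts <- read_contacts(p[["contacts"]])
  empty <- build_grn(p[["genome"]], p[["genes"]], p[["variants"]],
                     contacts[0, ], p[["genotypes"]], p[["expression"]],
                     covariates = p[["covariates"]])
  expect_equal(nrow(empty$edges), 0L)

  # drop all but one replicate of one planted pair's contacts
  grn <- grn_fixture()
  pair <- sim$truth$true_eqtl_pairs[1, ]
  v <- read_variants(p[["variants"]])
  g <- read_genes(p[["genes"]])
  # identify contact rows touching the pair's SNP fragment on either side
  spos <- v$pos[v$rsid == pair$snp]
  schrom <- v$chrom[v$rsid == pair$snp]
  genome <- read_genome(p[["genome"]])
  drop <- rep(FALSE, nrow(contacts))
  for (enz in c("HindIII", "MboI")) {
    fr <- digest_sequence(genome[[schrom]], enz)
    sf <- locate_position(spos, fr)
    cls <- grep(enz, unique(contacts$cell_line), value = TRUE)
    hit <- contacts$cell_line %in% cls & contacts$replicate > 1 &
      ((contacts$chrom1 == schrom & contacts$frag1_idx == sf) |
         (contacts$chrom2 == schrom & contacts$frag2_idx == sf))
    drop <- drop | hit
  }
  reduced <- contacts[!drop, ]
  grn2 <- build_grn(p[["genome"]], p[["genes"]], p[["variants"]], reduced,
                    p[["genotypes"]], p[["expression"]],
                    covariates = p[["covariates"]])
  key2 <- paste(grn2$edges$snp, grn2$edges$gene)
  expect_false(paste(pair$snp, pair$gene) %in% key2)
  expect_true(paste(pair$snp, pair$gene) %in%
                paste(grn$edges$snp, grn$edges$gene))
})
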