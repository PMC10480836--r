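test_that("hypergeometric tail matches draw enumeration on a small case", {
  # oracle: enumerate all C(10,5) draws and count those with >= 2 successes
  M <- 10; n <- 4; N <- 5; x <- 2
  pop <- c(rep(1, n), rep(0, M - n))
  draws <- utils::combn(M, N)
  hits <- sum(apply(draws, 2, function(ix) sum(pop[ix]) >= x))
  expect_equal(hits / ncol(draws), 186 / 252)
  expect_equal(hypergeom_sf(x, N, n, M), 186 / 252, tolerance = 1e-12)
})

test_that("hypergeometric tail agrees with counting and phyper oracles", {
  for (M in c(3, 7, 12, 20, 25)) {
    for (n in c(0, 1, M %/% 2, M)) {
      for (N in c(1, M %/% 3 + 1, M)) {
        for (x in 0:min(n, N)) {
          got <- hypergeom_sf(x, N, n, M)
          expect_equal(got, count_tail_oracle(x, N, n, M),
                       tolerance = 1e-12,
                       label = sprintf("sf(%d;%d,%d,%d)", x, N, n, M))
          # independent library route
          expect_equal(got,
                       stats::phyper(x - 1, n, M - n, N, lower.tail = FALSE),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("tail probability boundaries and monotonicity hold", {
  expect_identical(hypergeom_sf(0, 5, 4, 10), 1)
  expect_warning(p <- hypergeom_sf(5, 4, 4, 10), "min")
  expect_equal(p, 0)
  expect_error(hypergeom_sf(-1, 5, 4, 10), "non-negative")
  expect_error(hypergeom_sf(1, 5, 11, 10), "exceed")
  set.seed(3)
  for (rep in 1:20) {
    M <- sample(5:40, 1); n <- sample(1:M, 1); N <- sample(1:M, 1)
    xs <- 0:min(n, N)
    sf <- vapply(xs, hypergeom_sf, numeric(1), N = N, n = n, M = M)
    # below the attainable minimum success count the tail is flat at 1;
    # on the support it decreases strictly
    lo <- max(0L, N - (M - n))
    expect_true(all(sf[xs < lo] == 1))
    on_support <- sf[xs >= lo]
    expect_true(all(diff(on_support) < 0))
    # successive differences reconstruct a normalized pmf
    pmf <- c(-diff(sf), sf[length(sf)])
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    expect_true(all(pmf >= -1e-12))
  }
})

test_that("per-level enrichment computes x, N, n, M and is order-invariant", {
  cat <- gwas_catalog(data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    trait = c("T1", "T1", "T1", "T2", "T2", "T3"),
    pvalue = 1e-8, stringsAsFactors = FALSE))
  eq <- c("rs1", "rs2", "rs9")  # rs9 not in the catalog: counts in N only
  enr <- enrich_level(eq, cat, level = 0)
  expect_equal(enr$trait, "T1")  # T2, T3 absent from the level: not reported
  expect_equal(enr$x, 2L)
  expect_equal(enr$N, 3L)
  expect_equal(enr$n, 3L)
  expect_equal(enr$M, 6L)
  expect_equal(enr$pvalue, hypergeom_sf(2, 3, 3, 6))
  # boundary x = N
  enr2 <- enrich_level(c("rs1", "rs2"), cat, level = 0)
  expect_equal(enr2$x, enr2$N)
  # shuffling catalog rows and eQTL order changes nothing
  set.seed(8)
  cat2 <- gwas_catalog(cat$records[sample(nrow(cat$records)), ])
  enr3 <- enrich_level(sample(eq), cat2, level = 0)
  expect_equal(enr3, enr)
  expect_equal(nrow(enrich_level(character(0), cat)), 0L)
})

test_that("random trait assignment keeps the raw significance rate at bay", {
  set.seed(19)
  n_sig <- 0L
  n_tot <- 0L
  for (rep in 1:300) {
    M <- 400
    rsids <- sprintf("rs%03d", 1:M)
    cat <- gwas_catalog(data.frame(
      rsid = rsids,
      trait = sample(sprintf("T%d", 1:8), M, replace = TRUE),
      pvalue = 1e-8, stringsAsFactors = FALSE))
    eq <- sample(rsids, 30)
    enr <- enrich_level(eq, cat, level = 0)
    n_sig <- n_sig + sum(enr$pvalue < 0.05)
    n_tot <- n_tot + nrow(enr)
  }
  frac <- n_sig / n_tot
  # discrete tail p-values are conservative: the rate must not exceed nominal
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tot))
  expect_gt(frac, 0)
})

test_that("Monte Carlo null is reproducible and vetoes the hub confounder", {
  sim <- synth_fixture()
  grn <- grn_fixture()
  lf <- levels_fixture()
  mc1 <- monte_carlo_null(grn, lf$string_raw, lf$proper, lf$catalog,
                          set_size = length(lf$lev0$genes), n_iter = 5,
                          seed = 123)
  mc2 <- monte_carlo_null(grn, lf$string_raw, lf$proper, lf$catalog,
                          set_size = length(lf$lev0$genes), n_iter = 5,
                          seed = 123)
  expect_identical(mc1, mc2)
  expect_error(monte_carlo_null(grn, lf$string_raw, lf$proper, lf$catalog,
                                set_size = 1e6, n_iter = 1, seed = 1),
               "universe")

  mc <- monte_carlo_null(grn, lf$string_raw, lf$proper, lf$catalog,
                         set_size = length(lf$lev0$genes), n_iter = 200,
                         seed = 2024)
  enr <- enrich_levels(lf$levels, lf$catalog)
  verdict <- final_verdict(enr, mc, levels = lf$levels, grn = grn,
                           catalog = lf$catalog)
  hub <- sim$truth$planted_traits$hub_confounder
  specific <- sim$truth$planted_traits$level0_specific
  # the hub-planted trait is enriched somewhere but vetoed by topology
  expect_true(any(enr$trait == hub & enr$adj_pvalue < 0.05))
  expect_false(hub %in% verdict$trait)
  hub_freq <- mc$mc_frequency[mc$trait == hub &
                                mc$level %in% enr$level[enr$trait == hub &
                                                          enr$adj_pvalue < 0.05]]
  expect_true(any(hub_freq >= 0.05))
  # the level-0-specific trait survives
  expect_true(specific %in% verdict$trait)
  triples <- attr(verdict, "triples")
  expect_true(all(triples$rsid %in% grn$edges$snp))
  expect_true(all(triples$gene %in% grn$edges$gene))
})

test_that("final verdict combines enrichment and Monte Carlo rules", {
  enr <- data.frame(trait = c("A", "B", "C"), level = 1L, x = 1L, N = 1L,
                    n = 1L, M = 10L, pvalue = c(0.01, 0.20, 0.001),
                    adj_pvalue = c(0.01, 0.20, 0.001),
                    stringsAsFactors = FALSE)
  mc <- data.frame(trait = c("A", "C"), level = 1L,
                   mc_frequency = c(0.30, 0.002), stringsAsFactors = FALSE)
  v <- final_verdict(enr, mc)
  expect_equal(v$trait, "C")  # A: topology-generic; B: not enriched
  expect_true(all(v$passes))
  # a trait absent from the MC table has frequency zero
  enr2 <- data.frame(trait = "D", level = 2L, x = 1L, N = 1L, n = 1L,
                     M = 10L, pvalue = 0.01, adj_pvalue = 0.01,
                     stringsAsFactors = FALSE)
  v2 <- final_verdict(enr2, mc)
  expect_equal(v2$mc_frequency, 0)
  expect_true(v2$passes)
})
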