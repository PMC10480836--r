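# Shared synthetic fixture, generated once per test run and cached.
# seed 42 is the fixture's study condition; the small config keeps the
# suite fast while satisfying the planted-layout constraints.

synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "grntraits-fixture")
      cfg <- synth_config(seed = 42)
      cache <<- synth_generate(cfg, dir)
    }
    cache
  }
})

grn_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- synth_fixture()
      p <- sim$paths
      cache <<- build_grn(p[["genome"]], p[["genes"]], p[["variants"]],
                          p[["contacts"]], p[["genotypes"]],
                          p[["expression"]],
                          covariates = p[["covariates"]],
                          tissue = "synthetic")
    }
    cache
  }
})

levels_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- synth_fixture()
      p <- sim$paths
      grn <- grn_fixture()
      catalog <- gwas_catalog(p[["gwas"]])
      seeds <- select_seed_snps(catalog, "Asthma")
      lev0 <- grn_level0(grn, seeds)
      fs <- filter_string_edges(read_string_edges(p[["ppin_string"]]))
      proper <- read_proper_edges(p[["ppin_proper"]])
      cache <<- list(
        catalog = catalog, seeds = seeds, lev0 = lev0,
        string_raw = read_string_edges(p[["ppin_string"]]),
        string = fs, proper = proper,
        levels = expand_levels(lev0, fs, proper, depth = 4, grn = grn))
    }
    cache
  }
})

# small configuration for tests that regenerate data repeatedly
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chrom = 1L, chrom_len = 200000L,
               n_genes = 80L, n_snps = 120L, n_samples = 40L,
               n_true_eqtls = 60L, n_hub_neighbors = 20L,
               n_patients = 500L, n_background_snps = 200L)
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}

# naive substring-scan digestion oracle, independent of digest_sequence()
naive_digest <- function(s, site, offset) {
  len <- nchar(s)
  cuts <- integer(0)
  i <- 1L
  w <- nchar(site)
  while (i + w - 1L <= len) {
    if (substr(s, i, i + w - 1L) == site) cuts <- c(cuts, i - 1L + offset)
    i <- i + 1L
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
  cbind(start = c(0L, cuts), end = c(cuts, len))
}

# exact hypergeometric tail oracle by counting draws with choose()
count_tail_oracle <- function(x, N, n, M) {
  if (x == 0) return(1)
  total <- choose(M, N)
  hits <- 0
  for (i in x:min(n, N)) {
    if (N - i <= M - n) hits <- hits + choose(n, i) * choose(M - n, N - i)
  }
  hits / total
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
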