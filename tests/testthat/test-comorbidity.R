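mk_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], age = as.numeric(r[[2]]), sex = "F",
               code = r[[3]], stringsAsFactors = FALSE)
  }))
}

# patients fixture with exact counts: 5 both, 5 index-only, 15 candidate-only,
# 75 neither (carrying a filler code so they appear in the records)
fixture_sets <- function() {
  rows <- list()
  add <- function(ids, code) {
    for (i in ids) rows[[length(rows) + 1L]] <<- list(sprintf("P%03d", i), 50, code)
  }
  add(1:10, "A00")          # index patients: 1..10
  add(1:5, "B00")           # both: 1..5
  add(11:25, "B00")         # candidate only: 11..25
  add(26:100, "Z99")        # neither
  patient_code_sets(do.call(mk_records, rows))
}

test_that("age filter, boundary, and deduplication follow the cohort rules", {
  rec <- mk_records(list("P1", 101, "A00"), list("P2", 100, "A00"),
                    list("P3", 40, "B00"), list("P3", 40, "B00"),
                    list("P4", 99, "A00"))
  ps <- patient_code_sets(rec)
  expect_equal(ps$n, 3L)              # P1 excluded (strictly over 100)
  expect_equal(ps$n_excluded_age, 1L)
  expect_true("P2" %in% names(ps$sets))  # exactly 100 retained
  expect_equal(ps$sets[["P3"]], "B00")   # duplicates collapse
  # malformed rows are skipped and counted
  bad <- rbind(rec, data.frame(patient_id = "P9", age = "old", sex = "F",
                               code = "A00", stringsAsFactors = FALSE))
  expect_equal(patient_code_sets(bad)$n_malformed, 1L)
})

test_that("the 2x2 partition uses exclusive counts and sums to N", {
  ps <- fixture_sets()
  ct <- count_2x2(ps, "A00", "B00")
  expect_equal(ct$C_A, 5L)
  expect_equal(ct$C_B, 15L)
  expect_equal(ct$C_AB, 5L)
  expect_equal(ct$H, 75L)
  expect_equal(ct$C_A + ct$C_B + ct$C_AB + ct$H, ct$N)
  expect_equal(ct$P_A, 0.1)
  expect_equal(ct$P_B, 0.2)
  expect_error(count_2x2(ps, "A00", "A00"), "index")
  expect_error(count_2x2(ps, "ZZZ", "B00"), "absent")
  # random partitions always sum to N
  set.seed(12)
  for (rep in 1:10) {
    rows <- lapply(1:50, function(i)
      list(sprintf("Q%03d", i), 30,
           sample(c("A00", "B00", "C00"), 1)))
    ps2 <- patient_code_sets(do.call(mk_records, rows))
    if (!any(vapply(ps2$sets, function(s) "A00" %in% s, logical(1)))) next
    ct2 <- try(count_2x2(ps2, "A00", "B00"), silent = TRUE)
    if (inherits(ct2, "try-error")) next
    expect_equal(ct2$C_A + ct2$C_B + ct2$C_AB + ct2$H, ct2$N)
  }
})

test_that("odds ratio, relative risk and score match hand arithmetic", {
  ps <- fixture_sets()
  ct <- count_2x2(ps, "A00", "B00")
  or <- odds_ratio(ct)
  expect_equal(or$or, 5 * 75 / (5 * 15))  # = 5.0
  expect_true(or$ci_low < or$or && or$or < or$ci_high)
  expect_equal(relative_risk(ct), 5 / (100 * 0.1 * 0.2))  # = 2.5
  expect_equal(comorbidity_score(ct), log2((5 + 1) / (100 * 0.1 * 0.2 + 1)))

  # independence-constructed table: OR = 1, RR = 1, score ~ 0
  ind <- structure(list(code = "B", C_A = 16L, C_B = 36L, C_AB = 4L,
                        H = 144L, N = 200L, P_A = 0.1, P_B = 0.2),
                   class = "comorbidity_counts")
  expect_equal(odds_ratio(ind)$or, 1)
  expect_equal(relative_risk(ind), 1)
  expect_equal(comorbidity_score(ind), 0)

  # Haldane smoothing engages only on zero cells
  z <- structure(list(code = "B", C_A = 10L, C_B = 5L, C_AB = 0L, H = 85L,
                      N = 100L, P_A = 0.1, P_B = 0.05),
                 class = "comorbidity_counts")
  expect_equal(odds_ratio(z)$or, (0.5 * 85.5) / (10.5 * 5.5))
  expect_error(relative_risk(structure(list(C_AB = 0, N = 10, P_A = 0,
                                            P_B = 0.5),
                                       class = "comorbidity_counts")),
               "undefined")

  # linearity and monotonicity
  ct2 <- ct; ct2$C_AB <- 2L * ct$C_AB
  expect_equal(relative_risk(ct2), 2 * relative_risk(ct))
  expect_gt(comorbidity_score(ct2), comorbidity_score(ct))
})

test_that("the comorbidity screen excludes rare codes and finds planted pairs", {
  sim <- synth_fixture()
  com <- comorbidity(sim$paths[["patients"]], "J45.9")
  expect_false("Q87.1" %in% com$table$code)  # 3 carriers: below the minimum
  planted <- sim$truth$comorbid_code_pairs$code_b
  sig <- com$table$code[com$table$qvalue < 0.05]
  expect_true(all(planted %in% sig))
  expect_true(all(com$table$or[com$table$code %in% planted] > 1))
  # independent background codes are not called positive comorbidities
  background <- c("E11.9", "I10", "K21.0", "M54.5")
  expect_false(any(background %in% sig))
  expect_true(all(com$table$qvalue >= com$table$pvalue))
  # partition invariant on every retained row
  expect_true(all(com$table$C_A + com$table$C_B + com$table$C_AB +
                    com$table$H == com$n_patients))
})

test_that("Fisher p is invariant to consistent row/column swaps", {
  m <- matrix(c(5, 10, 15, 70), 2)
  p1 <- stats::fisher.test(m)$p.value
  p2 <- stats::fisher.test(t(m))$p.value
  p3 <- stats::fisher.test(m[2:1, 2:1])$p.value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("overlap test matches the exact hypergeometric tail", {
  # disjoint sets in a large universe: no evidence of overlap
  ov <- overlap_test(c("A00", "B00"), c("C00", "D00"), 500)
  expect_equal(length(ov$overlap), 0L)
  expect_gt(ov$p, 0.5)
  # identical non-trivial sets: strong overlap
  ov2 <- overlap_test(sprintf("A%02d", 1:10), sprintf("A%02d", 1:10), 500)
  expect_equal(length(ov2$overlap), 10L)
  expect_lt(ov2$p, 1e-10)
  # the published-scale configuration against a tail-sum oracle
  U <- 500
  a <- sprintf("X%03d", 1:194)
  b <- c(sprintf("X%03d", 1:9), sprintf("Y%03d", 1:44))
  ov3 <- overlap_test(a, b, U, code_level = "full")
  oracle <- sum(vapply(9:53, function(i)
    choose(53, i) * choose(U - 53, 194 - i), numeric(1))) / choose(U, 194)
  expect_equal(ov3$p, oracle, tolerance = 1e-10)
  expect_error(overlap_test(a, b, 100, code_level = "full"), "universe")
})

test_that("null patient records stay below the nominal error rate", {
  set.seed(77)
  pvals <- numeric(0)
  for (s in 1:30) {
    pat <- synth_patients(synth_config(seed = 1, planted_or = 1,
                                       n_patients = 800))
    sets <- patient_code_sets(pat$patients, max_age = Inf)
    # every non-filler candidate code is independent of the index here
    codes <- setdiff(sort(unique(pat$patients$code)), c("J45.9", "Z00.0"))
    for (cd in codes) {
      ct <- count_2x2(sets, "J45.9", cd)
      if (ct$C_B + ct$C_AB < 6) next
      pvals <- c(pvals, stats::fisher.test(
        matrix(c(ct$C_AB, ct$C_A, ct$C_B, ct$H), 2))$p.value)
    }
  }
  expect_gt(length(pvals), 200)
  expect_lte(mean(pvals < 0.05),
             0.05 + 3 * sqrt(0.05 * 0.95 / length(pvals)))
  expect_lte(mean(bh_adjust(pvals) < 0.05), 0.01)
})
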