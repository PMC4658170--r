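test_that("region restriction keeps only fully contained key spans", {
  regions <- region_set("chr1", 50, 150)
  inside <- snv_callset("a", "chr1", 100)
  expect_length(restrict_to_regions(inside, regions), 1)

  # deletion span 149-151 exits the interval and is excluded
  del <- callset("d", variant("chr1", 148, "AGCT", "A"))
  k <- variant_keys(del)
  expect_equal(c(k$start, k$end), c(149L, 151L))
  expect_length(restrict_to_regions(del, regions), 0)
  # brute-force containment check agrees
  expect_false(any(sapply(list(c(50, 150)), function(iv)
    k$start >= iv[1] && k$end <= iv[2])))

  # empty region set removes everything
  expect_length(restrict_to_regions(inside, region_set(character(0), integer(0), integer(0))), 0)
})

test_that("restriction never grows a callset and is the identity when contained", {
  set.seed(21)
  ref <- generate_reference(30000, seed = 21)
  truth <- generate_truth_set(ref, 150, 20, 20, seed = 21)
  regions <- generate_regions(ref, 0.6, 0.5, seed = 21)$confident
  r <- restrict_to_regions(truth, regions)
  expect_lte(length(r), length(truth))
  whole <- region_set("chrS", 1, 30000)
  expect_equal(length(restrict_to_regions(truth, whole)), length(truth))
})

test_that("truth matching has set semantics and respects the allele mode", {
  calls <- snv_callset("c", "chr1", c(10, 20, 30))
  truth <- snv_callset("truth", "chr1", c(20, 30, 40))
  m <- match_against_truth(calls, truth)
  expect_setequal(m$tp_keys, c("SNV:chr1:20-20", "SNV:chr1:30-30"))
  expect_setequal(m$fp_keys, "SNV:chr1:10-10")
  expect_setequal(m$matched_truth_keys, m$tp_keys)
  # partition: tp and fp are disjoint and exhaust the callset
  expect_length(intersect(m$tp_keys, m$fp_keys), 0)
  expect_setequal(c(m$tp_keys, m$fp_keys), unique(variant_keys(calls)$key))

  # identity gives no false positives
  m2 <- match_against_truth(calls, calls)
  expect_length(m2$fp_keys, 0)

  # same coordinate, different alt: TP in coords mode, FP in strict mode
  c3 <- callset("x", variant("chr1", 100, "A", "T", qual = 50))
  t3 <- callset("truth", variant("chr1", 100, "A", "G"))
  expect_length(match_against_truth(c3, t3)$tp_keys, 1)
  expect_length(match_against_truth(c3, t3, mode = "strict")$tp_keys, 0)
})

test_that("false rates follow their definitions and flag empty denominators", {
  # 3 calls in regions, 2 matching; 4 eligible truth, 2 matched
  calls <- snv_callset("c", "chr1", c(10, 20, 99))
  truth <- snv_callset("truth", "chr1", c(10, 20, 30, 40))
  conf <- region_set("chr1", 1, 1000)
  r <- false_rates(calls, truth, conf)
  expect_equal(r$n_calls_in_regions, 3)
  expect_equal(r$n_tp + r$n_fp, r$n_calls_in_regions)
  expect_equal(r$fp_rate, 1 / 3)
  expect_equal(r$fn_rate, 2 / 4)

  # calls identical to eligible truth
  r0 <- false_rates(truth, truth, conf)
  expect_equal(c(r0$fp_rate, r0$fn_rate), c(0, 0))

  # empty truth: all calls FP, warn, flagged
  empty_truth <- callset("truth")
  expect_warning(re <- false_rates(calls, empty_truth, conf), "no eligible truth")
  expect_equal(re$fp_rate, 1)
  expect_true(re$flagged)

  # FN denominator restricted to the narrower region set
  fnr <- region_set("chr1", 25, 1000)
  r2 <- false_rates(calls, truth, conf, fnr)
  expect_equal(r2$n_truth_eligible, 2)   # truth at 30, 40
  expect_equal(r2$fn_rate, 1)            # neither called
})

test_that("adding truth never increases FP and adding calls never increases FN", {
  set.seed(31)
  conf <- region_set("chr1", 1, 10000)
  pos_truth <- sample(10:9990, 200)
  pos_calls <- sample(10:9990, 200)
  calls <- snv_callset("c", "chr1", pos_calls)
  truth <- snv_callset("t", "chr1", pos_truth)
  base <- false_rates(calls, truth, conf)
  more_truth <- snv_callset("t", "chr1", unique(c(pos_truth, sample(10:9990, 50))))
  expect_lte(false_rates(calls, more_truth, conf)$n_fp, base$n_fp)
  more_calls <- snv_callset("c", "chr1", unique(c(pos_calls, sample(10:9990, 50))))
  expect_lte(false_rates(more_calls, truth, conf)$n_fn, base$n_fn)
})

test_that("measured rates recover the generator's sensitivity and FP load", {
  set.seed(41)
  ref <- generate_reference(150000, seed = 41)
  truth <- generate_truth_set(ref, 2200, 150, 150, seed = 41)
  n_truth <- length(truth)
  sens <- 0.9; fp_frac <- 0.05
  prof <- callset_profile(sensitivity = sens,
                          fp_count = fp_frac / (1 - fp_frac) * n_truth * sens,
                          indel_jitter = 0.3, seed = 42)
  cs <- generate_callset(truth, prof, ref)
  cs <- suppressMessages(dedup_callset(regularize(cs, ref)))
  conf <- region_set("chrS", 1, 150000)
  r <- false_rates(cs, truth, conf)
  se_fn <- sqrt((1 - sens) * sens / n_truth)
  expect_lt(abs(r$fn_rate - (1 - sens)), 3 * se_fn)
  se_fp <- sqrt(fp_frac * (1 - fp_frac) / r$n_calls_in_regions)
  expect_lt(abs(r$fp_rate - fp_frac), 3 * se_fp)
})

test_that("tool-specific variants are exactly the singleton keys", {
  A <- snv_callset("A", "chr1", c(10, 20))
  B <- snv_callset("B", "chr1", c(20, 30))
  C <- snv_callset("C", "chr1", 30)
  sp <- tool_specific_variants(list(A, B, C))
  expect_equal(sort(sp$A$variants$pos), 10L)
  expect_length(sp$B, 0)
  expect_length(sp$C, 0)
  # brute-force occurrence count oracle
  all_keys <- c(variant_keys(A)$key, variant_keys(B)$key, variant_keys(C)$key)
  singles <- names(table(all_keys))[table(all_keys) == 1]
  expect_setequal(variant_keys(sp$A)$key, intersect(variant_keys(A)$key, singles))

  # identical callsets have empty specific sets; disjoint ones keep everything
  sp2 <- tool_specific_variants(list(A, snv_callset("A2", "chr1", c(10, 20))))
  expect_length(sp2$A, 0)
  D <- snv_callset("D", "chr1", c(100, 200))
  sp3 <- tool_specific_variants(list(A, D))
  expect_length(sp3$D, 2)
  expect_error(tool_specific_variants(list(A, snv_callset("A", "chr1", 1))), "unique")
})
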