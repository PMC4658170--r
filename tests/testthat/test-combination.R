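test_that("union and intersection have key-level set semantics", {
  A <- snv_callset("A", "chr1", c(10, 20), gq = c(50, 50))
  B <- snv_callset("B", "chr1", c(20, 30), gq = c(80, 60))
  u <- union_callsets(list(A, B))
  expect_setequal(variant_keys(u)$key,
                  c("SNV:chr1:10-10", "SNV:chr1:20-20", "SNV:chr1:30-30"))
  i <- intersect_callsets(list(A, B))
  expect_equal(variant_keys(i)$key, "SNV:chr1:20-20")
  # union keeps the highest-GQ record for a shared key
  expect_equal(u$variants$gq[u$variants$pos == 20], 80)

  # single callset: both are the identity
  expect_equal(variant_keys(union_callsets(list(A)))$key, variant_keys(A)$key)
  expect_equal(variant_keys(intersect_callsets(list(A)))$key, variant_keys(A)$key)
  # disjoint sets: empty intersection
  expect_length(intersect_callsets(list(A, snv_callset("C", "chr1", 99))), 0)
})

test_that("detection frequency equals a brute-force membership tally", {
  set.seed(17)
  positions <- seq(10, 2000, by = 10)
  sets <- lapply(1:5, function(i)
    snv_callset(paste0("s", i), "chr1", sample(positions, 120)))
  freqs <- detection_frequency(sets)
  # exhaustive recount
  keysets <- lapply(sets, function(s) variant_keys(s)$key)
  for (k in names(freqs)) {
    expect_equal(freqs[[k]], sum(vapply(keysets, function(ks) k %in% ks, logical(1))))
  }
  expect_true(all(freqs >= 1 & freqs <= 5))
})

test_that("frequency bins partition the union and report shares as printed percentages", {
  A <- snv_callset("A", "chr1", c(10, 20, 30), gq = 50)
  B <- snv_callset("B", "chr1", c(10, 20, 40), gq = 50)
  C <- snv_callset("C", "chr1", c(10, 50), gq = 50)
  truth <- snv_callset("truth", "chr1", c(10, 20, 30))
  conf <- region_set("chr1", 1, 100)
  bins <- frequency_bins(list(A, B, C), truth, conf)
  b <- function(x) bins[bins$bin == x, ]
  expect_equal(b("union")$n, 5)
  expect_equal(b("intersection")$n, 1)   # pos 10
  expect_equal(b("middle")$n, 1)         # pos 20
  expect_equal(b("singleton")$n, 3)      # 30, 40, 50
  expect_equal(b("intersection")$n + b("middle")$n + b("singleton")$n, b("union")$n)
  expect_equal(b("intersection")$pct_of_union, 20)
  expect_equal(b("singleton")$fp_rate, 2 / 3)
  expect_true(is.na(b("middle")$fn_rate))

  # all sources identical: middle and singleton empty, intersection == union
  same <- lapply(1:3, function(i) snv_callset(paste0("i", i), "chr1", c(10, 20)))
  bins2 <- frequency_bins(same, truth, conf)
  expect_equal(bins2[bins2$bin == "middle", "n"], 0)
  expect_equal(bins2[bins2$bin == "singleton", "n"], 0)
  expect_equal(bins2[bins2$bin == "intersection", "n"],
               bins2[bins2$bin == "union", "n"])
})

test_that("detection shares reproduce published-style two-decimal rounding", {
  # deletions binned 9-of-9 / 2-8 / exactly-1 out of a 4194-call union
  expect_equal(detection_share(1158, 4194), 27.61)
  expect_equal(detection_share(2326, 4194), 55.46)
  expect_equal(detection_share(710, 4194), 16.93)
  # insertions out of 5524
  expect_equal(detection_share(1415, 5524), 25.62)
  expect_equal(detection_share(2612, 5524), 47.28)
  expect_equal(detection_share(1497, 5524), 27.10)
})

test_that("percent excess matches integer half-up rounding on call counts", {
  expect_equal(percent_excess(229215, 168348), 36)
  expect_equal(percent_excess(4856, 2140), 127)
  expect_equal(percent_excess(100, 100), 0)
  expect_error(percent_excess(10, 0), "positive")
})

test_that("three-way Venn counts match an exhaustive pattern tally", {
  # identical sets: everything in the center
  A <- snv_callset("A", "chr1", 1:5 * 10)
  vi <- venn_counts(list(A, snv_callset("B", "chr1", 1:5 * 10),
                         snv_callset("C", "chr1", 1:5 * 10)))
  expect_equal(unname(vi$counts[["111"]]), 5)
  expect_equal(sum(vi$counts), 5)
  expect_equal(vi$pct_unanimous, 100)

  # pairwise disjoint: only the three exclusive regions
  vd <- venn_counts(list(snv_callset("A", "chr1", c(10, 20)),
                         snv_callset("B", "chr1", 30),
                         snv_callset("C", "chr1", c(40, 50, 60))))
  expect_equal(unname(vd$counts[c("100", "010", "001")]), c(2, 1, 3))
  expect_equal(sum(vd$counts[c("110", "101", "011", "111")]), 0)

  # random triple against brute force
  set.seed(23)
  pools <- lapply(1:3, function(i) sample(seq(10, 990, 10), 40))
  sets <- lapply(1:3, function(i) snv_callset(paste0("s", i), "chr1", pools[[i]]))
  v <- venn_counts(sets)
  keys <- lapply(sets, function(s) variant_keys(s)$key)
  all_k <- unique(unlist(keys))
  pat <- sapply(all_k, function(k)
    paste(as.integer(vapply(keys, function(ks) k %in% ks, logical(1))), collapse = ""))
  for (p in names(v$counts)) expect_equal(unname(v$counts[[p]]), sum(pat == p))
  expect_error(venn_counts(sets[1:2]), "three")
})

test_that("ROC sweep behaves at the edges and on separable scores", {
  conf_positions <- seq(10, 4000, 2)
  # perfect separation: curve reaches (0, 1)
  truth <- snv_callset("t", "chr1", c(10, 20, 30))
  calls <- snv_callset("c", "chr1", c(10, 20, 30, 40, 50), gq = c(90, 85, 80, 20, 10))
  roc <- roc_points(calls, truth)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  # monotone in both axes along the sweep
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))

  # all scores equal: degenerate two-point curve ending at (1, 1)
  flat <- snv_callset("f", "chr1", c(10, 40), gq = c(30, 30))
  roc2 <- roc_points(flat, truth)
  expect_equal(nrow(roc2), 2)
  expect_equal(unlist(roc2[2, c("fpr", "tpr")], use.names = FALSE), c(1, 1 / 3))

  expect_error(roc_points(calls, callset("empty")), "empty")
})

test_that("ROC on well-separated score distributions yields high AUC matching pROC", {
  skip_if_not_installed("pROC")
  set.seed(19)
  n <- 1000
  tp_pos <- seq(10, by = 10, length.out = n)
  fp_pos <- seq(10 * n + 50, by = 10, length.out = n)
  gq <- c(rnorm(n, 50, 5), rnorm(n, 30, 5))
  cs <- snv_callset("c", "chr1", c(tp_pos, fp_pos), gq = gq)
  truth <- snv_callset("t", "chr1", tp_pos)
  roc <- roc_points(cs, truth)
  auc <- roc_auc(roc)
  expect_gt(auc, 0.95)
  # independent oracle: pROC on the same score/label data
  ref_auc <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, n), rep(0, n)), predictor = gq, quiet = TRUE)))
  expect_equal(auc, ref_auc, tolerance = 1e-6)
  # reversing the scores flips the curve through the diagonal
  cs_rev <- snv_callset("c", "chr1", c(tp_pos, fp_pos), gq = -gq)
  expect_equal(roc_auc(roc_points(cs_rev, truth)), 1 - auc, tolerance = 1e-6)
})
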