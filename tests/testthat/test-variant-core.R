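test_that("allele pairs classify into the three simple variant classes", {
  expect_equal(classify_variant("A", "T"), "SNV")
  expect_equal(classify_variant("T", "TGC"), "INS")
  expect_equal(classify_variant("TGC", "T"), "DEL")
  # trimming reveals the underlying class
  expect_equal(classify_variant("AT", "ATT"), "INS")
  expect_equal(classify_variant("CAT", "CT"), "DEL")
  expect_equal(classify_variant("TAG", "TCG"), "SNV")
  # identical alleles are not a variant
  expect_equal(classify_variant("A", "A"), "REJECTED")
  expect_error(classify_variant("AX", "A"), "DNA")
})

test_that("multi-nucleotide substitutions cannot be reduced and are rejected", {
  # exhaustive check: no combination of *shared*-base prefix/suffix trims
  # (keeping >= 1 base per allele) turns a 2-base substitution into
  # SNV/INS/DEL; only equal bases may legally be trimmed
  ref <- "AT"; alt <- "GC"
  reducible <- FALSE
  for (pre in 0:1) for (suf in 0:1) {
    if (pre > 0 && substr(ref, 1, pre) != substr(alt, 1, pre)) next
    if (suf > 0 && substr(ref, 3 - suf, 2) != substr(alt, 3 - suf, 2)) next
    r <- substr(ref, 1 + pre, 2 - suf); a <- substr(alt, 1 + pre, 2 - suf)
    if (!nzchar(r) || !nzchar(a) || r == a) next
    nr <- nchar(r); na <- nchar(a)
    if ((nr == 1 && na == 1) ||
        (nr == 1 && na > 1 && substr(a, 1, 1) == r) ||
        (na == 1 && nr > 1 && substr(r, 1, 1) == a)) reducible <- TRUE
  }
  expect_false(reducible)
  expect_equal(classify_variant("AT", "GC"), "REJECTED")
  expect_equal(classify_variant("ACGT", "TGCA"), "REJECTED")
})

test_that("indels are left-aligned to the minimum equivalent coordinate", {
  seq <- "ATGCGCGCA"
  r <- reference_sequence("chr1", seq)

  del <- regularize(variant("chr1", 6, "CGC", "C"), r)
  expect_equal(del[, c("pos", "ref", "alt")],
               data.frame(pos = 2L, ref = "TGC", alt = "T"))
  # sequence-equivalence oracle: both edits give identical strings, and the
  # returned placement is the minimum over all equivalent placements
  expect_identical(oracle_edit(seq, 6, "CGC", "C"), oracle_edit(seq, del$pos, del$ref, del$alt))
  expect_equal(oracle_min_placement(seq, 6, "CGC", "C")$pos, del$pos)

  ins <- regularize(variant("chr1", 7, "G", "GCG"), r)
  expect_equal(ins[, c("pos", "ref", "alt")],
               data.frame(pos = 2L, ref = "T", alt = "TGC"))
  expect_identical(oracle_edit(seq, 7, "G", "GCG"), oracle_edit(seq, ins$pos, ins$ref, ins$alt))
  expect_equal(oracle_min_placement(seq, 7, "G", "GCG")$pos, ins$pos)

  # SNVs have a unique position and pass through unchanged
  snv <- regularize(variant("chr1", 5, "G", "A"), r)
  expect_equal(snv[, c("pos", "ref", "alt")],
               data.frame(pos = 5L, ref = "G", alt = "A"))
})

test_that("regularization errors identify bad input", {
  r <- reference_sequence("chr1", "ATGCGCGCA")
  expect_error(regularize(variant("chr1", 5, "T", "A"), r), "REF mismatch")
  # a shift running into a truncated window demands a larger window
  w <- reference_sequence("chr1", "GCGCA", offset = 5L)
  expect_error(regularize(variant("chr1", 6, "CGC", "C"), w), "window")
})

test_that("regularization is idempotent and equivalence-preserving on random repeats", {
  set.seed(42)
  for (rep in 1:25) {
    unit <- paste(sample(c("A", "C", "G", "T"), sample(2:3, 1), replace = TRUE),
                  collapse = "")
    seq <- paste0(
      paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""),
      strrep(unit, sample(3:6, 1)),
      paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
    )
    r <- reference_sequence("chr1", seq)
    # place an indel of one unit somewhere inside the repeat run
    anchor <- sample(7:(nchar(seq) - 2 * nchar(unit) - 6), 1)
    if (rep %% 2 == 0) {
      v <- variant("chr1", anchor, substr(seq, anchor, anchor + nchar(unit)),
                   substr(seq, anchor, anchor))
    } else {
      base <- substr(seq, anchor, anchor)
      v <- variant("chr1", anchor, base, paste0(base, unit))
    }
    if (v$vtype == "REJECTED") next
    reg <- regularize(v, r)
    # idempotence
    expect_identical(regularize(reg, r), reg)
    # equivalence + minimality against the brute-force oracle
    expect_identical(oracle_edit(seq, v$pos, v$ref, v$alt),
                     oracle_edit(seq, reg$pos, reg$ref, reg$alt))
    expect_equal(reg$pos, oracle_min_placement(seq, v$pos, v$ref, v$alt)$pos)
  }
})

test_that("equivalent placements enumerated by the package match the oracle", {
  seq <- "ATGCGCGCA"
  r <- reference_sequence("chr1", seq)
  eq <- equivalent_placements(2, "TGC", "T", r)
  expect_equal(eq$pos, oracle_equivalents(seq, 2, "TGC", "T")$pos)
  eq2 <- equivalent_placements(2, "T", "TGC", r)
  expect_equal(eq2$pos, oracle_equivalents(seq, 2, "T", "TGC")$pos)
})

test_that("matching keys follow the type-specific span conventions", {
  snv <- variant("chr1", 100, "A", "T")
  expect_equal(variant_key(snv)[c("vtype", "start", "end")],
               list(vtype = "SNV", start = 100L, end = 100L))
  del <- variant("chr1", 100, "TGC", "T")
  expect_equal(variant_key(del)[c("vtype", "start", "end")],
               list(vtype = "DEL", start = 101L, end = 102L))
  ins <- variant("chr1", 100, "T", "TGC")
  expect_equal(variant_key(ins)[c("vtype", "start", "end")],
               list(vtype = "INS", start = 100L, end = 100L))
  # strict mode distinguishes alleles at the same coordinates
  snv2 <- variant("chr1", 100, "A", "G")
  expect_identical(variant_key(snv)$key, variant_key(snv2)$key)
  expect_false(identical(variant_key(snv, "strict")$key,
                         variant_key(snv2, "strict")$key))
})

test_that("key equality holds for all representations of the same edit", {
  set.seed(7)
  ref <- generate_reference(5000, repeat_fraction = 0.4, seed = 99)
  truth <- generate_truth_set(ref, 0, 20, 20, seed = 99,
                              repeat_indel_fraction = 1)
  tab <- truth$variants
  for (i in seq_len(nrow(tab))) {
    eq <- equivalent_placements(tab$pos[i], tab$ref[i], tab$alt[i], ref)
    if (nrow(eq) < 2) next
    keys <- vapply(seq_len(nrow(eq)), function(j) {
      v <- variant("chrS", eq$pos[j], eq$ref[j], eq$alt[j])
      variant_key(regularize(v, ref))$key
    }, character(1))
    expect_length(unique(keys), 1)
  }
})

test_that("quality filtering removes calls strictly below threshold", {
  tab <- rbind(
    variant("chr1", 10, "A", "T", qual = 39.9),
    variant("chr1", 20, "A", "T", qual = 40),
    variant("chr1", 30, "A", "T", qual = 41),
    variant("chr1", 40, "A", "T", qual = NA)
  )
  cs <- callset("x", tab)
  kept <- apply_quality_filter(cs, 40)
  expect_equal(kept$variants$pos, c(20L, 30L))
  expect_equal(attr(kept, "n_absent_removed"), 1L)
  # empty callset passes through
  expect_length(apply_quality_filter(callset("e"), 40), 0)
  # threshold 0 with all quals present is the identity
  cs2 <- callset("y", tab[1:3, ])
  expect_equal(apply_quality_filter(cs2, 0)$variants, cs2$variants)
  expect_error(apply_quality_filter(cs, -1), "non-negative")
})

test_that("multi-allelic records split into independent simple variants", {
  two <- split_multiallelic("chr1", 100, "A", c("T", "G"), qual = 50)
  expect_equal(two$vtype, c("SNV", "SNV"))
  expect_equal(two$pos, c(100L, 100L))

  mixed <- split_multiallelic("chr1", 100, "AT", c("A", "ATT"))
  expect_setequal(mixed$vtype, c("DEL", "INS"))
  expect_equal(mixed$vtype, classify_variant(mixed$ref, mixed$alt))

  expect_warning(none <- split_multiallelic("chr1", 100, "A", "A"), "non-simple")
  expect_equal(nrow(none), 0)
})

test_that("duplicate keys collapse to the best-supported record", {
  tab <- rbind(
    variant("chr1", 100, "A", "T", qual = 50, gq = 10),
    variant("chr1", 100, "A", "G", qual = 60, gq = 90),  # same coord key
    variant("chr1", 200, "A", "T", qual = 55, gq = 40)
  )
  cs <- suppressMessages(dedup_callset(callset("x", tab)))
  expect_length(cs, 2)
  expect_equal(attr(cs, "n_collapsed"), 1L)
  expect_equal(cs$variants$gq[cs$variants$pos == 100], 90)
})
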