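# Independent brute-force oracles used across tests. These deliberately do
# not call the package's regularization/shift code: edits are applied by
# plain string splicing and placements are found by exhaustive comparison.

# Apply REF->ALT at pos (1-based within `seq`) by splicing substrings.
oracle_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

# All placements (pos', ref', alt') of the same indel type and length whose
# edit of `seq` reproduces the same edited string; returns them sorted by pos.
oracle_equivalents <- function(seq, pos, ref, alt) {
  target <- oracle_edit(seq, pos, ref, alt)
  len <- nchar(seq)
  out <- list()
  if (nchar(ref) > nchar(alt)) {               # deletion, anchor + dlen bases
    dlen <- nchar(ref) - 1
    for (p in 1:(len - dlen)) {
      r <- substr(seq, p, p + dlen)
      a <- substr(seq, p, p)
      if (oracle_edit(seq, p, r, a) == target)
        out[[length(out) + 1]] <- data.frame(pos = p, ref = r, alt = a)
    }
  } else {                                     # insertion
    ilen <- nchar(alt) - 1
    for (p in 1:len) {
      r <- substr(seq, p, p)
      s <- substr(target, p + 1, p + ilen)
      if (nchar(s) < ilen) next
      a <- paste0(r, s)
      if (oracle_edit(seq, p, r, a) == target)
        out[[length(out) + 1]] <- data.frame(pos = p, ref = r, alt = a)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$pos), , drop = FALSE]
}

# Lowest-coordinate equivalent placement.
oracle_min_placement <- function(seq, pos, ref, alt) {
  eq <- oracle_equivalents(seq, pos, ref, alt)
  eq[1, , drop = FALSE]
}

# Small callset from key-like coordinates: SNVs at the given positions.
snv_callset <- function(label, chrom, positions, gq = NA_real_, qual = 50) {
  tab <- data.frame(
    chrom = chrom, pos = as.integer(positions), ref = "A", alt = "T",
    vtype = "SNV", qual = as.numeric(qual), gq = as.numeric(gq),
    filter = "PASS", stringsAsFactors = FALSE
  )
  callset(label, tab)
}

testdata <- function(...) test_path("testdata", ...)
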