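## Variant data model and representation regularization.
##
## A variant table is a data.frame with columns
##   chrom (chr), pos (int, 1-based first REF base), ref (chr), alt (chr),
##   vtype (chr: SNV/INS/DEL), qual (num, NA = absent), gq (num, NA = absent),
##   filter (chr)
## in the canonical (trimmed) form: SNV alleles length 1; INS ref length 1 and
## alt = ref + inserted; DEL alt length 1 and ref = alt + deleted.

variant_columns <- c("chrom", "pos", "ref", "alt", "vtype", "qual", "gq", "filter")

empty_variant_table <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), vtype = character(0), qual = numeric(0),
    gq = numeric(0), filter = character(0), stringsAsFactors = FALSE
  )
}

#' Construct a variant record
#'
#' @param chrom chromosome name.
#' @param pos 1-based position of the first REF base.
#' @param ref,alt REF and ALT alleles (uppercase DNA).
#' @param qual phred-scaled site quality (`NA` if absent).
#' @param gq phred-scaled genotype quality (`NA` if absent).
#' @param filter filter label from the source caller.
#' @return one-row variant data.frame (vtype set by [classify_variant()];
#'   alleles are not trimmed — use [regularize()] for canonical form).
#' @export
variant <- function(chrom, pos, ref, alt, qual = NA_real_, gq = NA_real_,
                    filter = "PASS") {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is_dna(ref) || !is_dna(alt)) stop_data("alleles must be non-empty DNA strings")
  data.frame(
    chrom = as.character(chrom), pos = as.integer(pos), ref = ref, alt = alt,
    vtype = classify_variant(ref, alt), qual = as.numeric(qual),
    gq = as.numeric(gq), filter = as.character(filter),
    stringsAsFactors = FALSE
  )
}

#' A named collection of variant calls
#'
#' @param label identifier naming the source, e.g. an (aligner, caller,
#'   filter-mode) combination such as `"bwa/GATK/U"`.
#' @param variants a variant data.frame (see [variant()]); rows with
#'   `vtype == "REJECTED"` are dropped with a message.
#' @param provenance free-text metadata.
#' @return a `Callset` object.
#' @export
callset <- function(label, variants = empty_variant_table(), provenance = "") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  missing_cols <- setdiff(variant_columns, names(variants))
  if (length(missing_cols))
    stop_data("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  variants <- variants[, variant_columns]
  rej <- variants$vtype == "REJECTED"
  if (any(rej)) {
    message(sprintf("callset '%s': dropping %d complex/MNV record(s)", label, sum(rej)))
    variants <- variants[!rej, , drop = FALSE]
  }
  rownames(variants) <- NULL
  structure(
    list(label = label, variants = variants, provenance = provenance),
    class = "Callset"
  )
}

#' @export
print.Callset <- function(x, ...) {
  tab <- table(factor(x$variants$vtype, levels = c("SNV", "INS", "DEL")))
  cat(sprintf("Callset '%s': %d variants (SNV %d, INS %d, DEL %d)\n",
              x$label, nrow(x$variants), tab[["SNV"]], tab[["INS"]], tab[["DEL"]]))
  invisible(x)
}

#' @export
length.Callset <- function(x) nrow(x$variants)

#' Variant table of a callset
#' @param cs a [callset()].
#' @return the underlying variant data.frame.
#' @export
variant_table <- function(cs) cs$variants

#' Classify an allele pair as SNV, insertion or deletion
#'
#' Shared leading/trailing bases are trimmed first (keeping at least one base
#' per allele); the trimmed pair is then classified. Allele pairs that do not
#' reduce to a single-base substitution or a simple insertion/deletion
#' (multi-nucleotide substitutions, complex indels) are `"REJECTED"` since the
#' downstream comparison handles only the three simple classes.
#'
#' @param ref_allele,alt_allele non-empty uppercase DNA strings.
#' @return one of `"SNV"`, `"INS"`, `"DEL"`, `"REJECTED"` (vectorized).
#' @export
classify_variant <- function(ref_allele, alt_allele) {
  if (!all(is_dna(ref_allele)) || !all(is_dna(alt_allele)))
    stop_data("alleles must be non-empty DNA strings over A,C,G,T,N")
  n <- length(ref_allele)
  out <- character(n)
  nr <- nchar(ref_allele); na <- nchar(alt_allele)
  simple <- nr == 1L & na == 1L        # fast path: the bulk of any callset
  out[simple] <- ifelse(ref_allele[simple] == alt_allele[simple], "REJECTED", "SNV")
  for (i in which(!simple)) {
    t <- trim_alleles(1L, ref_allele[i], alt_allele[i])
    r <- t$ref; a <- t$alt
    lr <- nchar(r); la <- nchar(a)
    out[i] <- if (r == a) "REJECTED"
      else if (lr == 1L && la == 1L) "SNV"
      else if (lr == 1L && la > 1L && substr(a, 1L, 1L) == r) "INS"
      else if (la == 1L && lr > 1L && substr(r, 1L, 1L) == a) "DEL"
      else "REJECTED"
  }
  out
}

## Trim shared suffix bases, then shared prefix bases (advancing pos),
## always keeping at least one base in each allele. Suffix-first ordering is
## what keeps the anchor-base convention of VCF indels intact.
trim_alleles <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  while (nr > 1L && na > 1L &&
         substr(ref, nr, nr) == substr(alt, na, na)) {
    nr <- nr - 1L; na <- na - 1L
  }
  ref <- substr(ref, 1L, nr); alt <- substr(alt, 1L, na)
  while (nr > 1L && na > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nr); alt <- substr(alt, 2L, na)
    nr <- nr - 1L; na <- na - 1L
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Regularize variant representations
#'
#' Rewrites each variant in canonical form: shared prefix/suffix bases are
#' trimmed, and insertions/deletions are shifted to the lowest genomic
#' coordinate among all placements that produce the same edited sequence —
#' e.g. a missing GC in a run of GC repeats is recorded as a deletion of the
#' first GC in the 5' to 3' direction. The operation is idempotent. REF
#' alleles are checked against the reference and mismatches are errors.
#'
#' @param x a [callset()] or a variant data.frame.
#' @param reference a [reference_sequence()] or list of them (one per
#'   chromosome), covering the variant positions and the upstream sequence an
#'   indel may shift across.
#' @return object of the same class as `x` with regularized records.
#' @export
regularize <- function(x, reference) UseMethod("regularize")

#' @export
regularize.Callset <- function(x, reference) {
  x$variants <- regularize.data.frame(x$variants, reference)
  x
}

#' @export
regularize.data.frame <- function(x, reference) {
  if (!nrow(x)) return(x)
  pos <- x$pos; ref <- x$ref; alt <- x$alt
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    refseq <- resolve_reference(reference, ch)
    off <- refseq$offset
    nr <- nchar(ref[idx])
    lo <- pos[idx] - off + 1L
    if (any(lo < 1L) || any(lo + nr - 1L > nchar(refseq$bases)))
      stop_data(sprintf("variant outside reference window on %s", ch))
    have <- substring(refseq$bases, lo, lo + nr - 1L)
    bad <- have != ref[idx]
    if (any(bad)) {
      j <- idx[which(bad)[1]]
      stop_data(sprintf("REF mismatch for %s:%d %s>%s: reference has '%s'",
                        ch, pos[j], ref[j], alt[j], have[which(bad)[1]]))
    }
    # single-base substitutions are already canonical; only the rest loop
    work <- idx[!(nr == 1L & nchar(alt[idx]) == 1L)]
    for (i in work) {
      v <- regularize_one(pos[i], ref[i], alt[i], refseq, ref_checked = TRUE)
      pos[i] <- v$pos; ref[i] <- v$ref; alt[i] <- v$alt
    }
  }
  out <- x
  out$pos <- pos; out$ref <- ref; out$alt <- alt
  out$vtype <- classify_variant(ref, alt)
  out
}

regularize_one <- function(pos, ref, alt, refseq, ref_checked = FALSE) {
  L <- nchar(ref)
  if (!ref_checked) {
    have <- ref_slice(refseq, pos, pos + L - 1L)
    if (have != ref)
      stop_data(sprintf("REF mismatch for %s:%d %s>%s: reference has '%s'",
                        refseq$name, pos, ref, alt, have))
  }
  t <- trim_alleles(pos, ref, alt)
  pos <- t$pos; ref <- t$ref; alt <- t$alt
  vtype <- classify_variant(ref, alt)
  if (vtype %in% c("SNV", "REJECTED")) return(list(pos = pos, ref = ref, alt = alt))

  off <- refseq$offset
  base_at <- function(p) substr(refseq$bases, p - off + 1L, p - off + 1L)

  if (vtype == "DEL") {
    dlen <- nchar(ref) - 1L
    d <- pos + 1L                       # first deleted base
    while (d > off + 1L && base_at(d - 1L) == base_at(d + dlen - 1L)) d <- d - 1L
    if (off > 1L && d == off + 1L && base_at(d - 1L) == base_at(d + dlen - 1L))
      stop_data(sprintf(
        "left-shift of deletion at %s:%d reached the reference window boundary; supply a larger upstream window",
        refseq$name, pos))
    anchor <- d - 1L
    list(pos = anchor,
         ref = ref_slice(refseq, anchor, anchor + dlen),
         alt = base_at(anchor))
  } else {                              # INS
    ins <- substr(alt, 2L, nchar(alt))
    ilen <- nchar(ins)
    p <- pos                            # anchor base position
    while (p > off && substr(ins, ilen, ilen) == base_at(p)) {
      ins <- paste0(base_at(p), substr(ins, 1L, ilen - 1L))
      p <- p - 1L
    }
    if (off > 1L && p == off && substr(ins, ilen, ilen) == base_at(p))
      stop_data(sprintf(
        "left-shift of insertion at %s:%d reached the reference window boundary; supply a larger upstream window",
        refseq$name, pos))
    list(pos = p, ref = base_at(p), alt = paste0(base_at(p), ins))
  }
}

#' Enumerate equivalent placements of an indel
#'
#' Brute-force search: every candidate placement inside the reference window
#' is applied to the sequence and kept when the edited sequence is
#' byte-identical to that of the input representation. For a canonical indel
#' the lowest-coordinate element of the result is what [regularize()]
#' returns; the generator uses the other elements to emit non-left-aligned
#' ("jittered") representations.
#'
#' @param pos,ref,alt a canonical-form indel record.
#' @param refseq a [reference_sequence()] covering the search window.
#' @param window scan margin in bp on each side of the variant; equivalent
#'   placements of a simple indel are contiguous with it, so a window
#'   larger than the surrounding repeat run is exhaustive.
#' @return data.frame with columns pos, ref, alt of all equivalent
#'   placements (including the input's), sorted by pos.
#' @export
equivalent_placements <- function(pos, ref, alt, refseq, window = 200L) {
  vtype <- classify_variant(ref, alt)
  if (!vtype %in% c("INS", "DEL")) stop_data("equivalent_placements applies to indels")
  lo <- max(refseq$offset, pos - as.integer(window))
  hi <- min(ref_end(refseq), pos + nchar(ref) + as.integer(window))
  refseq <- reference_sequence(refseq$name, ref_slice(refseq, lo, hi), offset = lo)
  target <- apply_variant_edit(refseq, pos, ref, alt)
  off <- refseq$offset; end <- ref_end(refseq)
  out <- list()
  if (vtype == "DEL") {
    dlen <- nchar(ref) - 1L
    for (anchor in off:(end - dlen)) {
      r <- ref_slice(refseq, anchor, anchor + dlen)
      a <- substr(r, 1L, 1L)
      if (apply_variant_edit(refseq, anchor, r, a) == target)
        out[[length(out) + 1L]] <- data.frame(pos = anchor, ref = r, alt = a,
                                              stringsAsFactors = FALSE)
    }
  } else {
    ilen <- nchar(alt) - 1L
    for (anchor in off:end) {
      i <- anchor - off + 1L
      s <- substr(target, i + 1L, i + ilen)    # inserted seq this anchor implies
      if (nchar(s) < ilen) next
      r <- ref_slice(refseq, anchor, anchor)
      a <- paste0(r, s)
      if (apply_variant_edit(refseq, anchor, r, a) == target)
        out[[length(out) + 1L]] <- data.frame(pos = anchor, ref = r, alt = a,
                                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$pos), , drop = FALSE]
}

#' Matching keys of variants
#'
#' The identity rule used throughout: two variants match when they are of the
#' same type and share the same start and end coordinates. For a regularized
#' variant the key is: SNV `(SNV, chrom, pos, pos)`; deletion of L bases
#' `(DEL, chrom, pos+1, pos+L)` spanning the deleted bases; insertion
#' `(INS, chrom, pos, pos)` collapsed onto the anchor base.
#'
#' @param x a [callset()] or variant data.frame (regularized).
#' @param mode `"coords"` (default, type + coordinates) or `"strict"`
#'   (additionally compares the allele strings).
#' @return data.frame with columns vtype, chrom, start, end, key (string).
#' @export
variant_keys <- function(x, mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  df <- if (inherits(x, "Callset")) x$variants else x
  if (!nrow(df)) {
    return(data.frame(vtype = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), key = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- ifelse(df$vtype == "DEL", df$pos + 1L, df$pos)
  end <- ifelse(df$vtype == "DEL", df$pos + nchar(df$ref) - 1L,
         ifelse(df$vtype == "SNV", df$pos, df$pos))
  key <- sprintf("%s:%s:%d-%d", df$vtype, df$chrom, start, end)
  if (mode == "strict") key <- sprintf("%s:%s>%s", key, df$ref, df$alt)
  data.frame(vtype = df$vtype, chrom = df$chrom,
             start = as.integer(start), end = as.integer(end), key = key,
             stringsAsFactors = FALSE)
}

#' @rdname variant_keys
#' @param v a single-row variant data.frame.
#' @return `variant_key()`: a list with vtype, chrom, start, end.
#' @export
variant_key <- function(v, mode = c("coords", "strict")) {
  k <- variant_keys(v[1, , drop = FALSE], mode = match.arg(mode))
  as.list(k[1, c("vtype", "chrom", "start", "end", "key")])
}

#' Collapse duplicate keys within a callset
#'
#' After regularization several source records can land on one key; the
#' record with the highest genotype quality is kept (absent GQ sorts last),
#' and the number collapsed is recorded in attribute `"n_collapsed"`.
#'
#' @param cs a [callset()], regularized.
#' @return deduplicated [callset()].
#' @export
dedup_callset <- function(cs) {
  df <- cs$variants
  if (!nrow(df)) { attr(cs, "n_collapsed") <- 0L; return(cs) }
  keys <- variant_keys(df)$key
  ord <- order(keys, -ifelse(is.na(df$gq), -Inf, df$gq))
  df <- df[ord, , drop = FALSE]
  keep <- !duplicated(keys[ord])
  n_collapsed <- sum(!keep)
  if (n_collapsed > 0L)
    message(sprintf("callset '%s': collapsed %d duplicate key(s)", cs$label, n_collapsed))
  cs$variants <- df[keep, , drop = FALSE]
  cs$variants <- cs$variants[order(cs$variants$chrom, cs$variants$pos), , drop = FALSE]
  rownames(cs$variants) <- NULL
  attr(cs, "n_collapsed") <- n_collapsed
  cs
}

#' Remove calls below a quality threshold
#'
#' Variants with phred quality strictly below `min_qual` are removed
#' (`qual == min_qual` is retained). Records with absent QUAL (`.` in VCF)
#' are treated conservatively as failing any positive threshold; their count
#' is stored in attribute `"n_absent_removed"`.
#'
#' @param cs a [callset()].
#' @param min_qual phred threshold (default 40).
#' @return filtered [callset()].
#' @export
apply_quality_filter <- function(cs, min_qual = 40) {
  if (min_qual < 0) stop_data("min_qual must be non-negative")
  df <- cs$variants
  absent <- is.na(df$qual)
  keep <- if (min_qual > 0) !absent & df$qual >= min_qual else rep(TRUE, nrow(df))
  out <- cs
  out$variants <- df[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  attr(out, "n_absent_removed") <- if (min_qual > 0) sum(absent) else 0L
  out
}

#' Split a multi-allelic VCF record into simple variants
#'
#' Each ALT allele becomes an independent record and is classified on its
#' own; alleles that do not reduce to SNV/INS/DEL (and identical REF/ALT
#' pairs) are dropped with a warning.
#'
#' @param chrom,pos,ref_allele record coordinates and REF.
#' @param alt_alleles character vector of ALT alleles.
#' @param qual,gq,filter per-record annotations recycled across alleles.
#' @return variant data.frame with one row per retained allele.
#' @export
split_multiallelic <- function(chrom, pos, ref_allele, alt_alleles,
                               qual = NA_real_, gq = NA_real_, filter = "PASS") {
  if (!length(alt_alleles)) stop_data("at least one ALT allele required")
  ref_allele <- toupper(ref_allele)
  alt_alleles <- toupper(alt_alleles)
  if (!is_dna(ref_allele) || !all(is_dna(alt_alleles)))
    stop_data("alleles must be non-empty DNA strings")
  vt <- classify_variant(rep(ref_allele, length(alt_alleles)), alt_alleles)
  bad <- vt == "REJECTED"
  if (any(bad))
    warning(sprintf("dropping %d non-simple allele(s) at %s:%d", sum(bad), chrom, pos))
  if (all(bad)) return(empty_variant_table())
  data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = ref_allele, alt = alt_alleles[!bad], vtype = vt[!bad],
    qual = as.numeric(qual), gq = as.numeric(gq),
    filter = as.character(filter), stringsAsFactors = FALSE
  )
}
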