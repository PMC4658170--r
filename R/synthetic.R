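## Synthetic-data generators: repeat-rich references, truth sets,
## tool-emulating callsets, region files and clinical tables, so every
## pipeline stage is exercisable without external downloads.

#' Generate a repeat-rich reference sequence
#'
#' I.i.d. uniform bases with embedded tandem-repeat blocks (unit length
#' drawn from `unit_lengths`, 3-10 copies) covering approximately
#' `repeat_fraction` of the sequence. Repeats give indels multiple
#' equivalent representations, which is what the regularization machinery
#' must resolve. Deterministic given `seed`; the placed blocks are recorded
#' in attribute `"repeat_blocks"` (data.frame start, end, unit).
#'
#' @param length sequence length (bp).
#' @param repeat_fraction target fraction of bases inside repeat blocks.
#' @param unit_lengths candidate repeat unit lengths.
#' @param seed RNG seed.
#' @param name sequence name.
#' @return a [reference_sequence()] with a `"repeat_blocks"` attribute.
#' @export
generate_reference <- function(length, repeat_fraction = 0.2,
                               unit_lengths = c(2L, 3L, 4L), seed = 1L,
                               name = "chrS") {
  stopifnot(length >= 100, repeat_fraction >= 0, repeat_fraction < 0.8)
  set.seed(derive_seed(seed, 1L))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  blocks <- list()
  occupied <- rep(FALSE, length)
  target <- repeat_fraction * length
  placed <- 0
  tries <- 0L
  while (placed < target && tries < 50L * length) {
    tries <- tries + 1L
    u <- sample(unit_lengths, 1L)
    k <- sample(3:10, 1L)
    blen <- u * k
    if (blen > length - 2L) next
    s <- sample.int(length - blen - 1L, 1L) + 1L
    span <- s:(s + blen - 1L)
    # keep a 1-base buffer so adjacent blocks do not merge into longer repeats
    guard <- max(1L, s - 1L):min(length, s + blen)
    if (any(occupied[guard])) next
    unit <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE), collapse = "")
    bases[span] <- strsplit(strrep(unit, k), "")[[1]]
    occupied[span] <- TRUE
    blocks[[length(blocks) + 1L]] <- data.frame(start = s, end = s + blen - 1L,
                                                unit = unit, stringsAsFactors = FALSE)
    placed <- placed + blen
  }
  ref <- reference_sequence(name, paste(bases, collapse = ""))
  attr(ref, "repeat_blocks") <- if (base::length(blocks)) do.call(rbind, blocks)
                                else data.frame(start = integer(0), end = integer(0),
                                                unit = character(0))
  ref
}

## Sample n positions in [lo, hi] pairwise separated by at least min_gap,
## avoiding the neighbourhood of excluded positions. Candidates come from a
## randomized lattice (successive gaps uniform in [min_gap, 2*min_gap]) so
## the whole routine is O(n log n) rather than quadratic.
sample_spaced_positions <- function(n, lo, hi, min_gap, exclude = integer(0)) {
  span <- hi - lo
  m <- max(n, floor(span / (1.5 * min_gap)))
  gaps <- stats::runif(m, min_gap, 2 * min_gap)
  cand <- lo + as.integer(round(cumsum(gaps)))
  cand <- cand[cand <= hi]
  if (length(exclude)) {
    ex <- sort(unique(as.integer(exclude)))
    below <- findInterval(cand, ex)                    # nearest excluded <= cand
    d_lo <- ifelse(below >= 1L, cand - ex[pmax(below, 1L)], Inf)
    d_hi <- ifelse(below < length(ex), ex[pmin(below + 1L, length(ex))] - cand, Inf)
    cand <- cand[pmin(d_lo, d_hi) >= min_gap]
  }
  if (length(cand) < n)
    stop_data("could not place the requested number of variants; sequence too short")
  sort(sample(cand, n))
}

#' Generate a truth set of SNVs, insertions and deletions
#'
#' Variants are placed at distinct, well-separated positions; at least 30%
#' of the indels are placed inside the reference's tandem-repeat blocks
#' (deleting or inserting one repeat unit) so that they have multiple
#' equivalent representations and genuinely exercise [regularize()]. All
#' records are emitted pre-regularized (canonical, left-aligned) and have
#' distinct matching keys.
#'
#' @param reference a [generate_reference()] result.
#' @param n_snv,n_ins,n_del variant counts.
#' @param seed RNG seed.
#' @param repeat_indel_fraction fraction of indels targeted at repeat
#'   blocks (default 0.4, floor 0.3 of the realized set when blocks exist).
#' @return a truth [callset()] labelled `"truth"`.
#' @export
generate_truth_set <- function(reference, n_snv, n_ins, n_del, seed = 1L,
                               repeat_indel_fraction = 0.4) {
  set.seed(derive_seed(seed, 2L))
  blocks <- attr(reference, "repeat_blocks")
  len <- nchar(reference$bases)
  min_gap <- 14L
  n_indel <- n_ins + n_del
  rows <- list()

  ## indels inside repeat blocks: delete or insert one unit copy
  n_rep <- if (!is.null(blocks) && nrow(blocks) > 0L)
    min(round(repeat_indel_fraction * n_indel), nrow(blocks)) else 0L
  rep_block_idx <- if (n_rep > 0L) sample(nrow(blocks), n_rep) else integer(0)
  rep_types <- if (n_rep > 0L)
    sample(rep(c("INS", "DEL"), length.out = n_rep)) else character(0)
  used_pos <- integer(0)
  for (j in seq_len(n_rep)) {
    b <- blocks[rep_block_idx[j], ]
    if (b$start <= 10L || b$end >= len - 10L) next
    u <- nchar(b$unit)
    anchor <- b$start - 1L
    if (rep_types[j] == "DEL") {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = reference$name, pos = anchor,
        ref = ref_slice(reference, anchor, anchor + u),
        alt = ref_slice(reference, anchor, anchor), vtype = "DEL",
        qual = NA_real_, gq = NA_real_, filter = "PASS",
        stringsAsFactors = FALSE)
    } else {
      base <- ref_slice(reference, anchor, anchor)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = reference$name, pos = anchor, ref = base,
        alt = paste0(base, b$unit), vtype = "INS",
        qual = NA_real_, gq = NA_real_, filter = "PASS",
        stringsAsFactors = FALSE)
    }
    used_pos <- c(used_pos, anchor, b$start, b$end)
  }
  made <- if (length(rows)) do.call(rbind, rows) else empty_variant_table()
  n_ins_left <- n_ins - sum(made$vtype == "INS")
  n_del_left <- n_del - sum(made$vtype == "DEL")

  ## remaining indels and all SNVs at spaced non-repeat positions
  n_ins_left <- max(0L, n_ins_left); n_del_left <- max(0L, n_del_left)
  n_free <- n_snv + n_ins_left + n_del_left
  pos <- sample_spaced_positions(n_free, 12L, len - 12L, min_gap,
                                 exclude = used_pos)
  pos <- pos[sample.int(length(pos))]  # shuffle; types must not be position-ordered
  types <- rep(c("SNV", "INS", "DEL"), c(n_snv, n_ins_left, n_del_left))
  rows[[length(rows) + 1L]] <-
    build_variant_rows(reference, pos, types, max_indel = 5L)
  cs <- callset("truth", do.call(rbind, rows), provenance = "synthetic truth set")
  cs <- regularize(cs, reference)
  cs <- suppressMessages(dedup_callset(cs))
  cs
}

#' Behaviour profile of a tool-emulating callset
#'
#' @param sensitivity fraction of truth variants the emulated tool emits.
#' @param fp_count Poisson mean of false calls.
#' @param qual_tp,qual_fp mean/sd of the phred QUAL score distributions for
#'   true and false calls (normal truncated at 0).
#' @param gq_tp,gq_fp likewise for genotype quality.
#' @param indel_jitter probability an emitted indel is re-expressed at a
#'   non-left-aligned equivalent placement (regularization must undo it).
#' @param seed RNG seed.
#' @return a `CallsetProfile` list.
#' @export
callset_profile <- function(sensitivity = 0.95, fp_count = 100,
                            qual_tp = c(mean = 60, sd = 10),
                            qual_fp = c(mean = 45, sd = 8),
                            gq_tp = c(mean = 55, sd = 10),
                            gq_fp = c(mean = 30, sd = 8),
                            indel_jitter = 0.3, seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_count >= 0,
            indel_jitter >= 0, indel_jitter <= 1)
  structure(
    list(sensitivity = sensitivity, fp_count = fp_count,
         qual_tp = qual_tp, qual_fp = qual_fp, gq_tp = gq_tp, gq_fp = gq_fp,
         indel_jitter = indel_jitter, seed = as.integer(seed)),
    class = "CallsetProfile"
  )
}

## Normal truncated at 0 (inverse-CDF sampling).
rtrunc_norm_pos <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

## Re-express an indel at a random equivalent non-canonical placement.
## Equivalent placements of a simple indel form a contiguous run reachable
## by single-base right shifts (deletion: shift right while the base before
## the deleted block equals the base after it; insertion: rotate the
## inserted sequence left while its first base matches the next reference
## base), so they are enumerated by iterated shifting rather than brute
## force. Returns the row unchanged when no alternative placement exists.
jitter_indel <- function(row, reference) {
  off <- reference$offset
  end <- ref_end(reference)
  base_at <- function(p) substring(reference$bases, p - off + 1L, p - off + 1L)
  placements <- list()
  if (row$vtype == "DEL") {
    dlen <- nchar(row$ref) - 1L
    d <- row$pos + 1L                       # first deleted base
    while (d + dlen <= end && base_at(d) == base_at(d + dlen)) {
      d <- d + 1L
      placements[[length(placements) + 1L]] <- list(
        pos = d - 1L,
        ref = ref_slice(reference, d - 1L, d + dlen - 1L),
        alt = base_at(d - 1L))
    }
  } else {
    ins <- substr(row$alt, 2L, nchar(row$alt))
    ilen <- nchar(ins)
    p <- row$pos                            # anchor base
    while (p + 1L <= end && substr(ins, 1L, 1L) == base_at(p + 1L)) {
      p <- p + 1L
      ins <- paste0(substr(ins, 2L, ilen), base_at(p))
      placements[[length(placements) + 1L]] <- list(
        pos = p, ref = base_at(p), alt = paste0(base_at(p), ins))
    }
  }
  if (!length(placements)) return(row)
  pick <- placements[[sample.int(length(placements), 1L)]]
  row$pos <- pick$pos; row$ref <- pick$ref; row$alt <- pick$alt
  row
}

## Vectorized construction of variant rows at given positions/types.
build_variant_rows <- function(reference, pos, types, max_indel = 3L) {
  n <- length(pos)
  if (!n) return(empty_variant_table())
  dna <- c("A", "C", "G", "T")
  off <- reference$offset
  base_of <- substring(reference$bases, pos - off + 1L, pos - off + 1L)
  ref <- base_of
  alt <- base_of
  is_snv <- types == "SNV"
  if (any(is_snv)) {
    # pick one of the three non-ref bases uniformly
    shift <- sample.int(3L, sum(is_snv), replace = TRUE)
    alt[is_snv] <- dna[((match(base_of[is_snv], dna) - 1L + shift) %% 4L) + 1L]
  }
  for (i in which(types == "INS")) {
    ins <- paste(sample(dna, sample.int(max_indel, 1L), replace = TRUE),
                 collapse = "")
    alt[i] <- paste0(ref[i], ins)
  }
  for (i in which(types == "DEL")) {
    dlen <- sample.int(max_indel, 1L)
    ref[i] <- substring(reference$bases, pos[i] - off + 1L, pos[i] - off + 1L + dlen)
  }
  data.frame(chrom = reference$name, pos = as.integer(pos), ref = ref,
             alt = alt, vtype = types, qual = NA_real_, gq = NA_real_,
             filter = "PASS", stringsAsFactors = FALSE)
}

## False-call rows at positions avoiding the truth keys; type mix follows
## the truth composition.
make_false_calls <- function(n, reference, truth_tab) {
  if (n <= 0L) return(empty_variant_table())
  len <- nchar(reference$bases)
  type_mix <- prop.table(table(factor(truth_tab$vtype,
                                      levels = c("SNV", "INS", "DEL"))))
  if (all(is.na(type_mix)) || !nrow(truth_tab))
    type_mix <- c(SNV = 1, INS = 0, DEL = 0)
  types <- sample(names(type_mix), n, replace = TRUE, prob = type_mix)
  pos <- sample_spaced_positions(n, 12L, len - 12L, 8L, exclude = truth_tab$pos)
  pos <- pos[sample.int(length(pos))]
  build_variant_rows(reference, pos, types, max_indel = 3L)
}

score_rows <- function(tab, qual_par, gq_par) {
  if (!nrow(tab)) return(tab)
  tab$qual <- rtrunc_norm_pos(nrow(tab), qual_par[["mean"]], qual_par[["sd"]])
  tab$gq <- rtrunc_norm_pos(nrow(tab), gq_par[["mean"]], gq_par[["sd"]])
  tab
}

#' Generate one tool-emulating callset
#'
#' Emits each truth variant with probability `sensitivity`, adds
#' `Poisson(fp_count)` false calls at positions absent from the truth set,
#' draws QUAL and GQ from the profile's truncated-normal distributions, and
#' with probability `indel_jitter` re-expresses an emitted indel at a
#' random equivalent non-left-aligned placement (which [regularize()] must
#' undo). An optional pool of extra false calls (`extra_fp`) supports
#' correlated errors across callsets.
#'
#' @param truth truth [callset()] (regularized).
#' @param profile a [callset_profile()].
#' @param reference the [generate_reference()] the truth was drawn on.
#' @param label callset label.
#' @param extra_fp optional variant data.frame of additional false calls
#'   shared with other callsets.
#' @return a [callset()] (not regularized; jittered indels are
#'   non-canonical on purpose).
#' @export
generate_callset <- function(truth, profile, reference, label = "tool",
                             extra_fp = NULL) {
  set.seed(profile$seed)
  truth_tab <- truth$variants
  emitted <- truth_tab[stats::runif(nrow(truth_tab)) < profile$sensitivity, ,
                       drop = FALSE]
  emitted <- score_rows(emitted, profile$qual_tp, profile$gq_tp)
  n_fp <- stats::rpois(1L, profile$fp_count)
  fps <- make_false_calls(n_fp, reference, truth_tab)
  fps <- score_rows(fps, profile$qual_fp, profile$gq_fp)
  if (!is.null(extra_fp) && nrow(extra_fp)) {
    extra_fp <- score_rows(extra_fp, profile$qual_fp, profile$gq_fp)
    fps <- rbind(fps, extra_fp)
  }
  tab <- rbind(emitted, fps)
  if (profile$indel_jitter > 0 && nrow(tab)) {
    idx <- which(tab$vtype %in% c("INS", "DEL") &
                 stats::runif(nrow(tab)) < profile$indel_jitter)
    for (i in idx) {
      r <- jitter_indel(list(pos = tab$pos[i], ref = tab$ref[i],
                             alt = tab$alt[i], vtype = tab$vtype[i]), reference)
      tab$pos[i] <- r$pos; tab$ref[i] <- r$ref; tab$alt[i] <- r$alt
    }
  }
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  callset(label, tab, provenance = sprintf(
    "synthetic callset: sensitivity %.3f, fp_count %.1f, jitter %.2f",
    profile$sensitivity, profile$fp_count, profile$indel_jitter))
}

#' Generate a family of callsets with correlated false calls
#'
#' Emulates several aligner/caller pairs over one truth set. False calls
#' come from three pools, reflecting that real tools share part of their
#' systematic errors: a per-callset independent pool, a correlated pool
#' whose entries enter each callset independently with probability
#' `correlated_inclusion`, and a universal pool present in every callset.
#'
#' @param truth truth [callset()].
#' @param profiles named list of [callset_profile()]s (names become labels).
#' @param reference the generating [generate_reference()].
#' @param shared_fp_fraction fraction of each profile's `fp_count` drawn
#'   from the universal pool.
#' @param correlated_fp_fraction fraction drawn from the correlated pool.
#' @param correlated_inclusion inclusion probability of a correlated-pool
#'   false call in any given callset.
#' @param seed RNG seed for the shared pools.
#' @return named list of [callset()]s.
#' @export
generate_callsets <- function(truth, profiles, reference,
                              shared_fp_fraction = 0,
                              correlated_fp_fraction = 0,
                              correlated_inclusion = 0.6,
                              seed = 1L) {
  stopifnot(shared_fp_fraction >= 0, correlated_fp_fraction >= 0,
            shared_fp_fraction + correlated_fp_fraction <= 1)
  labels <- names(profiles)
  if (is.null(labels) || anyDuplicated(labels))
    stop_data("profiles must be a named list with unique names")
  mean_fp <- mean(vapply(profiles, function(p) p$fp_count, numeric(1)))
  set.seed(derive_seed(seed, 3L))
  truth_tab <- truth$variants
  universal <- make_false_calls(round(shared_fp_fraction * mean_fp),
                                reference, truth_tab)
  correlated <- make_false_calls(
    round(correlated_fp_fraction * mean_fp / correlated_inclusion),
    reference, rbind(truth_tab, universal))
  out <- lapply(labels, function(lab) {
    p <- profiles[[lab]]
    p$fp_count <- p$fp_count * (1 - shared_fp_fraction - correlated_fp_fraction)
    set.seed(derive_seed(p$seed, 4L))
    inc <- if (nrow(correlated))
      correlated[stats::runif(nrow(correlated)) < correlated_inclusion, ,
                 drop = FALSE] else correlated
    generate_callset(truth, p, reference, label = lab,
                     extra_fp = rbind(universal, inc))
  })
  names(out) <- labels
  out
}

#' Generate confident-region and transcript-region sets
#'
#' The sequence is tiled into random-length segments (200-1000 bp); each
#' segment is kept with the target probability and kept segments are merged,
#' giving region sets covering approximately the requested fractions.
#' `fraction = 1` yields the whole sequence as one interval.
#'
#' @param reference a [reference_sequence()].
#' @param confident_fraction,transcript_fraction target coverage fractions.
#' @param seed RNG seed.
#' @return list with elements `confident` and `transcripts`
#'   ([region_set()]s).
#' @export
generate_regions <- function(reference, confident_fraction = 0.9,
                             transcript_fraction = 0.5, seed = 1L) {
  set.seed(derive_seed(seed, 5L))
  len <- nchar(reference$bases)
  one <- function(fraction, label) {
    if (fraction >= 1) {
      return(region_set(reference$name, 1L, len, label = label))
    }
    cuts <- integer(0)
    p <- 1L
    while (p < len) {
      step <- sample(200:1000, 1L)
      cuts <- c(cuts, p)
      p <- p + step
    }
    starts <- cuts
    ends <- c(cuts[-1] - 1L, len)
    keep <- stats::runif(length(starts)) < fraction
    if (!any(keep)) keep[sample(length(keep), 1L)] <- TRUE
    region_set(rep(reference$name, sum(keep)), starts[keep], ends[keep],
               label = label)
  }
  list(confident = one(confident_fraction, "confident"),
       transcripts = one(transcript_fraction, "transcripts"))
}

#' Generate a clinical annotation table from a truth set
#'
#' Samples positions from the truth set and attaches significance labels
#' ("Pathogenic", "risk factor", "Benign") and synthetic phenotype strings
#' and dbSNP-style ids.
#'
#' @param truth truth [callset()].
#' @param n_pathogenic,n_risk,n_benign record counts per significance class.
#' @param seed RNG seed.
#' @return clinical records data.frame (chrom, pos, dbsnp_id, significance,
#'   phenotype).
#' @export
generate_clinical_table <- function(truth, n_pathogenic, n_risk, n_benign,
                                    seed = 1L) {
  set.seed(derive_seed(seed, 6L))
  n <- n_pathogenic + n_risk + n_benign
  tab <- truth$variants
  if (n > nrow(tab)) stop_data("truth set has fewer variants than requested records")
  rows <- tab[sample(nrow(tab), n), , drop = FALSE]
  sig <- c(rep("Pathogenic", n_pathogenic), rep("risk factor", n_risk),
           rep("Benign", n_benign))
  keys <- variant_keys(rows)
  data.frame(
    chrom = rows$chrom,
    pos = keys$start,   # first affected base, so a key span covers it
    dbsnp_id = sprintf("rs%07d", sample.int(9999999L, n)),
    significance = sig,
    phenotype = sprintf("synthetic phenotype %d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}
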