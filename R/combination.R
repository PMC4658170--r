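## Combining many callsets: union/intersection, detection-frequency bins,
## three-way Venn counts, and genotype-quality ROC sweeps.

combined_table <- function(callsets, mode = "coords") {
  stopifnot(length(callsets) >= 1L)
  labels <- vapply(callsets, function(x) x$label, character(1))
  if (anyDuplicated(labels)) stop_data("callset labels must be unique")
  tabs <- lapply(seq_along(callsets), function(i) {
    df <- callsets[[i]]$variants
    if (!nrow(df)) {
      df$source <- character(0); df$key <- character(0)
      return(df)
    }
    df$source <- labels[i]
    df$key <- variant_keys(df, mode = mode)$key
    df[!duplicated(df$key), , drop = FALSE]
  })
  do.call(rbind, tabs)
}

#' Union of callsets
#'
#' Key-level set union. When several sources contribute a key, the retained
#' record is the one with the highest genotype quality (absent GQ sorts
#' last); ties are broken by the lexicographically smallest source label.
#'
#' @param callsets list of [callset()]s, regularized, unique labels.
#' @param label label of the result.
#' @param mode matching mode, see [variant_keys()].
#' @return a [callset()].
#' @export
union_callsets <- function(callsets, label = "union", mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  all_tab <- combined_table(callsets, mode = mode)
  if (!nrow(all_tab)) return(callset(label))
  ord <- order(all_tab$key, -ifelse(is.na(all_tab$gq), -Inf, all_tab$gq), all_tab$source)
  all_tab <- all_tab[ord, , drop = FALSE]
  all_tab <- all_tab[!duplicated(all_tab$key), , drop = FALSE]
  all_tab <- all_tab[order(all_tab$chrom, all_tab$pos), variant_columns]
  rownames(all_tab) <- NULL
  callset(label, all_tab,
          provenance = paste("union of", length(callsets), "callsets"))
}

#' Intersection of callsets
#'
#' Keys present in every callset; record selection as in [union_callsets()].
#'
#' @inheritParams union_callsets
#' @return a [callset()].
#' @export
intersect_callsets <- function(callsets, label = "intersection",
                               mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  freqs <- detection_frequency(callsets, mode = mode)
  shared <- names(freqs)[freqs == length(callsets)]
  u <- union_callsets(callsets, label = label, mode = mode)
  keys <- variant_keys(u, mode = mode)$key
  u$variants <- u$variants[keys %in% shared, , drop = FALSE]
  rownames(u$variants) <- NULL
  u$provenance <- paste("intersection of", length(callsets), "callsets")
  u
}

#' Detection frequency of variant keys across callsets
#'
#' Counts, for every key in the union, how many callsets contain it
#' (each source counted at most once per key).
#'
#' @inheritParams union_callsets
#' @return named integer vector: key -> count in `[1, n_sources]`.
#' @export
detection_frequency <- function(callsets, mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  per_set <- lapply(callsets, function(x) unique(variant_keys(x, mode = mode)$key))
  tab <- table(unlist(per_set))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Group union variants by frequency of detection
#'
#' Bins the union of calls by how many of the `n_sources` callsets detected
#' each key: `intersection` (all sources), `middle` (2 to n-1 sources),
#' `singleton` (exactly 1), plus the `union` itself. Each bin is compared
#' with the truth set (restricted to `confident`) for a false-positive rate;
#' union and intersection additionally get false-negative rates against the
#' truth restricted to `fn_regions`. Bin shares of the union are reported as
#' percentages (two decimals, half-up).
#'
#' @param callsets list of >= 2 regularized [callset()]s; variants are
#'   restricted to `confident` before binning.
#' @param truth truth [callset()], regularized.
#' @param confident confident-region [region_set()].
#' @param fn_regions FN-denominator [region_set()] (default `confident`).
#' @param mode matching mode.
#' @return a `FrequencyBins` object: data.frame with one row per bin
#'   (union, intersection, middle, singleton) and columns n, pct_of_union,
#'   fp_rate, fn_rate; detection counts in attribute `"freqs"`.
#' @export
frequency_bins <- function(callsets, truth, confident, fn_regions = confident,
                           mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  if (length(callsets) < 2L) stop_data("at least two callsets required")
  n_sources <- length(callsets)
  restricted <- lapply(callsets, restrict_to_regions, regions = confident)
  freqs <- detection_frequency(restricted, mode = mode)

  truth_conf_keys <- unique(variant_keys(restrict_to_regions(truth, confident), mode = mode)$key)
  truth_elig_keys <- unique(variant_keys(restrict_to_regions(truth, fn_regions), mode = mode)$key)

  bin_keys <- list(
    union = names(freqs),
    intersection = names(freqs)[freqs == n_sources],
    middle = names(freqs)[freqs >= 2L & freqs <= n_sources - 1L],
    singleton = names(freqs)[freqs == 1L]
  )
  n_union <- length(bin_keys$union)
  rows <- lapply(names(bin_keys), function(bin) {
    keys <- bin_keys[[bin]]
    n <- length(keys)
    n_fp <- length(setdiff(keys, truth_conf_keys))
    fn <- if (bin %in% c("union", "intersection")) {
      if (length(truth_elig_keys))
        length(setdiff(truth_elig_keys, keys)) / length(truth_elig_keys)
      else 0
    } else NA_real_
    data.frame(
      bin = bin, n = n,
      pct_of_union = detection_share(n, n_union),
      fp_rate = if (n > 0L) n_fp / n else 0,
      fn_rate = fn, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "freqs") <- freqs
  attr(out, "n_sources") <- n_sources
  class(out) <- c("FrequencyBins", "data.frame")
  out
}

#' Percentage share of a detection bin within the union
#'
#' @param bin_count variants in the bin.
#' @param union_count variants in the union (> 0).
#' @return percentage, two decimals, half-up.
#' @export
detection_share <- function(bin_count, union_count) {
  if (any(union_count <= 0)) stop_data("union count must be positive")
  round_half_up(100 * bin_count / union_count, 2)
}

#' Percent excess of one call count over another
#'
#' How many percent more calls `count_a` has than `count_b`, rounded half-up
#' to the nearest integer — the convention used when comparing total call
#' counts between tools (e.g. "36% more SNVs").
#'
#' @param count_a,count_b call counts; `count_b > 0`.
#' @return integer percentage.
#' @export
percent_excess <- function(count_a, count_b) {
  if (any(count_b <= 0)) stop_data("reference count must be positive")
  round_half_up(100 * (count_a - count_b) / count_b, 0)
}

#' Three-way Venn counts of callsets
#'
#' Counts the seven non-empty membership patterns of exactly three callsets
#' plus the unanimity percentage (keys in all three as a share of the union,
#' two decimals half-up).
#'
#' @param callsets list of exactly 3 regularized [callset()]s.
#' @param mode matching mode.
#' @return list with `counts` (named integer vector, names like `"110"`
#'   flagging membership in callsets 1..3), `labels`, `n_union`,
#'   `pct_unanimous`.
#' @export
venn_counts <- function(callsets, mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  if (length(callsets) != 3L) stop_data("exactly three callsets required")
  keysets <- lapply(callsets, function(x) unique(variant_keys(x, mode = mode)$key))
  all_keys <- unique(unlist(keysets))
  member <- vapply(keysets, function(k) all_keys %in% k, logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(m) paste(as.integer(m), collapse = ""))
  patterns <- c("100", "010", "001", "110", "101", "011", "111")
  counts <- vapply(patterns, function(p) sum(pattern == p), integer(1))
  n_union <- length(all_keys)
  list(
    counts = counts,
    labels = vapply(callsets, function(x) x$label, character(1)),
    n_union = n_union,
    pct_unanimous = if (n_union > 0L) detection_share(counts[["111"]], n_union) else 0
  )
}

#' ROC curve from genotype quality
#'
#' Sweeps thresholds over the distinct genotype-quality values of the calls
#' in descending order. At threshold t, `tpr = TP(gq >= t) / n_truth_eligible`
#' and `fpr = FP(gq >= t) / n_fp_total`, where the FPR denominator is the
#' callset's total false-positive count (classification-style, since
#' genome-wide negatives are ill-defined for variant calling). Absent
#' genotype quality is treated as -Inf, i.e. only included at the final
#' threshold. The curve starts at the (0, 0) point at threshold +Inf.
#'
#' @param cs a [callset()], regularized (restrict to regions beforehand).
#' @param truth truth [callset()], regularized and restricted the same way;
#'   must be non-empty.
#' @param mode matching mode.
#' @return a `RocCurve`: data.frame with columns threshold, fpr, tpr.
#' @export
roc_points <- function(cs, truth, mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  truth_keys <- unique(variant_keys(truth, mode = mode)$key)
  if (!length(truth_keys)) stop_data("truth set is empty")
  df <- cs$variants
  keys <- variant_keys(df, mode = mode)$key
  df <- df[!duplicated(keys), , drop = FALSE]
  keys <- keys[!duplicated(keys)]
  is_tp <- keys %in% truth_keys
  gq <- ifelse(is.na(df$gq), -Inf, df$gq)
  n_truth <- length(truth_keys)
  n_fp_total <- sum(!is_tp)

  thresholds <- sort(unique(gq), decreasing = TRUE)
  pts <- lapply(thresholds, function(t) {
    at <- gq >= t
    data.frame(
      threshold = t,
      fpr = if (n_fp_total > 0L) sum(at & !is_tp) / n_fp_total else 0,
      tpr = sum(at & is_tp) / n_truth
    )
  })
  out <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), do.call(rbind, pts))
  rownames(out) <- NULL
  class(out) <- c("RocCurve", "data.frame")
  out
}

#' Area under a ROC curve
#'
#' Trapezoidal area over the swept curve.
#'
#' @param roc a `RocCurve` from [roc_points()].
#' @return numeric in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
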