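## Comparison of callsets against a truth set under region restriction:
## the false-positive / false-negative machinery.

#' Match a callset against a truth set
#'
#' A call is a true positive iff its matching key (type + start + end, see
#' [variant_keys()]) equals the key of some truth variant of the same type;
#' comparison is performed independently per variant type by construction of
#' the key. In `"strict"` mode the allele strings must also agree.
#'
#' @param cs a [callset()], regularized.
#' @param truth truth [callset()], regularized.
#' @param mode `"coords"` (default) or `"strict"`.
#' @return list with character vectors `tp_keys`, `fp_keys` (disjoint,
#'   exhaustive over `cs`) and `matched_truth_keys` (each truth key counted
#'   at most once).
#' @export
match_against_truth <- function(cs, truth, mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  call_keys <- unique(variant_keys(cs, mode = mode)$key)
  truth_keys <- unique(variant_keys(truth, mode = mode)$key)
  tp <- intersect(call_keys, truth_keys)
  list(
    tp_keys = tp,
    fp_keys = setdiff(call_keys, truth_keys),
    matched_truth_keys = tp
  )
}

#' False-positive and false-negative rates of a callset
#'
#' Calls are restricted to the confident regions and compared with the truth
#' set (also restricted to confident regions) to obtain the false-positive
#' rate; the false-negative denominator is the truth set restricted to
#' `fn_regions` — typically the confident regions intersected with
#' transcript regions, the reduction needed when the calls derive from exome
#' data. Rates are 0 with a `flagged` marker when a denominator is empty.
#'
#' @param cs a [callset()], regularized (and quality-filtered as desired).
#' @param truth truth [callset()], regularized.
#' @param confident confident-region [region_set()].
#' @param fn_regions [region_set()] for the FN denominator; defaults to
#'   `confident`.
#' @param mode matching mode, see [match_against_truth()].
#' @return a `ComparisonResult`: list with callset_label, n_calls_in_regions,
#'   n_tp, n_fp, n_truth_eligible, n_fn, fp_rate, fn_rate, flagged.
#' @export
false_rates <- function(cs, truth, confident, fn_regions = confident,
                        mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  calls_r <- restrict_to_regions(cs, confident)
  truth_conf <- restrict_to_regions(truth, confident)
  truth_elig <- restrict_to_regions(truth, fn_regions)

  m <- match_against_truth(calls_r, truth_conf, mode = mode)
  n_calls <- length(m$tp_keys) + length(m$fp_keys)
  n_fp <- length(m$fp_keys)
  elig_keys <- unique(variant_keys(truth_elig, mode = mode)$key)
  call_keys <- unique(variant_keys(calls_r, mode = mode)$key)
  n_elig <- length(elig_keys)
  n_fn <- length(setdiff(elig_keys, call_keys))

  flagged <- n_calls == 0L || n_elig == 0L
  if (n_elig == 0L && n_calls > 0L)
    warning(sprintf("callset '%s': no eligible truth variants; fp_rate is %0.3f with empty truth",
                    cs$label, n_fp / n_calls))
  structure(
    list(
      callset_label = cs$label,
      n_calls_in_regions = n_calls,
      n_tp = length(m$tp_keys),
      n_fp = n_fp,
      n_truth_eligible = n_elig,
      n_fn = n_fn,
      fp_rate = if (n_calls > 0L) n_fp / n_calls else 0,
      fn_rate = if (n_elig > 0L) n_fn / n_elig else 0,
      flagged = flagged
    ),
    class = "ComparisonResult"
  )
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult '%s': %d calls in regions (TP %d, FP %d); %d eligible truth, FN %d\n",
              x$callset_label, x$n_calls_in_regions, x$n_tp, x$n_fp,
              x$n_truth_eligible, x$n_fn))
  cat(sprintf("  fp_rate %.2f%%  fn_rate %.2f%%%s\n", 100 * x$fp_rate,
              100 * x$fn_rate, if (x$flagged) "  [flagged: empty denominator]" else ""))
  invisible(x)
}

#' Variants unique to a single callset
#'
#' "Tool-specific" variants: for each callset, the variants whose keys appear
#' in that callset and in no other of the supplied callsets.
#'
#' @param callsets list of [callset()]s (>= 2, unique labels), regularized.
#' @param mode matching mode.
#' @return named list of [callset()]s, one per input label.
#' @export
tool_specific_variants <- function(callsets, mode = c("coords", "strict")) {
  mode <- match.arg(mode)
  if (length(callsets) < 2L) stop_data("at least two callsets required")
  labels <- vapply(callsets, function(x) x$label, character(1))
  if (anyDuplicated(labels)) stop_data("callset labels must be unique")
  per_set_keys <- lapply(callsets, function(x) unique(variant_keys(x, mode = mode)$key))
  counts <- table(unlist(per_set_keys))
  singles <- names(counts)[counts == 1L]
  out <- lapply(seq_along(callsets), function(i) {
    cs <- callsets[[i]]
    keys <- variant_keys(cs, mode = mode)$key
    cs$variants <- cs$variants[keys %in% singles & !duplicated(keys), , drop = FALSE]
    rownames(cs$variants) <- NULL
    cs$label <- paste0(cs$label, ":specific")
    cs
  })
  names(out) <- labels
  out
}

#' Tabulate comparison results in report layout
#'
#' One row per callset: Software, Filter, Total Calls, FP Rate, FN Rate,
#' Tool-specific count, Tool-specific FP Rate (percentages, two decimals
#' half-up). Software/Filter are parsed from labels of the form
#' `"software/filter"` when present.
#'
#' @param results list of `ComparisonResult`s.
#' @param specific_results optional named list of `ComparisonResult`s for the
#'   tool-specific subsets, indexed by callset label.
#' @return data.frame in the report layout.
#' @export
comparison_report <- function(results, specific_results = NULL) {
  rows <- lapply(results, function(r) {
    parts <- strsplit(r$callset_label, "/", fixed = TRUE)[[1]]
    software <- parts[1]
    filt <- if (length(parts) > 1L) paste(parts[-1], collapse = "/") else "None"
    sp <- specific_results[[r$callset_label]]
    data.frame(
      software = software, filter = filt,
      total_calls = r$n_calls_in_regions,
      fp_rate_pct = round_half_up(100 * r$fp_rate, 2),
      fn_rate_pct = round_half_up(100 * r$fn_rate, 2),
      tool_specific = if (is.null(sp)) NA_integer_ else sp$n_calls_in_regions,
      tool_specific_fp_pct = if (is.null(sp)) NA_real_ else round_half_up(100 * sp$fp_rate, 2),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a report table as TSV
#' @param report a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
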