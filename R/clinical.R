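## Overlap of callsets with a clinical-annotation table (ClinVar-like):
## significance filtering, per-variant detection matrix, unanimity summary.

#' Read a clinical annotation table
#'
#' TSV with header columns chrom, pos, dbsnp_id, significance, phenotype
#' (1-based positions). `dbsnp_id` may be empty/`.` for unannotated entries.
#'
#' @param path TSV path.
#' @return data.frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  required <- c("chrom", "pos", "dbsnp_id", "significance", "phenotype")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_data("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (any(df$pos < 1L)) stop_data("clinical positions must be >= 1")
  df
}

#' Write a clinical annotation table
#' @param records clinical records data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter clinical records by significance
#'
#' Matching is substring-based on the case-folded significance label,
#' because clinical significance labels are frequently compound (e.g.
#' "Pathogenic/Likely_pathogenic" retains for accepted label "pathogenic").
#'
#' @param records clinical records data.frame.
#' @param accepted labels to retain (default pathogenic + risk factor).
#' @return filtered records.
#' @export
filter_by_significance <- function(records,
                                   accepted = c("pathogenic", "risk factor")) {
  sig <- tolower(records$significance)
  keep <- Reduce(`|`, lapply(tolower(accepted), function(a) grepl(a, sig, fixed = TRUE)))
  if (is.null(keep)) keep <- rep(FALSE, nrow(records))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detection matrix of clinical records across callsets
#'
#' A record is detected by a callset when some variant's matching-key span
#' `[start, end]` covers the record position on the same chromosome (the
#' record coordinate carries no allele, so coverage of the position is the
#' defensible criterion; a deletion spanning the position counts as
#' detection). Alternatively, `mode = "dbsnp"` matches on dbSNP identifiers:
#' supply `callset_ids`, a named list (per callset label) of the rs ids each
#' callset annotated, for tables where ids are more reliable than
#' coordinates.
#'
#' @param records clinical records data.frame.
#' @param callsets list of regularized [callset()]s with unique labels.
#' @param mode `"coords"` (default, position coverage) or `"dbsnp"`.
#' @param callset_ids named list of character vectors of dbSNP ids per
#'   callset label (required for `mode = "dbsnp"`).
#' @return logical matrix, one row per record, one column per callset label,
#'   with attribute `"missing_labels"`: list of the labels missing each
#'   record.
#' @export
overlap_with_callsets <- function(records, callsets, mode = c("coords", "dbsnp"),
                                  callset_ids = NULL) {
  mode <- match.arg(mode)
  labels <- vapply(callsets, function(x) x$label, character(1))
  if (anyDuplicated(labels)) stop_data("callset labels must be unique")
  if (mode == "dbsnp") {
    if (is.null(callset_ids) || !all(labels %in% names(callset_ids)))
      stop_data("mode 'dbsnp' requires callset_ids for every callset label")
    detected <- vapply(labels, function(lab)
      records$dbsnp_id %in% callset_ids[[lab]], logical(nrow(records)))
    if (nrow(records) == 1L) detected <- matrix(detected, nrow = 1L)
    colnames(detected) <- labels
    rownames(detected) <- NULL
    attr(detected, "missing_labels") <- apply(detected, 1L, function(d)
      labels[!d], simplify = FALSE)
    return(detected)
  }
  rec_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  detected <- vapply(callsets, function(cs) {
    if (!nrow(cs$variants)) return(rep(FALSE, nrow(records)))
    hits <- GenomicRanges::findOverlaps(rec_gr, key_granges(cs$variants),
                                        ignore.strand = TRUE)
    out <- rep(FALSE, nrow(records))
    out[unique(S4Vectors::queryHits(hits))] <- TRUE
    out
  }, logical(nrow(records)))
  if (nrow(records) == 1L) detected <- matrix(detected, nrow = 1L)
  colnames(detected) <- labels
  rownames(detected) <- NULL
  attr(detected, "missing_labels") <- apply(detected, 1L, function(d)
    labels[!d], simplify = FALSE)
  detected
}

#' Unanimity of clinical-variant detection
#'
#' Of the clinical records overlapped by at least one callset, how many are
#' detected by all of them; percentages are reported at one decimal,
#' half-up.
#'
#' @param records clinical records data.frame.
#' @param callsets list of >= 2 regularized [callset()]s.
#' @return list with n_overlapping, n_unanimous, pct_unanimous, n_missed,
#'   pct_missed.
#' @export
unanimity_summary <- function(records, callsets) {
  if (length(callsets) < 2L) stop_data("at least two callsets required")
  detected <- overlap_with_callsets(records, callsets)
  n_by <- rowSums(detected)
  n_overlapping <- sum(n_by >= 1L)
  n_unanimous <- sum(n_by == length(callsets))
  n_missed <- n_overlapping - n_unanimous
  list(
    n_overlapping = n_overlapping,
    n_unanimous = n_unanimous,
    pct_unanimous = if (n_overlapping > 0L)
      round_half_up(100 * n_unanimous / n_overlapping, 1) else 0,
    n_missed = n_missed,
    pct_missed = if (n_overlapping > 0L)
      round_half_up(100 * n_missed / n_overlapping, 1) else 0
  )
}

#' Report of clinical variants and the tool combinations missing them
#'
#' One row per clinical record: coordinate, dbSNP id, the callset labels
#' failing to detect it (`"None"` when detected by all), and the phenotype
#' annotation.
#'
#' @param records clinical records data.frame.
#' @param callsets list of regularized [callset()]s.
#' @return data.frame in the report layout.
#' @export
clinical_report <- function(records, callsets) {
  detected <- overlap_with_callsets(records, callsets)
  missing <- attr(detected, "missing_labels")
  data.frame(
    coordinate = sprintf("%s:%d", records$chrom, records$pos),
    dbsnp_id = ifelse(is.na(records$dbsnp_id) | !nzchar(records$dbsnp_id),
                      ".", records$dbsnp_id),
    missing_pairs = vapply(missing, function(m)
      if (length(m)) paste(m, collapse = " ") else "None", character(1)),
    annotation = records$phenotype,
    stringsAsFactors = FALSE
  )
}
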