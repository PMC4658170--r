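## VCF input/output (sites + first sample column), via vcfR.

#' Read a callset from a VCF file
#'
#' Supports the VCFv4.1/4.2 site columns plus the first sample column.
#' QUAL and FILTER are taken from the fixed columns; genotype quality comes
#' from the sample's GQX field when present, else GQ (GQX, where a caller
#' emits it, is the minimum of the genotype quality assuming a variant and a
#' non-variant locus). Multi-allelic records are split into simple variants;
#' alleles that are not SNV/INS/DEL are dropped with a warning. Gzipped
#' files are read transparently.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param label callset label (default: file name).
#' @return a [callset()] (not regularized).
#' @export
read_callset_vcf <- function(path, label = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix)) || nrow(fix) == 0L)
    return(callset(label, provenance = path))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  filt <- fix[, "FILTER"]
  filt[is.na(filt) | filt == "."] <- "PASS"

  gq <- rep(NA_real_, nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    fmt <- v@gt[, 1L]
    has_gqx <- any(grepl("(^|:)GQX(:|$)", fmt))
    elem <- if (has_gqx) "GQX" else "GQ"
    g <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = elem, as.numeric = TRUE)[, 1L]),
      error = function(e) rep(NA_real_, nrow(fix))
    )
    if (length(g) == nrow(fix)) gq <- as.numeric(g)
  }

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alts <- alts[!is.na(alts) & nzchar(alts) & alts != "."]
    alts <- alts[!grepl("[<>\\[\\]]", alts)]       # skip symbolic/breakend alleles
    if (!length(alts)) return(NULL)
    split_multiallelic(fix[i, "CHROM"], as.integer(fix[i, "POS"]), fix[i, "REF"],
                       alts, qual = qual[i], gq = gq[i], filter = filt[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  variants <- if (length(rows)) do.call(rbind, rows) else empty_variant_table()
  callset(label, variants, provenance = path)
}

#' Write a callset to a VCF file
#'
#' Emits a minimal VCFv4.2 file with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO
#' and one sample column carrying GT:GQ (genotype written as `./.` since
#' zygosity is not modeled). Paths ending in `.gz` are written through
#' vcfR's gzip writer; plain `.vcf` paths are written uncompressed.
#' Round-trip via [read_callset_vcf()] preserves the variant table.
#'
#' @param cs a [callset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(cs, path) {
  df <- cs$variants
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=vcbench callset '%s'", cs$label),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  )
  n <- nrow(df)
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
  fix <- matrix(NA_character_, nrow = n, ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gt <- matrix(NA_character_, nrow = n, ncol = 2,
               dimnames = list(NULL, c("FORMAT", "SAMPLE1")))
  if (n) {
    fix[, "CHROM"] <- df$chrom; fix[, "POS"] <- as.character(df$pos)
    fix[, "ID"] <- "."; fix[, "REF"] <- df$ref; fix[, "ALT"] <- df$alt
    fix[, "QUAL"] <- fmt_num(df$qual)
    fix[, "FILTER"] <- ifelse(is.na(df$filter) | !nzchar(df$filter), "PASS", df$filter)
    fix[, "INFO"] <- "."
    gt[, "FORMAT"] <- "GT:GQ"
    gt[, "SAMPLE1"] <- paste0("./.:", ifelse(is.na(df$gq), ".",
                                             as.character(round(df$gq))))
  }
  if (grepl("\\.gz$", path)) {
    obj <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
    vcfR::write.vcf(obj, file = path)
  } else {
    header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "SAMPLE1"), collapse = "\t")
    body <- if (nrow(df)) apply(cbind(fix, gt), 1L, paste, collapse = "\t") else character(0)
    writeLines(c(meta, header, body), path)
  }
  invisible(path)
}
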