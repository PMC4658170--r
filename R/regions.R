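## Genomic interval sets (confident regions, transcript regions), backed by
## GenomicRanges. Coordinates are 1-based inclusive in memory; BED files on
## disk are 0-based half-open and converted at the parser boundary.

#' Construct a region set
#'
#' Overlapping/adjacent input intervals are merged so membership queries are
#' deterministic.
#'
#' @param chrom,start,end parallel vectors (1-based inclusive), or `chrom`
#'   may be a `GRanges` or a data.frame with those columns.
#' @param label identifier for reports.
#' @return a `RegionSet` object.
#' @export
region_set <- function(chrom, start = NULL, end = NULL, label = "regions") {
  gr <- if (methods::is(chrom, "GRanges")) {
    chrom
  } else if (is.data.frame(chrom)) {
    GenomicRanges::GRanges(chrom$chrom, IRanges::IRanges(chrom$start, chrom$end))
  } else {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  }
  gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  structure(list(granges = gr, label = label), class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet '%s': %d interval(s), %d bp\n", x$label,
              length(x$granges), sum(GenomicRanges::width(x$granges))))
  invisible(x)
}

#' @export
length.RegionSet <- function(x) length(x$granges)

#' Total bases covered by a region set
#' @param regions a [region_set()].
#' @return integer base count.
#' @export
region_width <- function(regions) sum(GenomicRanges::width(regions$granges))

#' Region set as a data.frame
#' @param x a [region_set()].
#' @param ... unused.
#' @return data.frame with chrom, start, end (1-based inclusive).
#' @export
as.data.frame.RegionSet <- function(x, ...) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x$granges)),
    start = GenomicRanges::start(x$granges),
    end = GenomicRanges::end(x$granges),
    stringsAsFactors = FALSE
  )
}

#' Intersect two region sets
#'
#' Used to build the false-negative denominator regions (confident regions
#' intersected with transcript regions).
#'
#' @param a,b [region_set()] objects.
#' @param label label for the result.
#' @return a [region_set()].
#' @export
regions_intersect <- function(a, b, label = paste0(a$label, "&", b$label)) {
  ga <- a$granges; gb <- b$granges
  lev <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lev
  GenomeInfoDb::seqlevels(gb) <- lev
  region_set(GenomicRanges::intersect(ga, gb, ignore.strand = TRUE), label = label)
}

#' Read regions from a BED file
#'
#' @param path BED path (0-based half-open on disk).
#' @param label region set label (default: file name).
#' @return a [region_set()] in 1-based inclusive coordinates.
#' @export
read_bed_regions <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  region_set(gr, label = label)
}

#' Write a region set to a BED file
#'
#' @param regions a [region_set()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed_regions <- function(regions, path) {
  rtracklayer::export(regions$granges, path, format = "BED")
  invisible(path)
}

## GRanges of the matching-key spans of a callset/table.
key_granges <- function(x) {
  k <- variant_keys(x)
  GenomicRanges::GRanges(k$chrom, IRanges::IRanges(k$start, k$end))
}

#' Restrict a callset to confident regions
#'
#' A variant is retained only when its matching-key span `[start, end]` lies
#' entirely within a single interval ("contained in" the regions); a variant
#' straddling a region boundary is excluded.
#'
#' @param cs a [callset()], regularized.
#' @param regions a [region_set()].
#' @return restricted [callset()].
#' @export
restrict_to_regions <- function(cs, regions) {
  df <- cs$variants
  if (!nrow(df)) return(cs)
  if (!length(regions$granges)) {
    cs$variants <- df[0, , drop = FALSE]
    return(cs)
  }
  hits <- GenomicRanges::findOverlaps(key_granges(df), regions$granges,
                                      type = "within", ignore.strand = TRUE)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  cs$variants <- df[keep, , drop = FALSE]
  rownames(cs$variants) <- NULL
  cs
}
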