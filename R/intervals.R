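#' Genomic intervals from printed 1-based coordinates
#'
#' Genome-browser reports, and most coordinates quoted in the regulatory
#' genomics literature, are 1-based and inclusive. `from_printed()` turns such
#' coordinate pairs into a [GenomicRanges::GRanges], the coordinate currency
#' used by every function in this package, and `format_printed()` renders
#' intervals back in the same notation (with thousands separators), so printed
#' input coordinates round-trip exactly. File formats with 0-based half-open
#' coordinates (BED, BEDPE, narrowPeak) are converted at the I/O boundary by
#' the readers and writers in this package.
#'
#' @param chrom chromosome name(s); non-empty strings.
#' @param start,end 1-based inclusive coordinates with `start <= end`.
#' @param strand `"+"`, `"-"`, or `"*"`/`"."` for unstranded. Strand is carried
#'   through but ignored by every operation in this package: the prediction
#'   procedure is strand-agnostic.
#' @return `from_printed()`: a `GRanges` of the common length of the inputs.
#'   `format_printed()`: a character vector like `"chr18:2,645,885-2,795,015"`.
#' @examples
#' smchd1 <- from_printed("chr18", 2645885, 2795015)
#' GenomicRanges::width(smchd1)   # 149131 bp
#' format_printed(smchd1)
#' @export
from_printed <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("`chrom` must be a non-empty chromosome name", call. = FALSE)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("coordinates must be finite numbers", call. = FALSE)
  if (any(start < 1))
    stop("1-based coordinates start at 1; got start < 1", call. = FALSE)
  if (any(end < start))
    stop("inverted span: `end` must be >= `start`", call. = FALSE)
  strand <- ifelse(strand == ".", "*", strand)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end),
                         strand = strand)
}

#' @rdname from_printed
#' @param x a `GRanges`.
#' @export
format_printed <- function(x) {
  if (length(x) == 0L) return(character(0))
  sprintf("%s:%s-%s", as.character(GenomicRanges::seqnames(x)),
          .fmt_bp(GenomicRanges::start(x)), .fmt_bp(GenomicRanges::end(x)))
}

#' Pairwise interval overlap
#'
#' Element-wise test of whether two intervals overlap: `TRUE` iff the
#' chromosomes match and the (closed, 1-based) intervals share at least one
#' base. Inputs of length one are recycled against the other argument.
#'
#' @param a,b `GRanges` objects of equal length (or either of length 1).
#' @return logical vector.
#' @examples
#' dhs <- from_printed("chr18", 2631700, 2631930)
#' overlaps_intervals(dhs, from_printed("chr18", 2631886, 2631886))  # TRUE
#' overlaps_intervals(dhs, from_printed("chr18", 2631610, 2631610))  # FALSE
#' @export
overlaps_intervals <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length (or length 1)", call. = FALSE)
  if (length(a) == 0L) return(logical(0))
  as.logical(IRanges::poverlaps(a, b, ignore.strand = TRUE))
}

#' Select the features overlapping a query interval
#'
#' Returns exactly the features that overlap `query`, in their original input
#' order, regardless of whether `features` is sorted.
#'
#' @param query a single `GRanges` interval.
#' @param features a `GRanges` of (scored) features.
#' @return the overlapping subset of `features`, input order preserved.
#' @export
intersect_features <- function(query, features) {
  stopifnot(methods::is(query, "GRanges"), methods::is(features, "GRanges"))
  if (length(query) != 1L)
    stop("`query` must be a single interval", call. = FALSE)
  if (length(features) == 0L) return(features)
  hit <- IRanges::overlapsAny(features, query, ignore.strand = TRUE)
  features[hit]
}
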