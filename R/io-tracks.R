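# Feature tracks: typed, scored interval collections tagged with a cell line.

TRACK_CLASSES <- c("CTCF", "H3K4me1", "H3K4me3", "H3K27ac", "DNase",
                   "TFBS", "ENHANCER", "CHROMHMM", "CONSERVATION")

#' Typed feature tracks
#'
#' A feature track is a `GRanges` of scored features (`name`, `score` in
#' 0--1000, `cell_line` metadata columns) tagged with one of the closed set of
#' track classes used by the evidence-integration step:
#' `r paste(TRACK_CLASSES, collapse = ", ")`. Unknown classes are rejected
#' rather than passed through, because candidate calling and classification
#' depend on the closed set.
#'
#' @param x a `GRanges`; optional metadata columns `name`, `score`
#'   (0--1000, ENCODE browser-track convention) and `cell_line` are filled
#'   with defaults when absent.
#' @param track_class one of the classes above.
#' @param cell_line cell line the track was assayed in (`""` if not tied to
#'   one, e.g. FANTOM enhancer atlases).
#' @return a `GRanges` with track class and cell line recorded in its
#'   metadata; retrieve them with `track_class()` / `track_cell_line()`.
#' @export
feature_track <- function(x, track_class, cell_line = "") {
  if (!methods::is(x, "GRanges"))
    stop("`x` must be a GRanges", call. = FALSE)
  if (length(track_class) != 1L || !track_class %in% TRACK_CLASSES)
    stop("unknown track_class '", track_class[1], "'; must be one of: ",
         paste(TRACK_CLASSES, collapse = ", "), call. = FALSE)
  mc <- S4Vectors::mcols(x)
  if (is.null(mc$name)) mc$name <- rep(track_class, length(x))
  if (is.null(mc$score)) mc$score <- rep(0, length(x))
  mc$score <- as.numeric(mc$score)
  if (length(x) && (any(is.na(mc$score)) || any(mc$score < 0) ||
                    any(mc$score > 1000)))
    stop("feature scores must lie in [0, 1000]", call. = FALSE)
  if (is.null(mc$cell_line)) mc$cell_line <- rep(cell_line, length(x))
  S4Vectors::mcols(x) <- mc
  S4Vectors::metadata(x)$track_class <- track_class
  S4Vectors::metadata(x)$cell_line <- cell_line
  x
}

#' @rdname feature_track
#' @export
track_class <- function(x) S4Vectors::metadata(x)$track_class

#' @rdname feature_track
#' @export
track_cell_line <- function(x) S4Vectors::metadata(x)$cell_line %||% ""

.is_feature_track <- function(x) {
  methods::is(x, "GRanges") && !is.null(track_class(x)) &&
    track_class(x) %in% TRACK_CLASSES
}

# Return data lines (text + original line numbers) of a whitespace-table file,
# skipping blanks, comments and browser/track header lines.
.data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(txt)) & !startsWith(txt, "#") &
    !startsWith(txt, "track") & !startsWith(txt, "browser")
  list(text = txt[keep], lineno = which(keep))
}

.check_table_file <- function(path, min_cols, what) {
  lines <- .data_lines(path)
  if (length(lines$text) == 0L) return(0L)
  nf <- lengths(strsplit(lines$text, "[\t ]+"))
  bad <- which(nf < min_cols)
  if (length(bad))
    stop(sprintf("malformed %s record at line %d of '%s': %d column(s), expected >= %d",
                 what, lines$lineno[bad[1]], path, nf[bad[1]], min_cols),
         call. = FALSE)
  length(lines$text)
}

#' Read feature tracks from BED and narrowPeak files
#'
#' BED coordinates on disk are 0-based half-open and are converted to the
#' 1-based inclusive `GRanges` convention on input (and back on output), so a
#' BED line `chr18 2631699 2631930` is the printed interval
#' 2,631,700--2,631,930. BED3 through BED6 dialects are accepted; narrowPeak
#' files must have the full 10 columns, of which `signalValue`, `pValue`,
#' `qValue` and `peak` are parsed but not used downstream (only positions and
#' the 0--1000 `score` enter the prediction). A malformed record raises an
#' error naming its line number; an empty file yields an empty track.
#'
#' @param path file to read.
#' @inheritParams feature_track
#' @return a [feature_track()] `GRanges`.
#' @export
read_bed <- function(path, track_class, cell_line = "") {
  n <- .check_table_file(path, min_cols = 3L, what = "BED")
  if (n == 0L) {
    return(feature_track(GenomicRanges::GRanges(), track_class, cell_line))
  }
  gr <- rtracklayer::import(path, format = "BED")
  feature_track(gr, track_class, cell_line)
}

#' @rdname read_bed
#' @export
read_narrowpeak <- function(path, track_class, cell_line = "") {
  n <- .check_table_file(path, min_cols = 10L, what = "narrowPeak")
  if (n == 0L) {
    return(feature_track(GenomicRanges::GRanges(), track_class, cell_line))
  }
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  feature_track(gr, track_class, cell_line)
}

#' @rdname read_bed
#' @param track a feature track to write.
#' @export
write_track_bed <- function(track, path) {
  gr <- GenomicRanges::granges(track)
  S4Vectors::mcols(gr)$name <- S4Vectors::mcols(track)$name %||%
    rep(".", length(track))
  S4Vectors::mcols(gr)$score <- S4Vectors::mcols(track)$score %||%
    rep(0, length(track))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_bed
#' @export
write_narrowpeak <- function(track, path) {
  mc <- S4Vectors::mcols(track)
  n <- length(track)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = .int_chr(GenomicRanges::start(track) - 1L),
    end = .int_chr(GenomicRanges::end(track)),
    name = as.character(mc$name %||% rep(".", n)),
    score = .int_chr(round(as.numeric(mc$score %||% rep(0, n)))),
    strand = rep(".", n),
    signalValue = as.numeric(mc$signalValue %||% rep(0, n)),
    pValue = as.numeric(mc$pValue %||% rep(-1, n)),
    qValue = as.numeric(mc$qValue %||% rep(-1, n)),
    peak = as.integer(mc$peak %||% rep(-1L, n)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-base conservation scores from a bedGraph file
#'
#' Conservation tracks (e.g. phyloP) are real-valued, so they are returned as
#' a plain `GRanges` with a `score` column rather than a 0--1000 feature
#' track. Look scores up at variant positions with [conservation_at()].
#'
#' @param path bedGraph file.
#' @return `GRanges` with numeric `score`.
#' @export
read_bedgraph <- function(path) {
  .check_table_file(path, min_cols = 4L, what = "bedGraph")
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname read_bedgraph
#' @param scores a `GRanges` with a numeric `score` column.
#' @export
write_bedgraph <- function(scores, path) {
  rtracklayer::export(scores, path, format = "bedGraph")
  invisible(path)
}
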