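# Step 6: validate candidate regions against chromatin-loop calls linking
# them to the gene promoter.

#' Default promoter interval for a gene
#'
#' When an H3K4me3 track is supplied and carries a call overlapping the
#' gene's start +/- `flank`, that call is used as the promoter region
#' (the active-promoter mark delimits it directly); otherwise the promoter
#' defaults to gene start +/- `flank`.
#'
#' @param gene single-interval `GRanges`.
#' @param h3k4me3 optional H3K4me3 [feature_track()].
#' @param flank half-width of the fallback promoter window, bp.
#' @return single-interval `GRanges`.
#' @export
promoter_region <- function(gene, h3k4me3 = NULL, flank = 2000) {
  stopifnot(methods::is(gene, "GRanges"), length(gene) == 1L)
  gs <- GenomicRanges::start(gene)
  window <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(gene)),
    IRanges::IRanges(max(1, gs - flank), gs + flank))
  if (!is.null(h3k4me3) && length(h3k4me3)) {
    hit <- intersect_features(window, h3k4me3)
    if (length(hit)) return(GenomicRanges::granges(hit[1]))
  }
  window
}

#' Validate a candidate region against chromatin-loop calls
#'
#' A candidate is `supported` when some loop has one anchor overlapping the
#' candidate and the other overlapping the promoter (anchor order is
#' irrelevant). When no such loop exists the status depends on whether the
#' loop source could have reported one: promoter Capture Hi-C call lists
#' omit pairs separated by less than ~20 kb, so for `capture_hic` calls a
#' candidate whose edge-to-edge separation from the promoter is at most
#' `min_separation` is `not_assessable` rather than `unsupported`.
#'
#' @param candidate single-interval `GRanges` (one row of a
#'   [find_candidates()] result).
#' @param promoter single-interval `GRanges`, same chromosome.
#' @param loops a [loop_calls()] table.
#' @param min_separation reporting floor of Capture Hi-C call lists, bp
#'   (default 20000).
#' @param source restrict to loops of this source (`"in_situ_hic"` or
#'   `"capture_hic"`); `NULL` uses `loops` as given (its default source
#'   applies when the table is empty).
#' @return an object of class `loop_validation`: list with `status`
#'   (`supported` / `unsupported` / `not_assessable`), `matching_loops`
#'   (the supporting subset of `loops`), `separation` (bp, 0 if candidate
#'   and promoter overlap), `source`, `min_separation`, `candidate`.
#' @export
validate_candidate <- function(candidate, promoter, loops,
                               min_separation = 20000, source = NULL) {
  stopifnot(methods::is(candidate, "GRanges"), length(candidate) == 1L,
            methods::is(promoter, "GRanges"))
  if (length(promoter) != 1L || GenomicRanges::width(promoter) < 1L)
    stop("`promoter` must be a single non-empty interval", call. = FALSE)
  stopifnot(inherits(loops, "loop_calls"))
  if (!is.null(source)) {
    source <- match.arg(source, LOOP_SOURCES)
    loops <- loops[loops$source == source, , drop = FALSE]
  } else {
    source <- if (nrow(loops)) unique(loops$source)
              else attr(loops, "default_source") %||% NA_character_
  }

  sep <- 0
  if (!overlaps_intervals(candidate, promoter)) {
    cs <- GenomicRanges::start(candidate); ce <- GenomicRanges::end(candidate)
    ps <- GenomicRanges::start(promoter); pe <- GenomicRanges::end(promoter)
    sep <- if (ce < ps) ps - ce - 1 else cs - pe - 1
  }

  matching <- loops[0, , drop = FALSE]
  if (nrow(loops)) {
    a <- loop_anchors(loops, "a")
    b <- loop_anchors(loops, "b")
    hit <- (overlaps_intervals(a, candidate) &
              overlaps_intervals(b, promoter)) |
           (overlaps_intervals(b, candidate) &
              overlaps_intervals(a, promoter))
    matching <- loops[hit, , drop = FALSE]
  }
  status <- if (nrow(matching)) {
    "supported"
  } else if (all(source %in% "capture_hic") && !anyNA(source) &&
             sep <= min_separation) {
    "not_assessable"
  } else {
    "unsupported"
  }
  structure(list(candidate = candidate, status = status,
                 matching_loops = matching, separation = sep,
                 source = source, min_separation = min_separation),
            class = "loop_validation")
}

#' @export
print.loop_validation <- function(x, ...) {
  cat(sprintf("<loop_validation> %s: %s (separation %s bp, %d matching loop(s), source %s)\n",
              format_printed(x$candidate), x$status, .fmt_bp(x$separation),
              nrow(x$matching_loops),
              paste(x$source, collapse = "/")))
  invisible(x)
}
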