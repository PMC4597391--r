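# Chromatin loop calls, read and written as BEDPE.

LOOP_SOURCES <- c("in_situ_hic", "capture_hic")

#' Chromatin loop calls
#'
#' A loop call joins two anchor intervals. Anchors are kept in the BEDPE
#' convention they are published in -- 0-based half-open `start`/`end` -- so
#' a 5-kb anchor printed as 2,630,000--2,635,000 keeps those numbers;
#' [loop_anchors()] converts to `GRanges` for overlap work. The `source`
#' distinguishes in situ Hi-C loop calls from promoter Capture Hi-C calls,
#' whose published lists omit promoter-proximal pairs (separation below
#' ~20 kb) and therefore cannot refute short-range loops.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b anchor coordinates
#'   (BEDPE convention). Intra-chromosomal calls only: `chrom_a == chrom_b`.
#' @param name,score optional per-loop label and score (carried through, never
#'   thresholded).
#' @param source `"in_situ_hic"` or `"capture_hic"`.
#' @param resolution calling resolution in bp (`NA` if unknown).
#' @return a data.frame of class `loop_calls`.
#' @export
loop_calls <- function(chrom_a = character(0), start_a = numeric(0),
                       end_a = numeric(0), chrom_b = character(0),
                       start_b = numeric(0), end_b = numeric(0),
                       name = NA_character_, score = NA_real_,
                       source = c("in_situ_hic", "capture_hic"),
                       resolution = NA_real_) {
  source <- match.arg(source)
  n <- length(chrom_a)
  df <- data.frame(chrom_a = as.character(chrom_a),
                   start_a = as.numeric(start_a), end_a = as.numeric(end_a),
                   chrom_b = as.character(chrom_b),
                   start_b = as.numeric(start_b), end_b = as.numeric(end_b),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   source = rep_len(source, n),
                   resolution = rep_len(as.numeric(resolution), n),
                   stringsAsFactors = FALSE)
  if (n) {
    if (any(df$chrom_a != df$chrom_b))
      stop("loop anchors must be intra-chromosomal", call. = FALSE)
    if (any(df$end_a <= df$start_a) || any(df$end_b <= df$start_b))
      stop("loop anchors must have end > start (BEDPE half-open)",
           call. = FALSE)
    if (any(!is.na(df$resolution) & df$resolution <= 0))
      stop("loop resolution must be positive", call. = FALSE)
  }
  attr(df, "default_source") <- source
  class(df) <- c("loop_calls", "data.frame")
  df
}

#' @rdname loop_calls
#' @param loops a `loop_calls` table.
#' @param which `"a"` or `"b"`: which anchor column to extract.
#' @return `loop_anchors()`: `GRanges` of the requested anchors (1-based).
#' @export
loop_anchors <- function(loops, which = c("a", "b")) {
  which <- match.arg(which)
  if (nrow(loops) == 0L) return(GenomicRanges::GRanges())
  s <- loops[[paste0("start_", which)]]
  e <- loops[[paste0("end_", which)]]
  GenomicRanges::GRanges(loops[[paste0("chrom_", which)]],
                         IRanges::IRanges(start = s + 1, end = e))
}

#' Read / write loop calls as BEDPE
#'
#' Six-column minimum BEDPE (`chrom1 start1 end1 chrom2 start2 end2`), with
#' optional `name` and `score` in columns 7--8. A malformed record raises an
#' error naming its line number; an empty file yields an empty call set.
#'
#' @param path file to read or write.
#' @inheritParams loop_calls
#' @return `read_loops_bedpe()`: a [loop_calls()] table.
#' @export
read_loops_bedpe <- function(path, source = c("in_situ_hic", "capture_hic"),
                             resolution = NA_real_) {
  source <- match.arg(source)
  lines <- .data_lines(path)
  if (length(lines$text) == 0L) {
    return(loop_calls(source = source, resolution = resolution))
  }
  parts <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6L)
  if (length(bad))
    stop(sprintf("malformed BEDPE record at line %d of '%s': %d column(s), expected >= 6",
                 lines$lineno[bad[1]], path, lengths(parts)[bad[1]]),
         call. = FALSE)
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_,
                            character(1))
  num <- function(k, lab) {
    v <- suppressWarnings(as.numeric(get(k)))
    na <- which(is.na(v))
    if (length(na))
      stop(sprintf("non-numeric %s at line %d of '%s'", lab,
                   lines$lineno[na[1]], path), call. = FALSE)
    v
  }
  nm <- get(7); nm[nm %in% c(".", NA)] <- NA_character_
  sc <- suppressWarnings(as.numeric(get(8)))
  loop_calls(chrom_a = get(1), start_a = num(2, "start1"),
             end_a = num(3, "end1"), chrom_b = get(4),
             start_b = num(5, "start2"), end_b = num(6, "end2"),
             name = nm, score = sc, source = source, resolution = resolution)
}

#' @rdname read_loops_bedpe
#' @param loops a `loop_calls` table.
#' @export
write_loops_bedpe <- function(loops, path) {
  if (nrow(loops) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(loops$chrom_a, .int_chr(loops$start_a),
                   .int_chr(loops$end_a), loops$chrom_b,
                   .int_chr(loops$start_b), .int_chr(loops$end_b),
                   ifelse(is.na(loops$name), ".", loops$name),
                   ifelse(is.na(loops$score), ".", as.character(loops$score)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
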