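# Sparse binned intra-chromosomal Hi-C contact maps.
#
# Contact input is a plain 4-column TSV (chrom, bin_i_start, bin_j_start,
# count) holding pre-binned counts at a fixed resolution; bin starts are the
# 0-based multiples of the bin size used by genome-browser fragment labels
# (the 1-Mb fragment printed as 2,000,000-2,999,999 is the bin starting at
# 2,000,000). Binary matrix formats (.hic/.cool) are out of scope.

#' Construct a contact map from a bin-pair count table
#'
#' The map is stored sparsely and symmetrically: each unordered bin pair is
#' kept once (`bin_i <= bin_j`), `contact_count()` answers queries in either
#' orientation, and unobserved pairs count 0. Bin starts must be multiples of
#' `bin_size`; counts must be non-negative. Duplicate records of the same
#' pair with conflicting counts are an error.
#'
#' @param chrom single chromosome name (maps are intra-chromosomal).
#' @param bin_size bin width in bp (e.g. `1e6` or `1e5`).
#' @param counts data.frame with columns `bin_i`, `bin_j`, `count`.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(chrom, bin_size, counts) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("`chrom` must be a single non-empty chromosome name", call. = FALSE)
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("`bin_size` must be a positive number of bp", call. = FALSE)
  counts <- as.data.frame(counts)
  need <- c("bin_i", "bin_j", "count")
  if (!all(need %in% names(counts)))
    stop("`counts` needs columns bin_i, bin_j, count", call. = FALSE)
  counts <- counts[need]
  for (cl in need) counts[[cl]] <- as.numeric(counts[[cl]])
  if (nrow(counts)) {
    if (any(!is.finite(unlist(counts))))
      stop("contact records must be finite numbers", call. = FALSE)
    if (any(counts$count < 0))
      stop("negative contact count", call. = FALSE)
    if (any(counts$bin_i < 0) || any(counts$bin_j < 0))
      stop("negative bin start", call. = FALSE)
    if (any(counts$bin_i %% bin_size != 0) ||
        any(counts$bin_j %% bin_size != 0))
      stop("bin starts must be multiples of bin_size (", bin_size, ")",
           call. = FALSE)
    swap <- counts$bin_i > counts$bin_j
    if (any(swap)) {
      tmp <- counts$bin_i[swap]
      counts$bin_i[swap] <- counts$bin_j[swap]
      counts$bin_j[swap] <- tmp
    }
    key <- paste(counts$bin_i, counts$bin_j)
    if (anyDuplicated(key)) {
      k <- tapply(counts$count, key, function(v) length(unique(v)))
      if (any(k > 1L))
        stop("conflicting duplicate records for the same bin pair",
             call. = FALSE)
      counts <- counts[!duplicated(key), , drop = FALSE]
    }
    counts <- counts[order(counts$bin_i, counts$bin_j), , drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(list(chrom = chrom, bin_size = bin_size, counts = counts),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s, bin size %s bp, %d observed bin pair(s)\n",
              x$chrom, .fmt_bp(x$bin_size), nrow(x$counts)))
  invisible(x)
}

#' Read / write binned contact counts (4-column TSV)
#'
#' File layout: tab-separated `chrom  bin_i_start  bin_j_start  count`, one
#' record per observed bin pair, `#` comment lines allowed. All records must
#' be on one chromosome.
#'
#' @param path file to read or write.
#' @inheritParams contact_map
#' @return `read_contacts()`: a [contact_map()].
#' @export
read_contacts <- function(path, bin_size) {
  lines <- .data_lines(path)
  if (length(lines$text) == 0L)
    stop("contact file is empty: ", path, call. = FALSE)
  parts <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop(sprintf("malformed contact record at line %d of '%s': expected 4 tab-separated columns",
                 lines$lineno[bad[1]], path), call. = FALSE)
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  chrom <- unique(m[, 1])
  if (length(chrom) != 1L)
    stop("contact map must be intra-chromosomal; found chromosomes: ",
         paste(chrom, collapse = ", "), call. = FALSE)
  df <- data.frame(bin_i = suppressWarnings(as.numeric(m[, 2])),
                   bin_j = suppressWarnings(as.numeric(m[, 3])),
                   count = suppressWarnings(as.numeric(m[, 4])))
  na <- which(is.na(df$bin_i) | is.na(df$bin_j) | is.na(df$count))
  if (length(na))
    stop(sprintf("non-numeric field at line %d of '%s'",
                 lines$lineno[na[1]], path), call. = FALSE)
  contact_map(chrom, bin_size, df)
}

#' @rdname read_contacts
#' @param map a `contact_map`.
#' @export
write_contacts <- function(map, path) {
  df <- data.frame(chrom = map$chrom,
                   bin_i = .int_chr(map$counts$bin_i),
                   bin_j = .int_chr(map$counts$bin_j),
                   count = .int_chr(map$counts$count))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname contact_map
#' @param map a `contact_map`.
#' @param bin_i,bin_j query bin starts (vectors recycle).
#' @return `contact_count()`: numeric vector of counts, 0 for unobserved
#'   pairs; symmetric in its two bin arguments.
#' @export
contact_count <- function(map, bin_i, bin_j) {
  stopifnot(inherits(map, "contact_map"))
  i <- pmin(bin_i, bin_j)
  j <- pmax(bin_i, bin_j)
  idx <- match(paste(i, j), paste(map$counts$bin_i, map$counts$bin_j))
  out <- map$counts$count[idx]
  out[is.na(out)] <- 0
  out
}
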