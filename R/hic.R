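# Hi-C fragment binning and interaction ranking (Steps 1-3 of the
# prediction procedure): fix a fragment (bin) size, find the bins harbouring
# the gene, and rank all other bins by their raw contact count with the
# gene-containing bins.

#' Genome binning at a fixed fragment size
#'
#' `bin_of()` maps a 1-based position to the start of its bin;
#' bin starts are the 0-based multiples of `bin_size` used in browser-style
#' fragment labels, so position 2,645,885 at 1 Mb falls in the bin starting
#' at 2,000,000 (the fragment printed as 2,000,000--2,999,999).
#' `gene_bins()` lists the bin starts intersecting a gene, ascending;
#' `bin_interval()` materializes bins as `GRanges`.
#'
#' @param pos 1-based position(s), `>= 1`.
#' @param bin_size bin width in bp, `> 0`.
#' @return `bin_of()`: numeric bin start(s), satisfying
#'   `bin_of(p) <= p - 1 < bin_of(p) + bin_size`.
#' @examples
#' bin_of(2645885, 1e6)    # 2000000
#' bin_of(2795015, 1e5)    # 2700000
#' @export
bin_of <- function(pos, bin_size) {
  pos <- as.numeric(pos)
  if (any(!is.finite(pos)) || any(pos < 1))
    stop("positions are 1-based and must be >= 1", call. = FALSE)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("`bin_size` must be a positive number of bp", call. = FALSE)
  floor((pos - 1) / bin_size) * bin_size
}

#' @rdname bin_of
#' @param bin_start bin start(s) (0-based multiples of `bin_size`).
#' @param chrom chromosome name.
#' @export
bin_interval <- function(bin_start, bin_size, chrom) {
  if (any(bin_start %% bin_size != 0))
    stop("bin starts must be multiples of bin_size", call. = FALSE)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = bin_start + 1,
                                          end = bin_start + bin_size))
}

#' @rdname bin_of
#' @param gene a single-interval `GRanges`.
#' @export
gene_bins <- function(gene, bin_size) {
  stopifnot(methods::is(gene, "GRanges"), length(gene) == 1L)
  seq(bin_of(GenomicRanges::start(gene), bin_size),
      bin_of(GenomicRanges::end(gene), bin_size), by = bin_size)
}

# per-bin interaction totals with a set of gene bins, over the bins observed
# in the map: total(b) = sum over g in gene_bins of count(g, b).
# An empty (all-zero) sparse map therefore yields no totals at all.
.bin_totals <- function(map, gene_bins) {
  cnt <- map$counts
  bins <- sort(unique(c(cnt$bin_i, cnt$bin_j)))
  totals <- setNames(numeric(length(bins)), .int_chr(bins))
  if (nrow(cnt)) {
    gi <- cnt$bin_i %in% gene_bins
    gj <- cnt$bin_j %in% gene_bins & cnt$bin_i != cnt$bin_j
    if (any(gi)) {
      add <- tapply(cnt$count[gi], .int_chr(cnt$bin_j[gi]), sum)
      totals[names(add)] <- totals[names(add)] + add
    }
    if (any(gj)) {
      add <- tapply(cnt$count[gj], .int_chr(cnt$bin_i[gj]), sum)
      totals[names(add)] <- totals[names(add)] + add
    }
  }
  data.frame(bin_start = bins, total_count = unname(totals))
}

.check_gene_bins <- function(map, gene_bins) {
  if (length(gene_bins) == 0L)
    stop("`gene_bins` must be non-empty", call. = FALSE)
  if (any(gene_bins < 0) || any(gene_bins %% map$bin_size != 0))
    stop("`gene_bins` are not bins of this map: starts must be non-negative ",
         "multiples of the map's bin size (", .int_chr(map$bin_size), ")",
         call. = FALSE)
}

#' Rank fragments by interaction count with the gene-containing bins
#'
#' For every bin `b` observed in the map, computes
#' `total_count(b) = sum over g in gene_bins of count(g, b)` and returns the
#' bins with `total_count >= min_count`, sorted by descending count with ties
#' broken by ascending bin start (deterministic). For genes spanning several
#' bins the totals are summed over all gene bins; [interaction_summary()]
#' provides the unranked per-bin view. With `include_self = FALSE` the gene
#' bins themselves are excluded from the ranking and reported separately
#' (the top hit of a raw ranking is typically the self-interaction).
#' Counts are used raw: no matrix balancing or expected-count normalization
#' is applied.
#'
#' @param map a [contact_map()].
#' @param gene_bins bin starts harbouring the gene (from [gene_bins()]).
#' @param min_count report only bins with at least this total (default 0).
#' @param include_self keep the gene bins in the ranking (default `TRUE`).
#' @return an object of class `interaction_ranking` with elements
#'   `ranked` (data.frame `bin_start`, `total_count`), `self`
#'   (totals of the gene bins), `gene_bins`, `min_count`, `chrom`, `bin_size`.
#' @export
rank_interacting <- function(map, gene_bins, min_count = 0,
                             include_self = TRUE) {
  stopifnot(inherits(map, "contact_map"))
  .check_gene_bins(map, gene_bins)
  if (min_count < 0) stop("`min_count` must be >= 0", call. = FALSE)
  tot <- .bin_totals(map, gene_bins)
  self_idx <- match(gene_bins, tot$bin_start)
  self <- data.frame(bin_start = gene_bins,
                     total_count = ifelse(is.na(self_idx), 0,
                                          tot$total_count[self_idx]))
  ranked <- tot
  if (!include_self)
    ranked <- ranked[!ranked$bin_start %in% gene_bins, , drop = FALSE]
  ranked <- ranked[ranked$total_count >= min_count, , drop = FALSE]
  ranked <- ranked[order(-ranked$total_count, ranked$bin_start), ,
                   drop = FALSE]
  rownames(ranked) <- rownames(self) <- NULL
  structure(list(chrom = map$chrom, bin_size = map$bin_size,
                 gene_bins = gene_bins, ranked = ranked, self = self,
                 min_count = min_count, include_self = include_self),
            class = "interaction_ranking")
}

#' @export
print.interaction_ranking <- function(x, n = 6L, ...) {
  cat(sprintf("<interaction_ranking> %s @ %s bp; gene bins: %s\n",
              x$chrom, .fmt_bp(x$bin_size),
              paste(.fmt_bp(x$gene_bins), collapse = ", ")))
  print(utils::head(x$ranked, n))
  invisible(x)
}

#' Exhaustive per-bin interaction totals
#'
#' Unranked totals for reporting, e.g. to verify that background bins stay
#' below a ceiling while the top fragments stand out. With
#' `all_bins = TRUE` every bin from 0 to the largest observed bin is listed,
#' zeros included.
#'
#' @inheritParams rank_interacting
#' @param all_bins include unobserved (zero-count) bins.
#' @return data.frame with `bin_start`, `total_count`, ascending bin start.
#' @export
interaction_summary <- function(map, gene_bins, all_bins = FALSE) {
  stopifnot(inherits(map, "contact_map"))
  .check_gene_bins(map, gene_bins)
  tot <- .bin_totals(map, gene_bins)
  if (all_bins && nrow(tot)) {
    bins <- seq(0, max(tot$bin_start), by = map$bin_size)
    idx <- match(bins, tot$bin_start)
    tot <- data.frame(bin_start = bins,
                      total_count = ifelse(is.na(idx), 0,
                                           tot$total_count[idx]))
  }
  tot[order(tot$bin_start), , drop = FALSE]
}

#' Contiguous block of interacting fragments around the gene
#'
#' Expands from the gene-containing bins in both directions, one bin at a
#' time, for as long as the bin's total interaction count with the gene bins
#' stays at or above `min_count`. This is the fragment set handed to the
#' CTCF refinement step: strongly interacting fragments plus the weakly
#' interacting bins that connect them to the gene, while isolated distant
#' bins with stray background counts are excluded.
#'
#' @inheritParams rank_interacting
#' @param min_count minimum total to keep expanding (default 1, i.e. any
#'   observed interaction).
#' @return sorted numeric vector of bin starts; always includes `gene_bins`.
#' @export
interacting_block <- function(map, gene_bins, min_count = 1) {
  stopifnot(inherits(map, "contact_map"))
  .check_gene_bins(map, gene_bins)
  tot <- .bin_totals(map, gene_bins)
  lookup <- setNames(tot$total_count, .int_chr(tot$bin_start))
  total_of <- function(b) {
    v <- lookup[.int_chr(b)]
    if (is.na(v)) 0 else unname(v)
  }
  bs <- map$bin_size
  left <- min(gene_bins)
  while (left - bs >= 0 && total_of(left - bs) >= min_count) left <- left - bs
  right <- max(gene_bins)
  while (total_of(right + bs) >= min_count) right <- right + bs
  sort(unique(c(seq(left, right, by = bs), gene_bins)))
}
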