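# Annotation of patient variants against predicted regulatory regions, plus
# cohort-tally and bisulphite-methylation utilities.

#' Annotate variants with containment, overlap and conservation evidence
#'
#' Each variant (a 1-bp interval at its VCF position) is annotated with the
#' candidate regions containing it, the features of every supplied track
#' overlapping it, its conservation score and label, and whether it is novel
#' (absent from a user-supplied known-variant list, e.g. a dbSNP extract --
#' no online lookup is performed, and identity requires matching
#' chrom/pos/ref/alt). Distances to the nearest candidate are reported
#' rather than applying any "close proximity" cutoff; interpretation is left
#' to the user.
#'
#' @param variants a [variant_table()].
#' @param candidates candidate `GRanges` from [find_candidates()] (may be
#'   empty).
#' @param tracks list of [feature_track()]s to intersect with.
#' @param known optional `variant_table` of known variants.
#' @param conservation optional `GRanges` with a numeric `score` column
#'   (e.g. from [read_bedgraph()]).
#' @param conservation_threshold label a site conserved iff its score
#'   exceeds this (default 0; positive phyloP means slower-than-neutral
#'   evolution).
#' @return data.frame of class `annotated_variants`, one row per variant:
#'   `chrom, pos, ref, alt, zygosity, n_candidates, candidate` (printed
#'   interval of the first containing candidate or `NA`),
#'   `nearest_candidate_bp`, `features` (comma-separated overlapping feature
#'   names), `conservation_score`, `conserved`, `novel`, and a list column
#'   `overlaps` with the full per-variant evidence data.frame.
#' @export
annotate_variants <- function(variants, candidates, tracks = list(),
                              known = NULL, conservation = NULL,
                              conservation_threshold = 0) {
  stopifnot(is.data.frame(variants))
  n <- nrow(variants)
  vgr <- .variant_granges(variants)
  if (length(tracks)) {
    ok <- vapply(tracks, .is_feature_track, logical(1))
    if (any(!ok))
      stop("`tracks` must be a list of feature_track objects", call. = FALSE)
  }

  n_cand <- integer(n)
  cand_lab <- rep(NA_character_, n)
  nearest <- rep(NA_real_, n)
  if (length(candidates) && n) {
    ch <- GenomicRanges::findOverlaps(vgr, candidates, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ch)
    n_cand <- tabulate(qh, nbins = n)
    first <- !duplicated(qh)
    cand_lab[qh[first]] <-
      format_printed(candidates[S4Vectors::subjectHits(ch)[first]])
    dn <- GenomicRanges::distanceToNearest(vgr, candidates,
                                           ignore.strand = TRUE)
    nearest[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance
  }

  # per-variant evidence rows, in track supply order then feature order
  pieces <- rep(list(list()), n)
  for (tr in tracks) {
    hits <- GenomicRanges::findOverlaps(vgr, tr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    if (!length(qh)) next
    sh <- S4Vectors::subjectHits(hits)
    ef <- .evidence_frame(tr[sh], track_class(tr))
    for (grp in split(seq_along(qh), qh)) {
      grp <- grp[order(sh[grp])]   # keep the track's own feature order
      i <- qh[grp[1]]
      pieces[[i]] <- c(pieces[[i]], list(ef[grp, , drop = FALSE]))
    }
  }
  empty_ev <- .evidence_frame(GenomicRanges::GRanges(), "TFBS")[0, ]
  overlaps <- lapply(pieces, function(l) {
    if (length(l) == 0L) return(empty_ev)
    out <- do.call(rbind, c(l, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
  })

  cons_score <- conservation_at(conservation, variants)
  conserved <- conservation_label(cons_score,
                                  threshold = conservation_threshold)

  novel <- rep(NA, n)
  if (!is.null(known)) {
    key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    novel <- !(key(variants) %in% key(known))
  }

  out <- data.frame(variants[, c("chrom", "pos", "ref", "alt", "zygosity")],
                    n_candidates = n_cand, candidate = cand_lab,
                    nearest_candidate_bp = nearest,
                    features = vapply(overlaps, function(df)
                      paste(unique(df$name), collapse = ","), character(1)),
                    conservation_score = cons_score, conserved = conserved,
                    novel = novel, stringsAsFactors = FALSE)
  out$overlaps <- overlaps
  class(out) <- c("annotated_variants", "data.frame")
  out
}

#' @rdname annotate_variants
#' @param variant a single-row `variant_table`.
#' @export
annotate_variant <- function(variant, candidates, tracks = list(),
                             known = NULL, conservation = NULL,
                             conservation_threshold = 0) {
  stopifnot(nrow(variant) == 1L)
  annotate_variants(variant, candidates, tracks, known, conservation,
                    conservation_threshold)
}

#' Conservation score lookup and labelling
#'
#' `conservation_at()` looks per-base conservation scores (e.g. phyloP) up
#' at variant positions; `conservation_label()` labels a score as conserved
#' iff it exceeds the threshold. The default threshold 0 follows the phyloP
#' convention that positive scores indicate slower-than-neutral (conserved)
#' evolution and negative scores acceleration; the raw score should always
#' be reported alongside the label.
#'
#' @param conservation `GRanges` with a numeric `score` column, or `NULL`.
#' @param variants a [variant_table()].
#' @return `conservation_at()`: numeric scores (`NA` where no score covers
#'   the position).
#' @export
conservation_at <- function(conservation, variants) {
  n <- nrow(variants)
  if (is.null(conservation) || n == 0L) return(rep(NA_real_, n))
  stopifnot(methods::is(conservation, "GRanges"))
  score <- S4Vectors::mcols(conservation)$score
  if (is.null(score))
    stop("conservation track must carry a `score` column", call. = FALSE)
  vgr <- .variant_granges(variants)
  hits <- GenomicRanges::findOverlaps(vgr, conservation,
                                      ignore.strand = TRUE)
  out <- rep(NA_real_, n)
  first <- !duplicated(S4Vectors::queryHits(hits))
  out[S4Vectors::queryHits(hits)[first]] <-
    as.numeric(score)[S4Vectors::subjectHits(hits)[first]]
  out
}

#' @rdname conservation_at
#' @param score numeric score(s); `NA` propagates.
#' @param threshold conserved iff `score > threshold` (default 0).
#' @return `conservation_label()`: logical vector.
#' @examples
#' conservation_label(0.557)  # TRUE
#' conservation_label(-1.2)   # FALSE
#' @export
conservation_label <- function(score, threshold = 0) {
  score <- as.numeric(score)
  ifelse(is.na(score), NA, score > threshold)
}

#' Tally cohort allele calls at a position
#'
#' Exact integer counts and exact rational frequencies of per-patient allele
#' calls, e.g. 182 C-allele and 47 T-allele carriers among 229 patients.
#'
#' @param calls character vector of per-patient alleles (one per patient).
#' @param position optional 1-based coordinate the calls refer to.
#' @return object of class `cohort_summary`: list with `position`,
#'   `allele_counts` (named integer), `n`, `frequencies` (named numeric,
#'   summing to 1).
#' @export
cohort_summary <- function(calls, position = NA_real_) {
  if (length(calls) == 0L)
    stop("`calls` must be non-empty", call. = FALSE)
  calls <- as.character(calls)
  counts <- table(calls)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(position = as.numeric(position), allele_counts = counts,
                 n = length(calls), frequencies = counts / length(calls)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  pos <- if (is.na(x$position)) "" else paste0(" @ ", .fmt_bp(x$position))
  cat(sprintf("<cohort_summary>%s n=%d: %s\n", pos, x$n,
              paste(sprintf("%s=%d (%.3f)", names(x$allele_counts),
                            x$allele_counts, x$frequencies),
                    collapse = ", ")))
  invisible(x)
}

#' Average bisulphite C-vs-T ratios into a methylation percentage
#'
#' The methylation level of a region is the arithmetic mean of the C-vs-T
#' ratios at its validated CpG sites, reported as an integer percentage.
#' The site count is checked (ten validated sites by default): a profile
#' with a missing or extra site is an error, as is any ratio outside
#' \[0, 1\]. The result does not depend on site order.
#'
#' @param ratios per-site C-vs-T ratios in \[0, 1\].
#' @param n_sites expected number of sites (default 10).
#' @return methylation level as an integer percent.
#' @examples
#' mean_methylation(rep(0.24, 10))                    # 24
#' mean_methylation(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))  # 50
#' @export
mean_methylation <- function(ratios, n_sites = 10L) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != n_sites)
    stop("expected ", n_sites, " site ratios, got ", length(ratios),
         call. = FALSE)
  if (any(is.na(ratios)) || any(ratios < 0) || any(ratios > 1))
    stop("ratios must lie in [0, 1]", call. = FALSE)
  round(mean(ratios) * 100)
}
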