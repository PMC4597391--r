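# Step 5: intersect the CTCF-bounded search region with epigenomic evidence
# tracks and emit classified candidate regulatory regions.
#
# Candidate geometry is anchor-based: a candidate is the span of a cluster of
# open-chromatin anchor features (TFBS and DNaseI-hypersensitivity calls),
# and histone-mark / enhancer / chromatin-state tracks serve only as
# corroborating evidence -- the candidate is not widened to the (much
# broader) mark domains. "Enrichment" means presence of an overlapping call:
# the inputs are already enriched-region calls from ENCODE-style pipelines,
# so no additional statistical test is applied.

MARK_CLASSES <- c("H3K4me1", "H3K27ac", "H3K4me3", "ENHANCER", "CHROMHMM")
ANCHOR_CLASSES <- c("TFBS", "DNase")

# chromatin-state calls counted as evidence of activity
.chromhmm_active <- function(name) {
  name <- as.character(name)
  grepl("active|promoter|enhancer|tss|transcri", name, ignore.case = TRUE) &
    !grepl("poised|weak|inactive|repres|heterochrom|quies", name,
           ignore.case = TRUE)
}

.chromhmm_promoter <- function(name) {
  .chromhmm_active(name) &
    grepl("promoter|tss", as.character(name), ignore.case = TRUE)
}

# Cell-line substitution rule: one primary cell line is configured; for each
# track class, tracks assayed in the primary line are preferred, and tracks
# from other lines are used only when the class is entirely absent from the
# primary line (mirroring mark tracks missing for the Hi-C cell line being
# substituted from a related line).
.select_tracks <- function(tracks, primary_cell_line) {
  if (is.null(primary_cell_line)) return(tracks)
  cls <- vapply(tracks, track_class, character(1))
  lines <- vapply(tracks, track_cell_line, character(1))
  keep <- rep(TRUE, length(tracks))
  for (cl in unique(cls)) {
    in_cl <- cls == cl
    if (any(lines[in_cl] == primary_cell_line))
      keep[in_cl & lines != primary_cell_line] <- FALSE
  }
  tracks[keep]
}

.evidence_frame <- function(feats, class) {
  mc <- S4Vectors::mcols(feats)
  data.frame(track_class = rep(class, length(feats)),
             name = as.character(mc$name %||% rep(class, length(feats))),
             start = GenomicRanges::start(feats),
             end = GenomicRanges::end(feats),
             score = as.numeric(mc$score %||% rep(NA_real_, length(feats))),
             cell_line = as.character(mc$cell_line %||%
                                        rep("", length(feats))),
             stringsAsFactors = FALSE)
}

#' Find candidate regulatory regions within a search region
#'
#' Emits one candidate per maximal cluster of anchor features (TFBS and
#' DNase calls whose mutual gaps are at most `cluster_gap`) lying inside the
#' search region, provided the cluster overlaps calls from at least
#' `min_mark_classes` distinct corroborating mark classes
#' (H3K4me1, H3K27ac, H3K4me3, enhancer calls, or active chromatin states).
#' The candidate interval is the anchor-cluster span. Every overlapping
#' feature from every supplied track is recorded as evidence, and candidates
#' are classified ([classify_candidate()]) and returned sorted by start.
#'
#' @param region a `search_region` (from [refine_search_region()]) or a
#'   single-interval `GRanges`.
#' @param tracks list of [feature_track()]s; at least one TFBS or DNase
#'   track is required. All features must be on the region's chromosome.
#' @param cluster_gap maximal gap between anchor features in one cluster,
#'   bp (default 200).
#' @param min_mark_classes minimum number of distinct corroborating mark
#'   classes (default 1).
#' @param primary_cell_line preferred cell line; tracks from other lines are
#'   used for a class only when that class is absent in the primary line.
#'   `NULL` (default) uses every track.
#' @return a `GRanges` of candidates, sorted by start, with metadata columns
#'   `region_class` (`promoter_like`/`enhancer_like`/`unclassified`),
#'   `n_mark_classes`, `mark_classes` (comma-separated) and `evidence` (one
#'   data.frame per candidate; see [candidate_evidence()]).
#' @export
find_candidates <- function(region, tracks, cluster_gap = 200,
                            min_mark_classes = 1,
                            primary_cell_line = NULL) {
  if (inherits(region, "search_region")) region <- region$interval
  stopifnot(methods::is(region, "GRanges"), length(region) == 1L)
  if (!is.list(tracks) || length(tracks) == 0L)
    stop("no evidence tracks supplied", call. = FALSE)
  ok <- vapply(tracks, .is_feature_track, logical(1))
  if (any(!ok))
    stop("`tracks` must be a list of feature_track objects", call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(region))
  for (tr in tracks) {
    sq <- as.character(GenomicRanges::seqnames(tr))
    if (length(sq) && any(sq != chrom))
      stop("track '", track_class(tr),
           "' has features on a different chromosome than the search region",
           call. = FALSE)
  }
  cls_all <- vapply(tracks, track_class, character(1))
  if (!any(cls_all %in% ANCHOR_CLASSES))
    stop("at least one TFBS or DNase (anchor) track is required",
         call. = FALSE)
  tracks <- .select_tracks(tracks, primary_cell_line)
  cls <- vapply(tracks, track_class, character(1))

  anchors <- GenomicRanges::GRanges()
  for (tr in tracks[cls %in% ANCHOR_CLASSES])
    anchors <- c(anchors, GenomicRanges::granges(tr))
  anchors <- anchors[IRanges::overlapsAny(anchors, region,
                                                type = "within",
                                                ignore.strand = TRUE)]
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
    region_class = character(0), n_mark_classes = integer(0),
    mark_classes = character(0), evidence = I(list()))
  if (length(anchors) == 0L) return(empty)
  clusters <- GenomicRanges::reduce(anchors, min.gapwidth = cluster_gap + 1,
                                    ignore.strand = TRUE)
  clusters <- sort(clusters)

  # distinct corroborating mark classes overlapping each cluster
  mark_hits <- matrix(FALSE, nrow = length(clusters),
                      ncol = length(MARK_CLASSES),
                      dimnames = list(NULL, MARK_CLASSES))
  for (tr in tracks[cls %in% MARK_CLASSES]) {
    feats <- tr
    if (track_class(tr) == "CHROMHMM")
      feats <- feats[.chromhmm_active(S4Vectors::mcols(feats)$name)]
    if (length(feats) == 0L) next
    hit <- IRanges::overlapsAny(clusters, feats, ignore.strand = TRUE)
    mark_hits[, track_class(tr)] <- mark_hits[, track_class(tr)] | hit
  }
  n_marks <- rowSums(mark_hits)
  keep <- n_marks >= min_mark_classes
  if (!any(keep)) return(empty)
  cand <- clusters[keep]
  mark_hits <- mark_hits[keep, , drop = FALSE]

  evidence <- lapply(seq_along(cand), function(i) {
    do.call(rbind, c(lapply(tracks, function(tr) {
      ov <- intersect_features(cand[i], GenomicRanges::granges(tr,
                                                use.mcols = TRUE))
      .evidence_frame(ov, track_class(tr))
    }), list(make.row.names = FALSE)))
  })
  S4Vectors::mcols(cand)$region_class <-
    vapply(evidence, classify_candidate, character(1))
  S4Vectors::mcols(cand)$n_mark_classes <- as.integer(rowSums(mark_hits))
  S4Vectors::mcols(cand)$mark_classes <- apply(mark_hits, 1, function(r)
    paste(MARK_CLASSES[r], collapse = ","))
  S4Vectors::mcols(cand)$evidence <- I(evidence)
  cand
}

#' @rdname find_candidates
#' @param candidates a candidate `GRanges` from `find_candidates()`.
#' @param i candidate index.
#' @export
candidate_evidence <- function(candidates, i = 1L) {
  S4Vectors::mcols(candidates)$evidence[[i]]
}

#' Classify a candidate region from its evidence
#'
#' `promoter_like` if the evidence includes an H3K4me3 mark or an active
#' promoter chromatin state (promoter evidence takes precedence);
#' otherwise `enhancer_like` if it includes H3K4me1, H3K27ac or an enhancer
#' call; otherwise `unclassified` (anchors alone -- open chromatin with no
#' characteristic mark -- do not classify a region).
#'
#' @param evidence an evidence data.frame (see [candidate_evidence()]), or a
#'   length-1 candidate `GRanges` carrying an `evidence` column.
#' @return one of `"promoter_like"`, `"enhancer_like"`, `"unclassified"`.
#' @export
classify_candidate <- function(evidence) {
  if (methods::is(evidence, "GRanges")) {
    stopifnot(length(evidence) == 1L)
    evidence <- S4Vectors::mcols(evidence)$evidence[[1]]
  }
  stopifnot(is.data.frame(evidence))
  cls <- evidence$track_class
  if ("H3K4me3" %in% cls ||
      any(cls == "CHROMHMM" & .chromhmm_promoter(evidence$name)))
    return("promoter_like")
  if (any(cls %in% c("H3K4me1", "H3K27ac", "ENHANCER")))
    return("enhancer_like")
  "unclassified"
}

#' Signed distance from candidate regions to a gene
#'
#' 0 for overlapping intervals; otherwise the gap in bp, negative when the
#' candidate lies upstream of the gene start and positive when downstream of
#' the gene end. Report layers print this in kb rounded to one decimal
#' (a candidate ending 13,696 bp before the gene start reads "~13.7 kb
#' upstream").
#'
#' @param x candidate `GRanges` (any length).
#' @param gene single-interval `GRanges` on the same chromosome.
#' @return numeric vector of signed distances in bp.
#' @export
distance_to_gene <- function(x, gene) {
  stopifnot(methods::is(x, "GRanges"), methods::is(gene, "GRanges"),
            length(gene) == 1L)
  if (length(x) == 0L) return(numeric(0))
  if (any(as.character(GenomicRanges::seqnames(x)) !=
          as.character(GenomicRanges::seqnames(gene))))
    stop("candidates and gene must be on the same chromosome", call. = FALSE)
  gs <- GenomicRanges::start(gene)
  ge <- GenomicRanges::end(gene)
  s <- GenomicRanges::start(x)
  e <- GenomicRanges::end(x)
  ifelse(e < gs, -(gs - e - 1), ifelse(s > ge, s - ge - 1, 0))
}
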