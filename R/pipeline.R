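# Orchestration of the six prediction steps, and the report writers.

#' Run the prediction pipeline (Steps 1-5)
#'
#' Executes the full in silico prediction for one gene: bins the genome at
#' the supplied fragment size(s) and locates the gene-containing fragments
#' (Steps 1-2), ranks fragments by interaction count and takes the
#' contiguous interacting block around the gene (Step 3,
#' [interacting_block()]), refines it to a CTCF-bounded search region
#' (Step 4, [refine_search_region()]) and intersects the region with the
#' evidence tracks to emit classified candidates (Step 5,
#' [find_candidates()]). Every intermediate is recorded in the returned
#' report.
#'
#' @param gene single-interval `GRanges`.
#' @param map_fine [contact_map()] at the fine fragment size (e.g. 100 kb),
#'   used for fragment selection and refinement.
#' @param tracks named list of [feature_track()]s; must include a CTCF
#'   track and at least one TFBS or DNase track.
#' @param map_coarse optional coarser map (e.g. 1 Mb) ranked for the report.
#' @param min_count minimum interaction total for block expansion
#'   (see [interacting_block()]).
#' @param ctcf_threshold,ctcf_cluster_gap,policy passed to
#'   [refine_search_region()].
#' @param cluster_gap,min_mark_classes,primary_cell_line passed to
#'   [find_candidates()].
#' @param verbose narrate each step via `message()`.
#' @return an object of class `prediction_report`: list with `gene`,
#'   `coarse` (gene bins + ranking, or `NULL`), `fine` (gene bins, ranking,
#'   interacting block), `search_region`, `candidates` (with
#'   `distance_to_gene_bp` column added), and `params`.
#' @export
predict_regulatory_regions <- function(gene, map_fine, tracks,
                                       map_coarse = NULL, min_count = 1,
                                       ctcf_threshold = 500,
                                       ctcf_cluster_gap = 5000,
                                       cluster_gap = 200,
                                       min_mark_classes = 1,
                                       primary_cell_line = NULL,
                                       policy = "outermost",
                                       verbose = FALSE) {
  stopifnot(methods::is(gene, "GRanges"), length(gene) == 1L,
            inherits(map_fine, "contact_map"))
  say <- function(...) if (verbose) message(sprintf(...))
  cls <- vapply(tracks, track_class, character(1))
  if (!any(cls == "CTCF"))
    stop("a CTCF track is required for boundary refinement", call. = FALSE)
  ctcf <- tracks[[which(cls == "CTCF")[1]]]

  coarse <- NULL
  if (!is.null(map_coarse)) {
    gb_c <- gene_bins(gene, map_coarse$bin_size)
    coarse <- list(bin_size = map_coarse$bin_size, gene_bins = gb_c,
                   ranking = rank_interacting(map_coarse, gb_c))
    say("Step 1-2 (%s bp): gene occupies fragment(s) %s",
        .fmt_bp(map_coarse$bin_size), paste(.fmt_bp(gb_c), collapse = ", "))
  }
  gb_f <- gene_bins(gene, map_fine$bin_size)
  ranking <- rank_interacting(map_fine, gb_f)
  block <- interacting_block(map_fine, gb_f, min_count = min_count)
  say("Step 3 (%s bp): interacting block %s-%s (%d fragment(s))",
      .fmt_bp(map_fine$bin_size), .fmt_bp(min(block)),
      .fmt_bp(max(block) + map_fine$bin_size - 1), length(block))
  bins_gr <- bin_interval(block, map_fine$bin_size, map_fine$chrom)
  region <- refine_search_region(gene, bins_gr, ctcf,
                                 threshold = ctcf_threshold,
                                 cluster_gap = ctcf_cluster_gap,
                                 policy = policy)
  say("Step 4: search region %s (%s)", format_printed(region$interval),
      region$rationale)
  candidates <- find_candidates(region, tracks, cluster_gap = cluster_gap,
                                min_mark_classes = min_mark_classes,
                                primary_cell_line = primary_cell_line)
  if (length(candidates))
    S4Vectors::mcols(candidates)$distance_to_gene_bp <-
      distance_to_gene(candidates, gene)
  say("Step 5: %d candidate(s): %s", length(candidates),
      paste(format_printed(candidates), collapse = ", "))
  structure(list(
    version = "1.0", gene = gene,
    coarse = coarse,
    fine = list(bin_size = map_fine$bin_size, gene_bins = gb_f,
                ranking = ranking, interacting_block = block),
    search_region = region, candidates = candidates,
    params = list(min_count = min_count, ctcf_threshold = ctcf_threshold,
                  ctcf_cluster_gap = ctcf_cluster_gap,
                  cluster_gap = cluster_gap,
                  min_mark_classes = min_mark_classes,
                  primary_cell_line = primary_cell_line, policy = policy)),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> gene %s\n", format_printed(x$gene)))
  cat(sprintf("  search region: %s\n", format_printed(x$search_region$interval)))
  cat(sprintf("  %d candidate(s)\n", length(x$candidates)))
  for (i in seq_along(x$candidates)) {
    cand <- x$candidates[i]
    cat(sprintf("  - %s [%s], %.1f kb from gene\n", format_printed(cand),
                S4Vectors::mcols(cand)$region_class,
                S4Vectors::mcols(cand)$distance_to_gene_bp / 1000))
  }
  invisible(x)
}

#' Validate all candidates against loop-call sets (Step 6)
#'
#' Runs [validate_candidate()] for each candidate against each supplied loop
#' source and tabulates the statuses.
#'
#' @param candidates candidate `GRanges` from [find_candidates()].
#' @param promoter single-interval promoter `GRanges`.
#' @param loop_sets named list of [loop_calls()] tables (e.g.
#'   `list(in_situ_hic = ..., capture_hic = ...)`).
#' @param min_separation passed to [validate_candidate()].
#' @return data.frame with one row per candidate x source: candidate
#'   coordinates, `source`, `status`, `separation_bp`, `n_matching_loops`,
#'   and the matching anchor coordinates (BEDPE form, `NA` when
#'   unsupported); the underlying `loop_validation` objects are attached as
#'   attribute `"validations"`.
#' @export
validate_candidates <- function(candidates, promoter, loop_sets,
                                min_separation = 20000) {
  stopifnot(is.list(loop_sets), length(loop_sets) > 0L)
  rows <- list()
  vals <- list()
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    for (src in names(loop_sets)) {
      v <- validate_candidate(cand, promoter, loop_sets[[src]],
                              min_separation = min_separation)
      vals[[length(vals) + 1L]] <- v
      m <- v$matching_loops
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_start = GenomicRanges::start(cand),
        candidate_end = GenomicRanges::end(cand),
        source = src, status = v$status, separation_bp = v$separation,
        n_matching_loops = nrow(m),
        anchor_a_start = if (nrow(m)) m$start_a[1] else NA_real_,
        anchor_b_start = if (nrow(m)) m$start_b[1] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(candidate_start = numeric(0), candidate_end = numeric(0),
               source = character(0), status = character(0),
               separation_bp = numeric(0), n_matching_loops = integer(0),
               anchor_a_start = numeric(0), anchor_b_start = numeric(0))
  attr(out, "validations") <- vals
  out
}

#' Write candidates as BED and the full report as JSON
#'
#' The BED file is 0-based half-open with the candidate class in the name
#' column; the JSON report (schema version in its `version` field) records
#' every intermediate of the run -- gene fragments, interaction ranking,
#' search region with boundary provenance, candidates with their evidence
#' and distances (1-based inclusive coordinates, as in genome-browser
#' reports) -- plus any loop validations passed in.
#'
#' @param candidates candidate `GRanges`.
#' @param path output file.
#' @export
write_candidates_bed <- function(candidates, path) {
  gr <- GenomicRanges::granges(candidates)
  n <- length(gr)
  S4Vectors::mcols(gr)$name <- if (n)
    S4Vectors::mcols(candidates)$region_class else character(0)
  S4Vectors::mcols(gr)$score <- rep(0, n)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

.gr_record <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  list(chrom = as.character(GenomicRanges::seqnames(x))[1],
       start = GenomicRanges::start(x)[1], end = GenomicRanges::end(x)[1])
}

.report_to_list <- function(report, validations = NULL,
                            annotated = NULL) {
  cand <- report$candidates
  cand_list <- lapply(seq_along(cand), function(i) {
    mc <- S4Vectors::mcols(cand[i])
    c(.gr_record(cand[i]),
      list(region_class = mc$region_class,
           n_mark_classes = mc$n_mark_classes,
           mark_classes = mc$mark_classes,
           distance_to_gene_bp = mc$distance_to_gene_bp %||% NA_real_,
           distance_to_gene_kb = round((mc$distance_to_gene_bp %||%
                                          NA_real_) / 1000, 1),
           evidence = mc$evidence[[1]]))
  })
  sr <- report$search_region
  boundary <- function(b) list(
    type = b$type, coordinate = b$coord,
    strength = if (!is.na(b$strength %||% NA)) b$strength else NULL)
  out <- list(
    version = report$version, generated_by = "remreg",
    gene = .gr_record(report$gene),
    params = report$params,
    coarse = if (!is.null(report$coarse)) list(
      bin_size = report$coarse$bin_size,
      gene_bins = report$coarse$gene_bins,
      ranking = utils::head(report$coarse$ranking$ranked, 20)),
    fine = list(bin_size = report$fine$bin_size,
                gene_bins = report$fine$gene_bins,
                interacting_block = report$fine$interacting_block,
                ranking = utils::head(report$fine$ranking$ranked, 20)),
    search_region = list(
      interval = .gr_record(sr$interval), policy = sr$policy,
      upstream = boundary(sr$upstream),
      downstream = boundary(sr$downstream), rationale = sr$rationale),
    candidates = cand_list)
  if (!is.null(validations)) {
    v <- validations
    attr(v, "validations") <- NULL
    out$loop_validation <- v
  }
  if (!is.null(annotated)) {
    a <- annotated
    a$overlaps <- NULL
    class(a) <- "data.frame"
    out$annotated_variants <- a
  }
  out
}

#' @rdname write_candidates_bed
#' @param report a `prediction_report`.
#' @param validations optional [validate_candidates()] table.
#' @param annotated optional [annotate_variants()] table.
#' @export
write_report_json <- function(report, path, validations = NULL,
                              annotated = NULL) {
  stopifnot(inherits(report, "prediction_report"))
  jsonlite::write_json(.report_to_list(report, validations, annotated),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
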