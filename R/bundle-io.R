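# Writing a locus bundle to disk in the standard formats (BED, narrowPeak,
# BEDPE, VCF, bedGraph, 4-column contact TSV) and reading it back, so the
# command-line interface and end-to-end tests consume files rather than
# in-memory objects.

#' Write / read a locus bundle on disk
#'
#' `write_locus_bundle()` lays a bundle out as: `gene.bed`, `promoter.bed`,
#' `tracks/<name>.bed` (DNase tracks as `.narrowPeak`),
#' `contacts_fine.tsv` / `contacts_coarse.tsv`, `loops_insitu.bedpe` /
#' `loops_capture.bedpe`, `variants.vcf`, `known_variants.vcf`,
#' `conservation.bedGraph`, and a `meta.json` recording chromosome, bin
#' sizes, per-track classes and cell lines, and the planted interval if
#' any. `read_locus_bundle()` reconstructs the bundle from such a
#' directory.
#'
#' @param bundle a `locus_bundle` (from [paper_locus()] or
#'   [random_locus()]).
#' @param dir directory to write into (created if missing).
#' @return the directory (`write`) or a `locus_bundle` (`read`).
#' @export
write_locus_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "locus_bundle"))
  dir.create(file.path(dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  gene <- bundle$gene
  if (is.null(S4Vectors::mcols(gene)$name))
    S4Vectors::mcols(gene)$name <- bundle$gene_name %||% "gene"
  write_track_bed(gene, file.path(dir, "gene.bed"))
  write_track_bed(bundle$promoter, file.path(dir, "promoter.bed"))
  for (nm in names(bundle$tracks)) {
    tr <- bundle$tracks[[nm]]
    if (track_class(tr) == "DNase")
      write_narrowpeak(tr, file.path(dir, "tracks",
                                     paste0(nm, ".narrowPeak")))
    else
      write_track_bed(tr, file.path(dir, "tracks", paste0(nm, ".bed")))
  }
  write_contacts(bundle$map_fine, file.path(dir, "contacts_fine.tsv"))
  if (!is.null(bundle$map_coarse))
    write_contacts(bundle$map_coarse, file.path(dir, "contacts_coarse.tsv"))
  write_loops_bedpe(bundle$loops_insitu, file.path(dir,
                                                   "loops_insitu.bedpe"))
  write_loops_bedpe(bundle$loops_capture, file.path(dir,
                                                    "loops_capture.bedpe"))
  write_variants_vcf(bundle$variants, file.path(dir, "variants.vcf"))
  write_variants_vcf(bundle$known_variants,
                     file.path(dir, "known_variants.vcf"))
  if (!is.null(bundle$conservation))
    write_bedgraph(bundle$conservation,
                   file.path(dir, "conservation.bedGraph"))
  meta <- list(
    chrom = bundle$chrom, genome = bundle$genome %||% "unknown",
    gene_name = bundle$gene_name %||% "gene",
    bin_size_fine = bundle$map_fine$bin_size,
    bin_size_coarse = if (!is.null(bundle$map_coarse))
      bundle$map_coarse$bin_size else NULL,
    tracks = lapply(bundle$tracks, function(tr)
      list(track_class = track_class(tr),
           cell_line = track_cell_line(tr))),
    planted = if (!is.null(bundle$planted))
      c(GenomicRanges::start(bundle$planted),
        GenomicRanges::end(bundle$planted)) else NULL,
    cohort = bundle$cohort, methylation = bundle$methylation)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_locus_bundle
#' @export
read_locus_bundle <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop("not a bundle directory (no meta.json): ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  gene_tr <- read_bed(file.path(dir, "gene.bed"), "TFBS")  # carrier only
  gene <- GenomicRanges::granges(gene_tr)
  S4Vectors::mcols(gene)$name <- S4Vectors::mcols(gene_tr)$name
  promoter <- GenomicRanges::granges(
    read_bed(file.path(dir, "promoter.bed"), "TFBS"))
  tracks <- list()
  for (nm in names(meta$tracks)) {
    info <- meta$tracks[[nm]]
    bed <- file.path(dir, "tracks", paste0(nm, ".bed"))
    np <- file.path(dir, "tracks", paste0(nm, ".narrowPeak"))
    tracks[[nm]] <- if (file.exists(np))
      read_narrowpeak(np, info$track_class, info$cell_line)
    else read_bed(bed, info$track_class, info$cell_line)
  }
  coarse_path <- file.path(dir, "contacts_coarse.tsv")
  cons_path <- file.path(dir, "conservation.bedGraph")
  structure(list(
    chrom = meta$chrom, genome = meta$genome, gene = gene,
    gene_name = meta$gene_name, promoter = promoter,
    map_coarse = if (file.exists(coarse_path))
      read_contacts(coarse_path, meta$bin_size_coarse) else NULL,
    map_fine = read_contacts(file.path(dir, "contacts_fine.tsv"),
                             meta$bin_size_fine),
    tracks = tracks,
    loops_insitu = read_loops_bedpe(file.path(dir, "loops_insitu.bedpe"),
                                    source = "in_situ_hic"),
    loops_capture = read_loops_bedpe(file.path(dir, "loops_capture.bedpe"),
                                     source = "capture_hic"),
    variants = read_vcf_variants(file.path(dir, "variants.vcf")),
    known_variants = read_vcf_variants(file.path(dir,
                                                 "known_variants.vcf")),
    conservation = if (file.exists(cons_path))
      read_bedgraph(cons_path) else NULL,
    cohort = meta$cohort, methylation = meta$methylation,
    planted = if (!is.null(meta$planted))
      from_printed(meta$chrom, meta$planted[1], meta$planted[2]) else NULL,
    config = NULL), class = "locus_bundle")
}
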