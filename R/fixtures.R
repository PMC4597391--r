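# Synthetic locus bundles: a deterministic worked-example locus on chr18
# around the SMCHD1 gene, and seeded random loci with planted regulatory
# elements plus decoys for benchmarking. Bundles carry everything the
# pipeline consumes, and can be written to / read from disk in the standard
# formats so the command-line interface runs against files.

#' The worked-example locus: SMCHD1 on chromosome 18 (hg18)
#'
#' Builds, entirely in code and byte-identically on every call, the bundle
#' of inputs for the chr18 locus around the SMCHD1 gene
#' (positions 2,645,885--2,795,015, hg18): binned contact maps at 1 Mb and
#' 100 kb, CTCF / histone-mark / DNase / TFBS / enhancer / chromatin-state
#' tracks, in situ Hi-C loop calls, three patient variants with phyloP
#' scores, a known-variant list, a cohort allele tally and a bisulphite
#' methylation profile.
#'
#' Coordinates, scores and counts follow the published description of this
#' locus. Where only a region's span or a site's existence is published
#' (BATF and SPI1 binding sites, the distal TFBS/DNase peak, off-diagonal
#' and background contact counts), the features are synthetic: placed inside
#' the published spans so that cluster extents and interaction totals match
#' the published values. Those features carry `synthetic` in their names.
#'
#' @return an object of class `locus_bundle`; see [random_locus()] for the
#'   shared bundle shape.
#' @export
paper_locus <- function() {
  chrom <- "chr18"
  gi <- function(s, e) from_printed(chrom, s, e)
  trk <- function(s, e, name, score, class, cell = "GM06990") {
    gr <- gi(s, e)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = name, score = score,
                                                 cell_line = cell)
    feature_track(gr, class, cell)
  }
  gene <- gi(2645885, 2795015)
  S4Vectors::mcols(gene)$name <- "SMCHD1"

  # 1-Mb map: the gene-containing fragment interacts most strongly with
  # itself (3371) and the adjacent downstream fragment (663); everything
  # else is background below ~30.
  map_coarse <- contact_map(chrom, 1e6, data.frame(
    bin_i = c(2e6, 2e6, 1e6, 0, 2e6, 2e6),
    bin_j = c(2e6, 3e6, 2e6, 2e6, 4e6, 5e6),
    count = c(3371, 663, 25, 12, 19, 8)))

  # 100-kb map: the two gene fragments interact most strongly with
  # themselves (256, 237); the fragment holding the upstream CTCF cluster
  # totals 23 with the gene fragments; other totals stay below 30.
  map_fine <- contact_map(chrom, 1e5, data.frame(
    bin_i = c(2.6e6, 2.7e6, 2.6e6, 2.5e6, 2.5e6, 2.6e6, 2.7e6, 2.6e6,
              2.7e6, 1.2e6, 2.7e6),
    bin_j = c(2.6e6, 2.7e6, 2.7e6, 2.6e6, 2.7e6, 2.8e6, 2.8e6, 2.9e6,
              2.9e6, 2.6e6, 4.0e6),
    count = c(256, 237, 28, 15, 8, 9, 12, 7, 10, 11, 6)))

  tracks <- list(
    # two weak upstream sites spanning 2,531,952-2,537,783 and one strong
    # downstream site at 2,922,164-2,922,551 (score 719)
    ctcf = trk(c(2531952, 2537000, 2922164),
               c(2533000, 2537783, 2922551),
               c("CTCF_weak_a", "CTCF_weak_b", "CTCF_strong"),
               c(380, 444, 719), "CTCF"),
    h3k4me1_gm12878 = trk(2624475, 2635775, "H3K4me1", 600, "H3K4me1",
                          "GM12878"),
    h3k27ac_gm12878 = trk(2624475, 2635775, "H3K27ac", 600, "H3K27ac",
                          "GM12878"),
    h3k4me1_distal = trk(2557575, 2566775, "H3K4me1", 500, "H3K4me1",
                         "HUVEC"),
    h3k27ac_distal = trk(2557575, 2566775, "H3K27ac", 500, "H3K27ac",
                         "HUVEC"),
    # active-promoter mark over the gene promoter; distal span synthetic,
    # tied to the active-promoter chromatin state at 2,560,200-2,563,800
    h3k4me3 = trk(c(2644486, 2560200), c(2648785, 2563800),
                  c("H3K4me3", "H3K4me3_synthetic_distal"),
                  c(700, 600), "H3K4me3"),
    dnase = trk(c(2631700, 2561600), c(2631930, 2562400),
                c("DHS", "DHS_synthetic_distal"),
                c(976, 800), "DNase"),
    tfbs = trk(
      c(2631639, 2631540, 2631654, 2631672, 2631527, 2631798,
        2561489, 2562000),
      c(2632023, 2632016, 2632010, 2631955, 2631905, 2632188,
        2562100, 2562509),
      c("IRF1", "STAT1", "STAT2", "RUNX3",
        "BATF_synthetic_span", "SPI1_synthetic_span",
        "TFBS_synthetic_distal_a", "TFBS_synthetic_distal_b"),
      c(1000, 1000, 1000, 1000, 873, 841, 900, 870), "TFBS"),
    enhancer = trk(2631000, 2632200, "enhancer", 900, "ENHANCER", ""),
    chromhmm = trk(2560200, 2563800, "Active_Promoter", 1000, "CHROMHMM",
                   "GM12878"))

  # strong looping interaction between the 5-kb promoter fragment
  # (2,640,000-2,645,000) and the 5-kb fragment holding the variants
  # (2,630,000-2,635,000); Capture Hi-C lists report nothing here because
  # the separation is below their 20-kb floor.
  loops_insitu <- loop_calls(chrom, 2630000, 2635000, chrom, 2640000,
                             2645000, name = "SMCHD1_promoter_loop",
                             score = 100, source = "in_situ_hic",
                             resolution = 5000)
  loops_capture <- loop_calls(source = "capture_hic", resolution = 5000)
  promoter <- GenomicRanges::GRanges(chrom, IRanges::IRanges(2640001,
                                                             2645000))

  variants <- variant_table(
    chrom = rep(chrom, 3),
    pos = c(2631610, 2631858, 2631886),
    ref = c("T", "T", "G"), alt = c("C", "C", "A"),
    zygosity = "het")
  known <- variant_table(chrom, 2631858, "T", "C", "unknown")  # rs7229070
  conservation <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(c(2631610, 2631858, 2631886),
                            c(2631610, 2631858, 2631886)),
    score = c(0.557, 0.691, 0.431))

  structure(list(
    chrom = chrom, genome = "hg18", gene = gene, gene_name = "SMCHD1",
    promoter = promoter, map_coarse = map_coarse, map_fine = map_fine,
    tracks = tracks, loops_insitu = loops_insitu,
    loops_capture = loops_capture, variants = variants,
    known_variants = known, conservation = conservation,
    cohort = list(position = 2631858,
                  calls = c(rep("C", 182), rep("T", 47))),
    methylation = rep(0.24, 10),
    planted = NULL, config = NULL), class = "locus_bundle")
}

#' Simulation settings for randomized loci
#'
#' Defaults mirror the contrast the worked-example locus exhibits: planted
#' contact counts of 3371 (gene-fragment self-interaction) and 663 (planted
#' fragment) over a uniform background capped at 30, a 100-kb fragment size,
#' and a ~1-kb planted element. All randomness derives from the single
#' integer `seed`.
#'
#' @param seed integer seed governing every random draw.
#' @param chrom chromosome name of the simulated locus.
#' @param chrom_length chromosome length, bp.
#' @param bin_size contact-map fragment size, bp.
#' @param n_decoys decoy regions, each lacking at least one required
#'   evidence class.
#' @param background_count_max background contact-count ceiling; must stay
#'   below the planted counts.
#' @param planted_counts named vector `c(self = , planted = )`: contact
#'   counts for the gene bin self-interaction and for the planted bin's
#'   interaction with the gene bin.
#' @param planted_width width of the planted element, bp.
#' @param planted_region optional explicit planted interval
#'   (`c(start, end)`, 1-based); `NULL` places it randomly.
#' @param n_variants variants planted inside the element.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, chrom = "chrS", chrom_length = 5e6,
                       bin_size = 1e5, n_decoys = 3L,
                       background_count_max = 30,
                       planted_counts = c(self = 3371, planted = 663),
                       planted_width = 1000, planted_region = NULL,
                       n_variants = 2L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (background_count_max >= min(planted_counts))
    stop("background ceiling must stay below the planted counts",
         call. = FALSE)
  if (!is.null(planted_region)) {
    if (length(planted_region) != 2L || planted_region[1] < 1 ||
        planted_region[2] > chrom_length ||
        planted_region[2] <= planted_region[1])
      stop("planted region outside chromosome", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), chrom = chrom,
                 chrom_length = chrom_length, bin_size = bin_size,
                 n_decoys = as.integer(n_decoys),
                 background_count_max = background_count_max,
                 planted_counts = planted_counts,
                 planted_width = planted_width,
                 planted_region = planted_region,
                 n_variants = as.integer(n_variants)),
            class = "sim_config")
}

#' Randomized locus with a planted regulatory element
#'
#' Generates a locus bundle of the same shape as [paper_locus()]:
#' a gene with a promoter, a contact map in which the gene fragment
#' interacts strongly with itself and with the fragment containing the
#' planted element (background counts uniform below the ceiling), flanking
#' CTCF sites delimiting a search region that contains the element, a
#' planted element with a co-occurring TFBS cluster + DNase peak +
#' enhancer-mark evidence and an in situ loop to the promoter, `n_decoys`
#' decoy regions each lacking a required evidence class (anchors without
#' marks, or marks without anchors), and variants planted inside the
#' element. Everything is reproducible from the seed, and the planted
#' interval is recorded in the bundle (`$planted`) as the recovery oracle.
#'
#' @param config a [sim_config()].
#' @return list of class `locus_bundle` with elements `chrom`, `gene`,
#'   `promoter`, `map_coarse` (`NULL` here), `map_fine`, `tracks` (named
#'   list of [feature_track()]s), `loops_insitu`, `loops_capture`,
#'   `variants`, `known_variants`, `conservation`, `planted`, `config`.
#' @export
random_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .build_random_locus(config))
}

.build_random_locus <- function(cfg) {
  chrom <- cfg$chrom
  bs <- cfg$bin_size
  nb <- floor(cfg$chrom_length / bs)
  if (nb < 8L) stop("chromosome too short for the simulated geometry",
                    call. = FALSE)
  rint <- function(lo, hi) lo + floor(runif(1) * (hi - lo + 1))

  # gene occupying one or two fragments near 70% of the chromosome, with
  # >= 12 kb left free after the gene end inside its last fragment so a
  # downstream CTCF site fits within the interacting fragments
  gb_first <- floor(0.7 * nb)
  gstart <- gb_first * bs + rint(5000, 20000)
  gwidth <- rint(120000, 160000)
  gend <- gstart + gwidth - 1
  last_bin <- bin_of(gend, bs)
  if (gend > last_bin + bs - 12000) gend <- last_bin + bs - 12000
  gene <- from_printed(chrom, gstart, gend)
  S4Vectors::mcols(gene)$name <- "simgene"
  gbins <- gene_bins(gene, bs)

  # planted element 2-3 fragments upstream of the gene
  if (is.null(cfg$planted_region)) {
    pbin <- (gb_first - rint(2, 3)) * bs
    pstart <- pbin + rint(20000, bs - 30000)
    pend <- pstart + cfg$planted_width - 1
  } else {
    pstart <- cfg$planted_region[1]
    pend <- cfg$planted_region[2]
    pbin <- bin_of(pstart, bs)
  }
  if (pstart < 1 || pend > cfg$chrom_length)
    stop("planted region outside chromosome", call. = FALSE)
  planted <- from_printed(chrom, pstart, pend)

  # contact map: gene self-interaction + planted-bin interaction dominate;
  # every fragment between them keeps a nonzero background count with the
  # gene so the interacting block is contiguous; far background pairs avoid
  # the gene bins and therefore never perturb the gene's interaction totals
  bgmax <- cfg$background_count_max
  rows <- data.frame(bin_i = gbins[1], bin_j = gbins[1],
                     count = cfg$planted_counts[["self"]])
  if (length(gbins) > 1L)
    rows <- rbind(rows,
                  data.frame(bin_i = gbins[2], bin_j = gbins[2],
                             count = round(0.9 * cfg$planted_counts[["self"]])),
                  data.frame(bin_i = gbins[1], bin_j = gbins[2],
                             count = rint(1, bgmax)))
  rows <- rbind(rows, data.frame(bin_i = pbin, bin_j = gbins[1],
                                 count = cfg$planted_counts[["planted"]]))
  between <- setdiff(seq(pbin, max(gbins), by = bs), c(pbin, gbins))
  for (b in between)
    rows <- rbind(rows, data.frame(bin_i = b, bin_j = gbins[1],
                                   count = rint(1, bgmax)))
  far <- setdiff(seq(0, (nb - 1) * bs, by = bs),
                 seq(pbin - bs, max(gbins) + bs, by = bs))
  if (length(far) >= 2L) {
    for (k in seq_len(min(10L, length(far) %/% 2L))) {
      ij <- sample(far, 2L)
      rows <- rbind(rows, data.frame(bin_i = ij[1], bin_j = ij[2],
                                     count = rint(0, bgmax)))
    }
  }
  rows <- rows[!duplicated(paste(pmin(rows$bin_i, rows$bin_j),
                                 pmax(rows$bin_i, rows$bin_j))), ]
  map_fine <- contact_map(chrom, bs, rows)

  # CTCF boundaries: upstream of the planted element (inside its fragment)
  # and downstream of the gene (inside its last fragment); one decoy site
  # inside the gene body exercises the ignore rule
  up_ctcf <- pstart - rint(5000, 12000)
  down_ctcf <- gend + rint(2000, 8000)
  trk <- function(s, e, name, score, class, cell = "") {
    gr <- from_printed(chrom, s, e)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = name, score = score,
                                                 cell_line = cell)
    feature_track(gr, class, cell)
  }
  ctcf <- trk(c(up_ctcf, down_ctcf, gstart + 10000),
              c(up_ctcf + 300, down_ctcf + 300, gstart + 10300),
              c("CTCF_up", "CTCF_down", "CTCF_in_gene"),
              c(rint(550, 900), rint(600, 950), 800), "CTCF")

  # planted evidence: three TFBS tiling the element exactly, a DNase peak
  # inside it, enhancer-type marks spanning it
  w <- pend - pstart + 1
  tf_s <- c(pstart, pstart + round(0.25 * w), pend - round(0.5 * w))
  tf_e <- c(pstart + round(0.5 * w), pstart + round(0.8 * w), pend)
  tf_names <- c("TF1", "TF2", "TF3")
  dn_s <- pstart + round(0.2 * w)
  dn_e <- pend - round(0.2 * w)
  mark_s <- pstart - 3000
  mark_e <- pend + 3000

  # decoys in distinct slots between the planted element and the gene
  slot_lo <- pend + 5000
  slot_hi <- gstart - 10000
  nd <- cfg$n_decoys
  decoy <- list(tf_s = numeric(0), tf_e = numeric(0), dn_s = numeric(0),
                dn_e = numeric(0), mk_s = numeric(0), mk_e = numeric(0))
  if (nd > 0L) {
    slot_w <- floor((slot_hi - slot_lo) / nd)
    if (slot_w < 6000)
      stop("chromosome too short to place the requested decoys",
           call. = FALSE)
    for (d in seq_len(nd)) {
      ds <- slot_lo + (d - 1) * slot_w + rint(0, max(0, slot_w - 4000))
      de <- ds + rint(600, 1200)
      type <- (d - 1) %% 3
      if (type == 0) {        # TFBS cluster without marks
        decoy$tf_s <- c(decoy$tf_s, ds, ds + 100)
        decoy$tf_e <- c(decoy$tf_e, de - 100, de)
      } else if (type == 1) { # DNase peak without marks
        decoy$dn_s <- c(decoy$dn_s, ds)
        decoy$dn_e <- c(decoy$dn_e, de)
      } else {                # marks without an anchor
        decoy$mk_s <- c(decoy$mk_s, ds)
        decoy$mk_e <- c(decoy$mk_e, de)
      }
    }
  }

  tracks <- list(
    ctcf = ctcf,
    tfbs = trk(c(tf_s, decoy$tf_s), c(tf_e, decoy$tf_e),
               c(tf_names, sprintf("decoy_TF%d", seq_along(decoy$tf_s))),
               c(sapply(seq_along(tf_s), function(i) rint(700, 1000)),
                 rep(500, length(decoy$tf_s))), "TFBS"),
    dnase = trk(c(dn_s, decoy$dn_s), c(dn_e, decoy$dn_e),
                c("DHS", sprintf("decoy_DHS%d", seq_along(decoy$dn_s))),
                c(rint(600, 1000), rep(400, length(decoy$dn_s))), "DNase"),
    h3k4me1 = trk(c(mark_s, decoy$mk_s), c(mark_e, decoy$mk_e),
                  c("H3K4me1",
                    sprintf("decoy_mark%d", seq_along(decoy$mk_s))),
                  rep(500, 1 + length(decoy$mk_s)), "H3K4me1"),
    h3k27ac = trk(mark_s, mark_e, "H3K27ac", 500, "H3K27ac"))

  promoter <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(gstart - 5000,
                                                      gstart - 1))
  anchor_a <- bin_of(pstart, 5000)
  anchor_b <- bin_of(gstart - 5000, 5000)
  loops_insitu <- loop_calls(chrom, anchor_a, anchor_a + 5000,
                             chrom, anchor_b, anchor_b + 5000,
                             name = "planted_loop", score = 50,
                             source = "in_situ_hic", resolution = 5000)
  loops_capture <- loop_calls(source = "capture_hic", resolution = 5000)

  vpos <- sort(sample(seq(pstart, pend), cfg$n_variants))
  bases <- c("A", "C", "G", "T")
  vref <- sample(bases, cfg$n_variants, replace = TRUE)
  valt <- vapply(vref, function(r) sample(setdiff(bases, r), 1),
                 character(1))
  variants <- variant_table(rep(chrom, cfg$n_variants), vpos, vref, valt,
                            zygosity = "het")
  conservation <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(vpos, vpos),
    score = round(runif(cfg$n_variants, 0.1, 1), 3))

  structure(list(
    chrom = chrom, genome = "simulated", gene = gene, gene_name = "simgene",
    promoter = promoter, map_coarse = NULL, map_fine = map_fine,
    tracks = tracks, loops_insitu = loops_insitu,
    loops_capture = loops_capture, variants = variants,
    known_variants = variant_table(), conservation = conservation,
    cohort = NULL, methylation = NULL,
    planted = planted, config = cfg), class = "locus_bundle")
}

#' @export
print.locus_bundle <- function(x, ...) {
  cat(sprintf("<locus_bundle> %s (%s): gene %s; %d track(s), %d variant(s)\n",
              x$gene_name, x$chrom, format_printed(x$gene),
              length(x$tracks), nrow(x$variants)))
  if (!is.null(x$planted))
    cat("  planted element:", format_printed(x$planted), "\n")
  invisible(x)
}
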