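worked_example <- function() {
  b <- paper_locus()
  sr <- refine_search_region(b$gene,
                             bin_interval(seq(2.5e6, 2.9e6, 1e5), 1e5,
                                          b$chrom),
                             b$tracks$ctcf)
  list(bundle = b, region = sr)
}

test_that("evidence integration recovers both regulatory regions of the worked example", {
  w <- worked_example()
  cand <- find_candidates(w$region, w$bundle$tracks)
  expect_length(cand, 2)
  expect_equal(start(cand), c(2561489, 2631527))
  expect_equal(end(cand), c(2562509, 2632188))
  expect_equal(mcols(cand)$region_class,
               c("promoter_like", "enhancer_like"))

  # the proximal candidate is corroborated by enhancer-type evidence only
  ev <- candidate_evidence(cand, 2)
  expect_true(all(c("H3K4me1", "H3K27ac", "ENHANCER", "TFBS", "DNase")
                  %in% ev$track_class))
  expect_false("H3K4me3" %in% ev$track_class)
  expect_true("DHS" %in% ev$name)
  # the distal candidate carries promoter-type evidence
  ev1 <- candidate_evidence(cand, 1)
  expect_true("H3K4me3" %in% ev1$track_class)
  expect_true(any(ev1$track_class == "CHROMHMM"))

  # restricting to the primary cell line keeps the substituted mark tracks
  cand2 <- find_candidates(w$region, w$bundle$tracks,
                           primary_cell_line = "GM06990")
  expect_equal(start(cand2), start(cand))
  expect_equal(mcols(cand2)$region_class, mcols(cand)$region_class)
})

test_that("candidate distances to the gene match the printed upstream offsets", {
  w <- worked_example()
  cand <- find_candidates(w$region, w$bundle$tracks)
  d <- distance_to_gene(cand, w$bundle$gene)
  expect_equal(d, c(-83375, -13696))
  expect_equal(round(d / 1000, 1), c(-83.4, -13.7))
  expect_equal(distance_to_gene(w$bundle$gene, w$bundle$gene), 0)
  expect_error(distance_to_gene(from_printed("chr1", 1, 10),
                                w$bundle$gene), "same chromosome")
})

test_that("classification follows the mark hierarchy with promoter precedence", {
  ev <- function(...) data.frame(track_class = c(...),
                                 name = c(...), start = 1, end = 2,
                                 score = 0, cell_line = "")
  expect_equal(classify_candidate(ev("TFBS", "DNase")), "unclassified")
  expect_equal(classify_candidate(ev("TFBS", "H3K27ac")), "enhancer_like")
  expect_equal(classify_candidate(ev("ENHANCER")), "enhancer_like")
  expect_equal(classify_candidate(ev("H3K27ac", "H3K4me3")),
               "promoter_like")
  chromhmm <- data.frame(track_class = "CHROMHMM", name = "Active_Promoter",
                         start = 1, end = 2, score = 0, cell_line = "")
  expect_equal(classify_candidate(chromhmm), "promoter_like")
  repressed <- data.frame(track_class = "CHROMHMM", name = "Heterochrom",
                          start = 1, end = 2, score = 0, cell_line = "")
  expect_equal(classify_candidate(repressed), "unclassified")
})

test_that("degenerate inputs are rejected or yield empty candidate sets", {
  w <- worked_example()
  expect_error(find_candidates(w$region, list()), "no evidence tracks")
  marks_only <- list(h3k4me1 = w$bundle$tracks$h3k4me1_gm12878)
  expect_error(find_candidates(w$region, marks_only), "anchor")
  wrong_chrom <- list(tfbs = mk_track("chr7", 2631527, 2632188, "TFBS"))
  expect_error(find_candidates(w$region, wrong_chrom),
               "different chromosome")
  # anchors present but nothing inside the region
  outside <- list(tfbs = mk_track("chr18", 100, 400, "TFBS"),
                  marks = w$bundle$tracks$h3k4me1_gm12878)
  expect_length(find_candidates(w$region, outside), 0)
  # anchors without any corroborating mark are not candidates
  bare <- list(tfbs = w$bundle$tracks$tfbs)
  expect_length(find_candidates(w$region, bare), 0)
})

test_that("candidates are deterministic under track permutation and non-nested", {
  w <- worked_example()
  set.seed(8)
  for (r in 1:5) {
    perm <- sample(length(w$bundle$tracks))
    cand <- find_candidates(w$region, w$bundle$tracks[perm])
    expect_equal(start(cand), c(2561489, 2631527))
    expect_equal(end(cand), c(2562509, 2632188))
  }
  cand <- find_candidates(w$region, w$bundle$tracks)
  if (length(cand) > 1) {
    for (i in seq_len(length(cand) - 1))
      expect_lt(end(cand[i]), start(cand[i + 1]))  # disjoint, sorted
  }
})

test_that("planted elements are recovered and decoys rejected on random loci", {
  for (seed in 101:120) {
    b <- random_locus(sim_config(seed = seed))
    sr <- refine_search_region(
      b$gene,
      bin_interval(interacting_block(b$map_fine,
                                     gene_bins(b$gene,
                                               b$map_fine$bin_size)),
                   b$map_fine$bin_size, b$chrom),
      b$tracks$ctcf)
    cand <- find_candidates(sr, b$tracks)
    expect_length(cand, 1)
    expect_equal(start(cand), start(b$planted))
    expect_equal(end(cand), end(b$planted))
    # every emitted candidate overlaps an anchor and carries mark evidence
    ev <- candidate_evidence(cand, 1)
    expect_true(any(ev$track_class %in% c("TFBS", "DNase")))
    expect_true(any(ev$track_class %in%
                      c("H3K4me1", "H3K27ac", "H3K4me3", "ENHANCER",
                        "CHROMHMM")))
  }
})
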