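paper_ctcf <- function() paper_locus()$tracks$ctcf
smchd1 <- function() from_printed("chr18", 2645885, 2795015)
paper_bins <- function() bin_interval(seq(2.5e6, 2.9e6, 1e5), 1e5, "chr18")

test_that("CTCF sites classify as weak/strong around the configurable cut", {
  sites <- classify_ctcf(paper_ctcf())
  expect_equal(mcols(sites)$strength, c("weak", "weak", "strong"))
  one <- mk_track("chr1", 100, 400, "CTCF", score = 500)
  expect_equal(mcols(classify_ctcf(one))$strength, "strong")  # boundary
  expect_equal(mcols(classify_ctcf(one, threshold = 600))$strength, "weak")
})

test_that("nearby sites merge into one boundary cluster spanning their range", {
  cl <- ctcf_clusters(paper_ctcf(), gap = 5000)
  expect_length(cl, 2)
  expect_equal(start(cl), c(2531952, 2922164))
  expect_equal(end(cl), c(2537783, 2922551))
  expect_equal(mcols(cl)$strength, c("weak", "strong"))
  expect_equal(mcols(cl)$n_sites, c(2L, 1L))
  expect_equal(mcols(cl)$score, c(444, 719))
})

test_that("refinement reproduces the CTCF-bounded search region from printed sites", {
  sr <- refine_search_region(smchd1(), paper_bins(), paper_ctcf())
  expect_s3_class(sr, "search_region")
  expect_equal(start(sr$interval), 2531952)
  expect_equal(end(sr$interval), 2922551)
  expect_equal(sr$upstream$type, "ctcf")
  expect_equal(sr$upstream$strength, "weak")
  expect_equal(sr$downstream$type, "ctcf")
  expect_equal(sr$downstream$strength, "strong")
})

test_that("sides without admissible sites fall back to fragment edges, flagged", {
  gene <- smchd1()
  bins <- paper_bins()
  downstream_only <- mk_track("chr18", 2922164, 2922551, "CTCF",
                              score = 719)
  sr <- refine_search_region(gene, bins, downstream_only)
  expect_equal(sr$upstream$type, "fragment_edge")
  expect_equal(start(sr$interval), 2500001)  # edge of the first fragment
  expect_equal(end(sr$interval), 2922551)

  in_gene <- mk_track("chr18", 2700000, 2700400, "CTCF", score = 900)
  sr2 <- refine_search_region(gene, bins, in_gene)  # gene-body sites ignored
  expect_equal(sr2$upstream$type, "fragment_edge")
  expect_equal(sr2$downstream$type, "fragment_edge")
  expect_equal(start(sr2$interval), 2500001)
  expect_equal(end(sr2$interval), 3000000)

  # a site outside the interacting fragments is inadmissible
  far <- mk_track("chr18", c(2100000, 2922164), c(2100300, 2922551),
                  "CTCF", score = c(800, 719))
  sr3 <- refine_search_region(gene, bins, far)
  expect_equal(sr3$upstream$type, "fragment_edge")
  expect_error(refine_search_region(gene, GRanges(), paper_ctcf()),
               "no interacting")
})

test_that("strict policy takes the nearest strong site; outermost stays permissive", {
  sr <- refine_search_region(smchd1(), paper_bins(), paper_ctcf(),
                             policy = "strict")
  # no strong upstream site exists: strict falls back to the fragment edge
  expect_equal(sr$upstream$type, "fragment_edge")
  expect_equal(start(sr$interval), 2500001)
  expect_equal(end(sr$interval), 2922551)

  two_strong <- mk_track("chr18", c(2510000, 2560000, 2922164),
                         c(2510300, 2560300, 2922551), "CTCF",
                         score = c(700, 800, 719))
  strict <- refine_search_region(smchd1(), paper_bins(), two_strong,
                                 policy = "strict")
  outer <- refine_search_region(smchd1(), paper_bins(), two_strong)
  expect_equal(start(strict$interval), 2560000)  # nearest strong
  expect_equal(start(outer$interval), 2510000)   # farthest admissible
})

test_that("refinement is order-invariant, monotone in added sites, and bin-bounded", {
  gene <- from_printed("chrZ", 5200000, 5350000)
  bins <- bin_interval(seq(5.0e6, 5.4e6, 1e5), 1e5, "chrZ")
  set.seed(99)
  for (r in 1:25) {
    n <- sample.int(8, 1)
    s <- sample(seq(5000001, 5598000), n)
    ctcf <- mk_track("chrZ", s, s + 300, "CTCF",
                     score = sample.int(1000, n, replace = TRUE),
                     name = paste0("c", seq_len(n)))
    sr <- refine_search_region(gene, bins, ctcf)
    perm <- sample(n)
    sr_shuffled <- refine_search_region(gene, bins, ctcf[perm])
    expect_equal(start(sr$interval), start(sr_shuffled$interval))
    expect_equal(end(sr$interval), end(sr_shuffled$interval))
    # never extends past the interacting fragments
    expect_gte(start(sr$interval), 5000001)
    expect_lte(end(sr$interval), 5500000)

    # adding a farther admissible upstream site can only widen the region
    # (relative to an existing CTCF boundary; a fragment-edge fallback is
    # replaced by the new site)
    farther <- mk_track("chrZ", 5000501, 5000800, "CTCF", score = 300)
    wider <- refine_search_region(gene, bins,
                                  suppressWarnings(c(ctcf, farther)))
    if (sr$upstream$type == "ctcf") {
      expect_lte(start(wider$interval), start(sr$interval))
    } else {
      expect_equal(start(wider$interval), 5000501)
    }
    expect_equal(end(wider$interval), end(sr$interval))
  }
})
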