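annotated_example <- function() {
  b <- paper_locus()
  sr <- refine_search_region(b$gene,
                             bin_interval(seq(2.5e6, 2.9e6, 1e5), 1e5,
                                          b$chrom),
                             b$tracks$ctcf)
  cand <- find_candidates(sr, b$tracks)
  list(bundle = b,
       ann = annotate_variants(b$variants, cand, b$tracks,
                               known = b$known_variants,
                               conservation = b$conservation))
}

test_that("the three variants annotate against the printed DHS/TFBS geometry", {
  x <- annotated_example()
  a <- x$ann
  expect_equal(a$pos, c(2631610, 2631858, 2631886))
  expect_true(all(a$n_candidates == 1))
  expect_true(all(a$candidate == "chr18:2,631,527-2,632,188"))

  feats <- function(i) a$overlaps[[i]]$name
  # 2,631,610: inside STAT1 but not IRF1 (starts 2,631,639) nor the DHS
  # cluster (starts 2,631,700)
  expect_true("STAT1" %in% feats(1))
  expect_false("IRF1" %in% feats(1))
  expect_false("DHS" %in% feats(1))
  # 2,631,886: inside the DHS cluster and IRF1/STAT1/STAT2/RUNX3
  expect_true(all(c("DHS", "IRF1", "STAT1", "STAT2", "RUNX3")
                  %in% feats(3)))
  # 2,631,858: inside the DHS cluster
  expect_true("DHS" %in% feats(2))

  # novelty against the supplied known list: only the polymorphism is known
  expect_equal(a$novel, c(TRUE, FALSE, TRUE))
  expect_equal(a$conservation_score, c(0.557, 0.691, 0.431))
  expect_true(all(a$conserved))

  far <- annotate_variants(variant_table("chr18", 1e6, "A", "G"),
                           GRanges(), x$bundle$tracks)
  expect_equal(far$n_candidates, 0)
  expect_equal(nrow(far$overlaps[[1]]), 0)
})

test_that("variant overlap lists equal a brute-force scan on random tracks", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 150
    fs <- sample.int(50000, n, replace = TRUE)
    fe <- fs + sample.int(300, n, replace = TRUE) - 1L
    tr <- mk_track("chrV", fs, fe, "TFBS", name = paste0("f", seq_len(n)),
                   score = sample.int(1000, n, replace = TRUE))
    pos <- sample.int(50000, 200, replace = TRUE)
    vars <- variant_table(rep("chrV", 200), pos, rep("A", 200),
                          rep("G", 200))
    ann <- annotate_variants(vars, GRanges(), list(tfbs = tr))
    for (i in sample.int(200, 25)) {
      idx <- brute_intersect_idx("chrV", pos[i], pos[i],
                                 rep("chrV", n), fs, fe)
      want <- if (length(idx)) paste0("f", idx) else character(0)
      expect_identical(ann$overlaps[[i]]$name, want)
    }
  }
})

test_that("conservation labelling follows the positive-score convention", {
  expect_true(conservation_label(0.557))
  expect_true(conservation_label(0.431))
  expect_false(conservation_label(-1.2))
  expect_false(conservation_label(0))       # neutral is not conserved
  expect_true(conservation_label(0.1, threshold = 0.05))
  expect_true(is.na(conservation_label(NA)))
  cons <- GRanges("chrV", IRanges(c(10, 30), c(10, 30)),
                  score = c(0.7, -0.2))
  v <- variant_table(rep("chrV", 3), c(10, 20, 30), rep("A", 3),
                     rep("G", 3))
  expect_equal(conservation_at(cons, v), c(0.7, NA, -0.2))
})

test_that("cohort tallies give exact counts and frequencies summing to one", {
  calls <- c(rep("C", 182), rep("T", 47))
  cs <- cohort_summary(calls, position = 2631858)
  expect_equal(cs$n, 229)
  expect_equal(cs$allele_counts[["C"]], 182L)
  expect_equal(cs$allele_counts[["T"]], 47L)
  expect_equal(cs$frequencies[["C"]], 182 / 229)
  expect_equal(sum(cs$frequencies), 1, tolerance = 1e-12)

  expect_equal(cohort_summary(c("A", "A", "G"))$allele_counts,
               c(A = 2L, G = 1L))
  expect_equal(unname(cohort_summary(rep("T", 5))$frequencies), 1)
  expect_error(cohort_summary(character(0)), "non-empty")
})

test_that("methylation averaging is exact, site-count-checked and order-free", {
  expect_equal(mean_methylation(rep(0.24, 10)), 24)
  expect_equal(mean_methylation(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)), 50)
  set.seed(4)
  r <- runif(10)
  expect_equal(mean_methylation(r), mean_methylation(sample(r)))
  expect_error(mean_methylation(rep(0.2, 9)), "expected 10")
  expect_error(mean_methylation(c(rep(0.2, 9), 1.4)), "\\[0, 1\\]")
  expect_equal(mean_methylation(c(0.5, 0.5), n_sites = 2), 50)
})
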