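paper_maps <- function() paper_locus()[c("map_coarse", "map_fine")]

test_that("binning maps printed positions to browser-style fragment starts", {
  expect_equal(bin_of(2645885, 1e6), 2e6)
  expect_equal(bin_of(2795015, 1e5), 2.7e6)
  expect_equal(bin_of(1, 1e6), 0)
  expect_equal(bin_of(1e6, 1e6), 0)       # last base of the first fragment
  expect_equal(bin_of(1e6 + 1, 1e6), 1e6)
  expect_error(bin_of(0, 1e6), ">= 1")
  set.seed(3)
  p <- sample.int(1e7, 500)
  for (bs in c(1e5, 1e6, 7)) {
    b <- bin_of(p, bs)
    expect_true(all(b <= p - 1 & p - 1 < b + bs))
    expect_true(all(b %% bs == 0))
  }
})

test_that("a gene is assigned every fragment it intersects", {
  gene <- from_printed("chr18", 2645885, 2795015)
  expect_equal(gene_bins(gene, 1e6), 2e6)
  expect_equal(gene_bins(gene, 1e5), c(2.6e6, 2.7e6))
  expect_equal(gene_bins(from_printed("chr1", 150, 900), 1e3), 0)
  iv <- bin_interval(2.6e6, 1e5, "chr18")
  expect_equal(start(iv), 2600001)
  expect_equal(end(iv), 2700000)
})

test_that("ranking recovers the dominant self- and adjacent-fragment interactions", {
  maps <- paper_maps()
  rk <- rank_interacting(maps$map_coarse, 2e6)
  expect_equal(rk$ranked$bin_start[1:2], c(2e6, 3e6))
  expect_equal(rk$ranked$total_count[1:2], c(3371, 663))
  expect_true(all(rk$ranked$total_count[-(1:2)] <= 30))

  rk2 <- rank_interacting(maps$map_coarse, 2e6, include_self = FALSE)
  expect_false(2e6 %in% rk2$ranked$bin_start)
  expect_equal(rk2$self$total_count, 3371)

  # 100-kb view: the two gene fragments dominate via their self-counts
  sm <- interaction_summary(maps$map_fine, c(2.6e6, 2.7e6))
  expect_equal(sm$total_count[sm$bin_start == 2.6e6], 256 + 28)
  expect_equal(sm$total_count[sm$bin_start == 2.7e6], 237 + 28)
  expect_equal(sm$total_count[sm$bin_start == 2.5e6], 23)
  bg <- sm[!sm$bin_start %in% c(2.6e6, 2.7e6), ]
  expect_true(all(bg$total_count <= 30))
})

test_that("ranking handles empty maps, ties and bad gene bins", {
  empty <- contact_map("chr1", 1e5,
                       data.frame(bin_i = numeric(0), bin_j = numeric(0),
                                  count = numeric(0)))
  expect_equal(nrow(rank_interacting(empty, 0)$ranked), 0)
  tie <- contact_map("chr1", 1e5, data.frame(
    bin_i = c(0, 0), bin_j = c(3e5, 1e5), count = c(7, 7)))
  rk <- rank_interacting(tie, 0, include_self = FALSE)
  expect_equal(rk$ranked$bin_start, c(1e5, 3e5))  # tie: ascending bin start
  expect_error(rank_interacting(tie, 12345), "not bins")
  expect_error(rank_interacting(tie, numeric(0)), "non-empty")
})

test_that("ranking totals equal a dense-matrix oracle on random maps", {
  for (seed in 1:15) {
    set.seed(seed)
    bs <- 1e5
    n <- sample.int(60, 1)
    df <- data.frame(bin_i = sample(0:49, n, replace = TRUE) * bs,
                     bin_j = sample(0:49, n, replace = TRUE) * bs,
                     count = sample.int(100, n, replace = TRUE))
    df <- df[!duplicated(paste(pmin(df$bin_i, df$bin_j),
                               pmax(df$bin_i, df$bin_j))), ]
    map <- contact_map("chrX", bs, df)
    gbins <- sort(sample(0:49, sample.int(3, 1))) * bs
    obs <- unique(c(map$counts$bin_i, map$counts$bin_j))
    oracle <- dense_totals(map, gbins)
    oracle <- oracle[oracle$bin_start %in% obs, ]
    rk <- rank_interacting(map, gbins, min_count = 0)
    # the ranking is a permutation of all observed bins
    expect_setequal(rk$ranked$bin_start, oracle$bin_start)
    got <- rk$ranked$total_count[match(oracle$bin_start,
                                       rk$ranked$bin_start)]
    expect_equal(got, oracle$total_count)
    # monotone non-increasing, ties broken by ascending bin start
    expect_true(all(diff(rk$ranked$total_count) <= 0))
    same <- diff(rk$ranked$total_count) == 0
    expect_true(all(diff(rk$ranked$bin_start)[same] > 0))
  }
})

test_that("the interacting block is the contiguous non-background neighbourhood", {
  maps <- paper_maps()
  expect_equal(interacting_block(maps$map_fine, c(2.6e6, 2.7e6)),
               seq(2.5e6, 2.9e6, by = 1e5))
  # the stray background pair at 1.2 Mb is not connected to the gene block
  expect_false(1.2e6 %in% interacting_block(maps$map_fine,
                                            c(2.6e6, 2.7e6)))
  expect_equal(interacting_block(maps$map_coarse, 2e6),
               seq(0, 5e6, by = 1e6))
})
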