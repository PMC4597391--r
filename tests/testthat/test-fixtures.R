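test_that("the worked-example locus is deterministic and encodes its published values", {
  b1 <- paper_locus()
  b2 <- paper_locus()
  expect_identical(b1$map_fine$counts, b2$map_fine$counts)
  expect_identical(format_printed(b1$gene), format_printed(b2$gene))
  expect_identical(start(b1$tracks$tfbs), start(b2$tracks$tfbs))

  expect_equal(contact_count(b1$map_coarse, 2e6, 2e6), 3371)
  expect_equal(contact_count(b1$map_coarse, 2e6, 3e6), 663)
  expect_equal(contact_count(b1$map_fine, 2.6e6, 2.6e6), 256)
  expect_equal(contact_count(b1$map_fine, 2.7e6, 2.7e6), 237)

  ctcf <- b1$tracks$ctcf
  strong <- ctcf[mcols(ctcf)$score == 719]
  expect_equal(start(strong), 2922164)
  expect_equal(end(strong), 2922551)
  expect_true(all(mcols(ctcf)$score[mcols(ctcf)$score != 719] < 445))

  expect_equal(b1$variants$pos, c(2631610, 2631858, 2631886))
  expect_equal(b1$variants$ref, c("T", "T", "G"))
  expect_equal(b1$variants$alt, c("C", "C", "A"))
  dhs <- b1$tracks$dnase
  expect_equal(mcols(dhs)$score[start(dhs) == 2631700], 976)
})

test_that("random loci are seed-deterministic and honour their configuration", {
  a <- random_locus(sim_config(seed = 7))
  b <- random_locus(sim_config(seed = 7))
  expect_identical(format_printed(a$planted), format_printed(b$planted))
  expect_identical(a$map_fine$counts, b$map_fine$counts)
  expect_identical(a$variants$pos, b$variants$pos)
  expect_identical(start(a$tracks$tfbs), start(b$tracks$tfbs))
  c_ <- random_locus(sim_config(seed = 8))
  expect_false(identical(format_printed(a$planted),
                         format_printed(c_$planted)))

  # background ceiling versus planted counts
  gb <- gene_bins(a$gene, a$map_fine$bin_size)
  tot <- interaction_summary(a$map_fine, gb)
  top <- tot[order(-tot$total_count), ]
  expect_gte(top$total_count[1], 663)
  pbin <- bin_of(start(a$planted), a$map_fine$bin_size)
  expect_equal(tot$total_count[tot$bin_start == pbin], 663)
  expect_error(sim_config(background_count_max = 700), "ceiling")
  expect_error(sim_config(planted_region = c(1, 9e9)),
               "outside chromosome")

  # zero decoys leaves exactly the planted anchors in the tracks
  z <- random_locus(sim_config(seed = 3, n_decoys = 0))
  expect_false(any(grepl("decoy", mcols(z$tracks$tfbs)$name)))
  expect_length(z$tracks$dnase, 1)
})

test_that("bundles round-trip through their on-disk layout", {
  b <- random_locus(sim_config(seed = 12))
  dir <- withr::local_tempdir()
  write_locus_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "meta.json")))
  rb <- read_locus_bundle(dir)
  expect_equal(format_printed(rb$gene), format_printed(b$gene))
  expect_equal(format_printed(rb$promoter), format_printed(b$promoter))
  expect_equal(rb$map_fine$counts, b$map_fine$counts)
  expect_equal(rb$variants$pos, b$variants$pos)
  expect_equal(rb$variants$zygosity, b$variants$zygosity)
  expect_equal(rb$loops_insitu$start_a, b$loops_insitu$start_a)
  expect_equal(nrow(rb$loops_capture), 0)
  expect_equal(format_printed(rb$planted), format_printed(b$planted))
  for (nm in names(b$tracks)) {
    expect_equal(start(rb$tracks[[nm]]), start(b$tracks[[nm]]),
                 info = nm)
    expect_equal(track_class(rb$tracks[[nm]]), track_class(b$tracks[[nm]]))
    expect_equal(track_cell_line(rb$tracks[[nm]]),
                 track_cell_line(b$tracks[[nm]]))
  }
  expect_equal(mcols(rb$conservation)$score, mcols(b$conservation)$score)

  pb <- paper_locus()
  dir2 <- withr::local_tempdir()
  write_locus_bundle(pb, dir2)
  rpb <- read_locus_bundle(dir2)
  expect_equal(rpb$cohort$position, 2631858)
  expect_equal(length(rpb$cohort$calls), 229)
  expect_equal(rpb$methylation, rep(0.24, 10))
  expect_equal(rpb$map_coarse$counts, pb$map_coarse$counts)
})
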