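# Brute-force oracles and small builders shared across tests. The oracles
# deliberately avoid the GenomicRanges machinery the implementation relies
# on, so implementation and expectation stay independent.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# closed-interval overlap straight from the definition
brute_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 <= e2 & s2 <= e1
}

# indices of features overlapping the query, O(n) scan, input order
brute_intersect_idx <- function(qc, qs, qe, fc, fs, fe) {
  which(fc == qc & fs <= qe & fe >= qs)
}

# per-bin interaction totals via an explicit dense symmetric matrix
dense_totals <- function(map, gbins) {
  bins <- sort(unique(c(map$counts$bin_i, map$counts$bin_j, gbins)))
  M <- matrix(0, length(bins), length(bins),
              dimnames = list(bins, bins))
  for (r in seq_len(nrow(map$counts))) {
    i <- as.character(map$counts$bin_i[r])
    j <- as.character(map$counts$bin_j[r])
    M[i, j] <- map$counts$count[r]
    M[j, i] <- map$counts$count[r]
  }
  out <- vapply(as.character(bins), function(b)
    sum(vapply(as.character(gbins), function(g) M[g, b], numeric(1))),
    numeric(1))
  data.frame(bin_start = bins, total_count = unname(out))
}

# quick scored-track builder from 1-based printed coordinates
mk_track <- function(chrom, start, end, class, name = NULL, score = 500,
                     cell = "") {
  gr <- from_printed(chrom, start, end)
  mcols(gr)$name <- name %||% rep(class, length(gr))
  mcols(gr)$score <- rep_len(score, length(gr))
  feature_track(gr, class, cell)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run the installed command-line interface in a child R process
run_cli <- function(...) {
  cli <- system.file("cli", "remreg.R", package = "remreg")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(cli, ...), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}
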