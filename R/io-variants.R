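# Variant tables and VCF I/O.

ZYGOSITIES <- c("het", "hom", "mosaic", "unknown")

#' Variant tables
#'
#' Variants are single-position substitutions kept in VCF coordinates
#' (1-based `pos`) with a zygosity in `het`, `hom`, `mosaic`, `unknown`.
#' Mosaicism is carried as metadata only (the detection of a mosaic carrier
#' is qualitative); no allele-fraction modelling is done.
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt reference and alternate alleles, `ref != alt`.
#' @param zygosity one of `r paste(ZYGOSITIES, collapse = ", ")` (recycled).
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(chrom = character(0), pos = numeric(0),
                          ref = character(0), alt = character(0),
                          zygosity = "unknown") {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   zygosity = rep_len(as.character(zygosity), n),
                   stringsAsFactors = FALSE)
  if (n) {
    if (any(!nzchar(df$chrom))) stop("empty chromosome name", call. = FALSE)
    if (any(!is.finite(df$pos)) || any(df$pos < 1))
      stop("variant positions must be >= 1", call. = FALSE)
    if (any(df$ref == df$alt))
      stop("`ref` and `alt` alleles must differ", call. = FALSE)
    if (any(!df$zygosity %in% ZYGOSITIES))
      stop("zygosity must be one of: ", paste(ZYGOSITIES, collapse = ", "),
           call. = FALSE)
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

# 1-bp GRanges at the variant positions
.variant_granges <- function(variants) {
  if (nrow(variants) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(variants$pos, variants$pos))
}

#' Read / write variants as VCF
#'
#' Sites-level VCF 4.x parsing via the vcfR package. Zygosity is derived from
#' the first sample's GT field when a genotype column is present (0/1 or
#' phased equivalents are `het`, 1/1 is `hom`, otherwise `unknown`); a
#' variant is labelled `mosaic` only via an explicit `MOSAIC` INFO flag.
#' An empty VCF body yields an empty table.
#'
#' @param path file to read or write.
#' @return `read_vcf_variants()`: a [variant_table()].
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  body <- which(!startsWith(txt, "#") & nzchar(trimws(txt)))
  if (length(body) == 0L) return(variant_table())
  nf <- lengths(strsplit(txt[body], "\t", fixed = TRUE))
  bad <- which(nf < 8L)
  if (length(bad))
    stop(sprintf("malformed VCF record at line %d of '%s': %d column(s), expected >= 8",
                 body[bad[1]], path, nf[bad[1]]), call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  zyg <- rep("unknown", nrow(fix))
  gt <- tryCatch(vcfR::extract.gt(v), error = function(e) NULL)
  if (!is.null(gt) && ncol(gt) >= 1L) {
    g <- gsub("\\|", "/", gt[, 1])
    zyg[g %in% c("0/1", "1/0")] <- "het"
    zyg[g %in% "1/1"] <- "hom"
  }
  info <- v@fix[, "INFO"]
  mosaic <- !is.na(info) & grepl("(^|;)MOSAIC(;|=|$)", info)
  zyg[mosaic] <- "mosaic"
  variant_table(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                ref = fix[, "REF"], alt = fix[, "ALT"], zygosity = zyg)
}

#' @rdname read_vcf_variants
#' @param variants a `variant_table`.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MOSAIC,Number=0,Type=Flag,Description=\"Variant observed as a somatic mosaic in the carrier\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE1", sep = "\t"))
  gt <- c(het = "0/1", hom = "1/1", mosaic = "0/1",
          unknown = "./.")[variants$zygosity]
  info <- ifelse(variants$zygosity == "mosaic", "MOSAIC", ".")
  rows <- if (nrow(variants)) {
    paste(variants$chrom, .int_chr(variants$pos), ".", variants$ref,
          variants$alt, ".", "PASS", info, "GT", gt, sep = "\t")
  } else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}
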