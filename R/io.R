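#' Read and write genotype matrices as TSV or minimal VCF
#'
#' The TSV layout is individuals x loci with an \code{id} first column and
#' dosages 0/1/2 (empty or NA for missing). The VCF writer emits a minimal
#' VCFv4.2 with CHROM, POS, ID, REF=A, ALT=C and a GT-only FORMAT
#' (0/0, 0/1, 1/1, ./.); the reader parses exactly that subset (any
#' diploid GT field, '.' alleles treated as missing).
#'
#' @param g a [genotype_matrix()].
#' @param path file path.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_genotypes_tsv <- function(g, path) {
  df <- data.frame(id = rownames(g$dosage), g$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df[[1]]
  genotype_matrix(dos)
}

#' @rdname genotype_io
#' @export
write_vcf_min <- function(g, path) {
  meta <- g$locus_meta
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- t(g$dosage)  # loci x individuals
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[as.character(dos[ok])]
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g$dosage)), collapse = "\t"))
  body <- paste(meta$chrom, meta$pos, meta$id, "A", "C", ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  stopifnot(hdr[1] == "#CHROM")
  ids <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  # one column per locus: dosage over individuals
  dos <- vapply(rows, function(r) {
    stopifnot(startsWith(r[9], "GT"))
    gts <- sub(":.*", "", r[-(1:9)])
    vapply(strsplit(gts, "[/|]"), function(a) {
      if (any(a == ".")) NA_real_ else sum(as.numeric(a))
    }, 0)
  }, numeric(length(ids)))
  if (length(ids) == 1) dos <- matrix(dos, nrow = 1)
  meta <- data.frame(id = vapply(rows, `[`, "", 3),
                     chrom = vapply(rows, `[`, "", 1),
                     pos = as.integer(vapply(rows, `[`, "", 2)),
                     stringsAsFactors = FALSE)
  dimnames(dos) <- list(ids, meta$id)
  genotype_matrix(dos, meta)
}
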