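#' Write genotypes as a VCF file
#'
#' Minimal VCF 4.2 export of the dosage matrix (GT field only, unphased,
#' 1-based positions), one sample column per animal.
#'
#' @param genotypes A `geno_matrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pleioscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            genotypes$animals$animal_id), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  sm <- genotypes$snp_map
  for (j in seq_len(nrow(sm))) {
    gt <- gt_code[genotypes$dosages[, j] + 1L]
    writeLines(paste(c(sm$chrom[j], format(sm$pos_bp[j], scientific = FALSE),
                       sm$snp[j], sm$allele_ref[j], sm$allele_alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotype dosages as a TSV matrix
#'
#' Companion to [write_vcf()]: a SNP x animal dosage table plus a separate
#' map file (`<path>.map.tsv`) with chromosome and position.
#'
#' @param genotypes A `geno_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- t(genotypes$dosages)
  colnames(d) <- genotypes$animals$animal_id
  out <- cbind(data.frame(snp = genotypes$snp_map$snp), as.data.frame(d))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(genotypes$snp_map), paste0(path, ".map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write trait panels and summary tables as TSV
#'
#' Plain-TSV persistence for the tabular artifacts; round-trips
#' losslessly through [read_tsv_table()].
#'
#' @param x A data frame / tibble.
#' @param path File path.
#' @return `write_tsv_table()` returns `path` invisibly;
#'   `read_tsv_table()` a tibble.
#' @export
write_tsv_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE))
}

#' Persist a summary-stats object as one TSV per phenotype set
#'
#' @param stats A `summary_stats` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  write_tsv_table(tidy(stats), path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  long <- read_tsv_table(path)
  set <- long$set[1]
  traits <- unique(long$trait)
  snp_map <- dplyr::distinct(long[, c("snp", "chrom", "pos_bp")])
  wide <- function(col) {
    m <- matrix(long[[col]], nrow = nrow(snp_map), ncol = length(traits),
                dimnames = list(snp_map$snp, traits))
    m
  }
  structure(
    list(set = set, traits = traits, snp_map = snp_map,
         beta = wide("beta"), se = wide("se"), tval = wide("t"),
         pval = wide("p"), conditioned_on = NULL),
    class = "summary_stats"
  )
}
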