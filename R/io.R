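## Readers/writers for the standard text formats at the package surface.
## FASTA goes through Biostrings; the BLAST-tabular, GFF3, TSV and minimal
## VCF surfaces are line-based formats written/parsed directly.

#' Read a BLAST-tabular (outfmt 6 dialect) hit table
#'
#' Expects the classic 12 columns; only the columns the analyses use are
#' retained, self-hits are dropped.
#'
#' @param file Path to a tab-separated hit file without header.
#' @return data.frame with `query`, `subject`, `pct_identity`,
#'   `aln_length`, `bit_score`, `e_value`.
#' @export
read_hit_table <- function(file) {
  x <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)
  abort_if(ncol(x) < 12L, "expected 12 BLAST tabular columns, got %d",
           ncol(x))
  out <- data.frame(query = x[[1]], subject = x[[2]], pct_identity = x[[3]],
                    aln_length = x[[4]], e_value = x[[11]],
                    bit_score = x[[12]], stringsAsFactors = FALSE)
  out[out$query != out$subject, ]
}

#' @rdname read_hit_table
#' @param hits Hit table data.frame.
#' @param file Output path.
#' @export
write_hit_table <- function(hits, file) {
  x <- data.frame(hits$query, hits$subject, hits$pct_identity,
                  hits$aln_length, 0L, 0L, 1L, hits$aln_length, 1L,
                  hits$aln_length, hits$e_value, hits$bit_score)
  utils::write.table(x, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write element annotations as GFF3
#'
#' Features are typed `repeat_region`; `family`, `element_type`,
#' `element_id` and `ltr_ids` travel in the attribute column. Coordinates
#' are converted from the internal 0-based half-open convention to GFF3's
#' 1-based inclusive one.
#'
#' @param annotations Annotation table (see [simulate_te_genomes()]).
#' @param file Output path.
#' @export
write_ty_gff <- function(annotations, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attr_str <- sprintf("ID=%s;family=%s;element_type=%s;ltr_ids=%s",
                      annotations$element_id, annotations$family,
                      annotations$element_type, annotations$ltr_ids)
  writeLines(sprintf("%s\ttylandscape\trepeat_region\t%d\t%d\t.\t%s\t.\t%s",
                     paste(annotations$genome, annotations$contig, sep = ":"),
                     annotations$start + 1L, annotations$end,
                     annotations$strand, attr_str), con)
  invisible(file)
}

#' Read GFF3 element annotations written by [write_ty_gff()]
#'
#' @param file GFF3 path.
#' @return Annotation data.frame in 0-based half-open coordinates.
#' @export
read_ty_gff <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  seqid <- vapply(f, `[`, "", 1L)
  attrs <- vapply(f, `[`, "", 9L)
  gsplit <- strsplit(seqid, ":", fixed = TRUE)
  data.frame(
    element_id = get_attr(attrs, "ID"),
    genome = vapply(gsplit, `[`, "", 1L),
    contig = vapply(gsplit, `[`, "", 2L),
    start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L),
    family = get_attr(attrs, "family"),
    element_type = get_attr(attrs, "element_type"),
    ltr_ids = get_attr(attrs, "ltr_ids"),
    stringsAsFactors = FALSE)
}

#' Write simulated genomes as FASTA
#'
#' @param genomes Named character vector of sequences.
#' @param file Output path.
#' @export
write_genomes_fasta <- function(genomes, file) {
  set <- Biostrings::DNAStringSet(genomes)
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Write a minimal VCF 4.2 of diploid genotypes
#'
#' @param genotypes strains x sites dosage matrix (0/1/2).
#' @param file Output path.
#' @param contig Contig name for all sites.
#' @export
write_snp_vcf <- function(genotypes, file, contig = "chr1") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    gts <- gt_code[genotypes[, j] + 1L]
    writeLines(paste(c(contig, j, colnames(genotypes)[j], "A", "T", ".",
                       "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(file)
}

#' Write a strains-by-families NRD matrix as TSV
#'
#' @param cn_matrix Numeric matrix with strain rownames.
#' @param file Output path.
#' @export
write_cn_matrix <- function(cn_matrix, file) {
  df <- data.frame(strain = rownames(cn_matrix), cn_matrix,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a depth table TSV
#'
#' @param file TSV with header columns `strain`, `locus`, `median_depth`,
#'   `genome_wide_depth` (extra columns kept).
#' @return data.frame.
#' @export
read_depth_table <- function(file) {
  x <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  abort_if(!all(c("strain", "locus", "median_depth",
                  "genome_wide_depth") %in% names(x)),
           "depth table must have strain, locus, median_depth, genome_wide_depth")
  x
}
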