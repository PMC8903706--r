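# Delimited-text interchange: cohort tables as TSV, genotypes as TSV or a
# minimal VCF (GT field only), model summaries as TSV + JSON.

#' Write a cohort table as tab-separated text
#'
#' @param cohort data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort table, validating required columns
#'
#' @param path TSV file with a header row.
#' @param required character vector of columns that must be present; a
#'   missing column is reported by name.
#' @return data.frame.
#' @export
read_cohort_tsv <- function(path, required = c("subject_id",
                                               "exposure_25ohd")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write genotype dosages as a tab-separated table
#'
#' Subjects in rows (first column `subject_id`), SNPs in columns.
#'
#' @param genotypes dosage matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  g <- unclass(genotypes)
  df <- data.frame(subject_id = rownames(g), g, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a tab-separated table
#'
#' @param path TSV written by [write_genotypes_tsv()].
#' @return Dosage matrix of class `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("genotype table is missing required column(s): subject_id")
  g <- as.matrix(df[setdiff(names(df), "subject_id")])
  storage.mode(g) <- "integer"
  rownames(g) <- df$subject_id
  class(g) <- c("genotype_matrix", class(g))
  g
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Synthetic sites on chromosome 1 at consecutive positions with alleles
#' A (reference, non-effect) and G (alternate, effect); dosage d is
#' emitted as the unphased genotype with d alternate alleles. Intended for
#' interoperability with standard tooling, not as a faithful record of
#' real variants.
#'
#' @param genotypes dosage matrix.
#' @param path output `.vcf` file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  g <- unclass(genotypes)
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t")), con)
  for (j in seq_len(ncol(g))) {
    calls <- ifelse(is.na(g[, j]), "./.", gt[g[, j] + 1L])
    writeLines(paste(c("1", j, colnames(g)[j], "A", "G", ".", "PASS", ".",
                       "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a minimal VCF
#'
#' Parses the GT field of a VCF, counting alternate alleles per call;
#' `./.` becomes missing.
#'
#' @param path VCF file.
#' @return Dosage matrix of class `genotype_matrix` (SNPs in columns).
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header")
  fields <- strsplit(lines[hdr], "\t")[[1L]]
  subjects <- fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  parse_row <- function(ln) {
    f <- strsplit(ln, "\t")[[1L]]
    gt <- sub(":.*", "", f[-(1:9)])
    d <- vapply(strsplit(gt, "[/|]"), function(a)
      if (any(a == ".")) NA_integer_ else sum(a != "0"), integer(1L))
    list(id = f[3L], dosage = d)
  }
  rows <- lapply(body, parse_row)
  g <- vapply(rows, `[[`, integer(length(subjects)), "dosage")
  if (is.null(dim(g))) g <- matrix(g, nrow = length(subjects))
  dimnames(g) <- list(subjects, vapply(rows, `[[`, character(1L), "id"))
  class(g) <- c("genotype_matrix", class(g))
  g
}

#' Write a results table as TSV and JSON twins
#'
#' @param df data.frame.
#' @param stem output path without extension; writes `<stem>.tsv` and
#'   `<stem>.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_results_table <- function(df, stem) {
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(tsv, js))
}
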