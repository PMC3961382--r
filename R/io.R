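#' Read genotypes from PLINK-style transposed text or VCF
#'
#' The PLINK-style format is one header line (`snp_id chromosome position
#' ref alt` followed by subject ids) and one row per SNP carrying its
#' metadata and 0/1/2 calls (`NA` = missing). VCF files are read through
#' the vcfR package; unphased or phased diploid GT fields are mapped to
#' counts of the ALT (effect) allele, and `./.` to missing.
#'
#' @param path Input file.
#' @param format `"plink_text"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink_text", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "plink_text") read_plink_text(path) else read_vcf_genotypes(path)
}

read_plink_text <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("snp_id", "chromosome", "position", "ref", "alt")
  if (!all(meta_cols %in% names(df)[1:5])) {
    stop("malformed PLINK-style file (header): ", path, call. = FALSE)
  }
  subjects <- names(df)[-(1:5)]
  calls <- t(as.matrix(df[, -(1:5), drop = FALSE]))
  bad <- which(!(calls %in% c(0L, 1L, 2L) | is.na(calls)))
  if (length(bad)) {
    snp_row <- ((bad[1] - 1L) %/% nrow(calls)) + 1L
    stop(sprintf("invalid genotype call in %s at SNP line %d", path, snp_row),
         call. = FALSE)
  }
  genotype_matrix(calls, subjects,
                  data.frame(id = df$snp_id, chromosome = df$chromosome,
                             position = df$position, ref = df$ref,
                             alt = df$alt, stringsAsFactors = FALSE))
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  counts <- vapply(alleles, function(a) {
    if (length(a) != 2L) return(NA_integer_)  # mixed ploidy -> missing
    if (any(a == ".")) return(NA_integer_)
    s <- suppressWarnings(sum(as.integer(a)))
    if (is.na(s) || any(as.integer(a) > 1L)) return(NA_integer_)
    s
  }, integer(1))
  gtm <- matrix(counts, nrow = nrow(gt), dimnames = dimnames(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  genotype_matrix(t(gtm), colnames(gt),
                  data.frame(id = fix$ID, chromosome = fix$CHROM,
                             position = as.integer(fix$POS), ref = fix$REF,
                             alt = fix$ALT, stringsAsFactors = FALSE))
}

#' Write genotypes to the interchange formats
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @param format `"plink_text"` or `"vcf"` (a minimal VCFv4.2 with GT-only
#'   unphased calls).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("plink_text", "vcf")) {
  format <- match.arg(format)
  if (format == "plink_text") {
    df <- data.frame(snp_id = G$snps$id, chromosome = G$snps$chromosome,
                     position = G$snps$position, ref = G$snps$ref,
                     alt = G$snps$alt, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(t(G$calls)))
    names(df)[-(1:5)] <- G$subjects
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    body <- apply(G$calls, 2L, function(col) {
      ifelse(is.na(col), "./.", gt_codes[as.character(col)])
    })
    lines <- c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$subjects), collapse = "\t"))
    rows <- paste(G$snps$chromosome, G$snps$position, G$snps$id, G$snps$ref,
                  G$snps$alt, ".", "PASS", ".", "GT",
                  apply(body, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(lines, rows), path)
  }
  invisible(path)
}

#' Write / read the phenotype table as TSV
#'
#' @param P A [phenotype_table()] (for writing).
#' @param path File path.
#' @export
write_phenotypes <- function(P, path) {
  utils::write.table(P, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' Write / read a survival cohort table as TSV
#'
#' @param cohort A `survival_cohort` data frame (for writing).
#' @param path File path.
#' @export
write_survival_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_cohort
#' @export
read_survival_cohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (any(df$time < 0)) stop("negative follow-up time in ", path, call. = FALSE)
  class(df) <- c("survival_cohort", "data.frame")
  df
}

#' Write a whole study bundle to a directory
#'
#' @param bundle As returned by [make_fixture_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(bundle$training$genotypes,
                  file.path(dir, "training_genotypes.txt"))
  write_phenotypes(bundle$training$phenotypes,
                   file.path(dir, "training_phenotypes.tsv"))
  write_genotypes(bundle$test$genotypes, file.path(dir, "test_genotypes.txt"))
  write_phenotypes(bundle$test$phenotypes,
                   file.path(dir, "test_phenotypes.tsv"))
  write_survival_cohort(bundle$cohort, file.path(dir, "cohort.tsv"))
  write_risk_model(bundle$oracle_model, file.path(dir, "oracle_model.json"))
  invisible(dir)
}

#' @rdname write_study_bundle
#' @export
read_study_bundle <- function(dir) {
  list(
    training = list(
      genotypes = read_genotypes(file.path(dir, "training_genotypes.txt")),
      phenotypes = read_phenotypes(file.path(dir, "training_phenotypes.tsv"))),
    test = list(
      genotypes = read_genotypes(file.path(dir, "test_genotypes.txt")),
      phenotypes = read_phenotypes(file.path(dir, "test_phenotypes.tsv"))),
    cohort = read_survival_cohort(file.path(dir, "cohort.tsv")),
    oracle_model = read_risk_model(file.path(dir, "oracle_model.json"))
  )
}
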