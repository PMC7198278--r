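# File interchange: VCF genotypes, TSV dosage/phenotype/kinship tables.
# Every writer stamps a header comment with the seed and a parameter hash
# so identical runs are byte-identical and traceable.

# Header comment lines for output files.
io_header <- function(seed = NA, params_hash = NA, prefix = "#") {
  sprintf("%s sparsemet seed=%s params=%s", prefix,
          format(seed), format(params_hash))
}

# Short deterministic hash of an R object (parameters), independent of the
# session: sums the UTF-8 bytes of the deparsed object with positional
# weights, mod 2^28, rendered as hex.
params_hash <- function(x) {
  txt <- paste(deparse(x, control = "exact"), collapse = "\n")
  b <- as.integer(charToRaw(txt))
  w <- (seq_along(b) %% 97) + 1
  sprintf("%07x", sum((b * w) %% 268435399) %% 268435456)
}

#' Write genotypes as VCF
#'
#' Plain-text VCFv4.2 with contigs `Pv01`..`Pv11`, 1-based positions, and
#' unphased `GT` calls (`0/0`, `0/1`, `1/1`; missing as `./.`).
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, seed = NA) {
  dos <- geno$dosages
  map <- geno$snp_map
  gt <- matrix("./.", nrow(map), nrow(dos))
  td <- t(dos)
  for (d in 0:2) {
    gt[which(td == d)] <- c("0/0", "0/1", "1/1")[d + 1]
  }
  contigs <- sprintf("##contig=<ID=%s>", sort(unique(map$chrom)))
  header <- c(
    "##fileformat=VCFv4.2",
    io_header(seed, params_hash(dim(dos)), prefix = "##"),
    contigs,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(dos)), collapse = "\t")
  )
  body <- paste(map$chrom, map$pos, map$snp, map$ref, map$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses `GT` calls into alternate-allele dosages (0/1/2, missing as
#' `NA`) via vcfR. Phased separators are rejected.
#'
#' @param path Path to a VCF file.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("|", gt, fixed = TRUE), na.rm = TRUE)) {
    stop_sparsemet("Phased genotypes are not supported.",
                   "sparsemet_parameter_error")
  }
  dos_map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- matrix(dos_map[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  fix <- vcfR::getFIX(v)
  new_genotype_matrix(
    dos = t(dos),
    snp_map = tibble(
      snp = unname(fix[, "ID"]),
      chrom = unname(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = unname(fix[, "REF"]),
      alt = unname(fix[, "ALT"])
    )
  )
}

#' Write a dosage matrix as TSV
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @param seed Seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path, seed = NA) {
  dos <- geno$dosages
  lines <- c(
    io_header(seed, params_hash(dim(dos))),
    paste(c("entry", colnames(dos)), collapse = "\t"),
    paste(rownames(dos), apply(dos, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a dosage matrix from TSV
#'
#' @param path Path written by [write_dosage_tsv()].
#' @return Entry x SNP numeric matrix.
#' @export
read_dosage_tsv <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a long-format phenotype table as TSV
#'
#' Columns `entry,location,year,trait,value`, preceded by the seed header
#' comment.
#'
#' @param table Long-format phenotype tibble.
#' @param path Output path.
#' @param seed Seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(table, path, seed = NA) {
  tab <- select(table, entry, location, year, trait, value)
  lines <- c(
    io_header(seed, params_hash(dim(tab))),
    paste(names(tab), collapse = "\t"),
    do.call(paste, c(lapply(tab, format_tsv_col), list(sep = "\t")))
  )
  writeLines(lines, path)
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.double(x)) sprintf("%.10g", x) else format(x, trim = TRUE)
}

#' Read a long-format phenotype table from TSV
#'
#' @param path Path written by [write_phenotype_tsv()].
#' @return Tibble `entry,location,year,trait,value`.
#' @export
read_phenotype_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    entry = readr::col_character(),
                    location = readr::col_character(),
                    year = readr::col_integer(),
                    trait = readr::col_character(),
                    value = readr::col_double()
                  ))
}

#' Write a kinship matrix as square TSV
#'
#' @param K A kinship matrix (or `kinship` object).
#' @param path Output path.
#' @param seed Seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(K, path, seed = NA) {
  m <- if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
  lines <- c(
    io_header(seed, params_hash(dim(m))),
    paste(c("entry", colnames(m)), collapse = "\t"),
    paste(rownames(m),
          apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = "\t")),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a kinship matrix from square TSV
#'
#' @param path Path written by [write_kinship_tsv()].
#' @return A `kinship_matrix` object.
#' @export
read_kinship_tsv <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  new_kinship(m)
}
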