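# Plain-text interchange: feature matrices, dosages, VCF with dosage
# FORMAT field, summary statistics, pseudo-spectra.

#' Read and write feature matrices as TSV
#'
#' Layout: one row per sample, first column `sample_id`, remaining
#' columns labelled by bin-center ppm; `NA` marks missing bins.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @param scale Scale tag to attach on read.
#' @return `read_feature_matrix()` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(sample_id = fm$sample_ids, fm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, scale = "log") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1L]]
  v <- as.matrix(df[, -1L, drop = FALSE])
  feature_matrix(v, as.numeric(colnames(v)), ids, scale = scale)
}

#' Read and write dosage matrices as TSV
#'
#' Layout: one row per sample, first column `sample_id`, remaining
#' columns are SNP ids holding allelic dosages in `[0, 2]`.
#'
#' @param dosage Dosage matrix (or [simulate_genotypes()] result).
#' @param path File path.
#' @export
write_dosage <- function(dosage, path) {
  if (inherits(dosage, "sim_genotypes")) dosage <- dosage$dosage
  df <- data.frame(sample_id = rownames(dosage) %||%
                     sprintf("S%04d", seq_len(nrow(dosage))),
                   dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write genotypes as a VCF with dosage (DS) FORMAT field
#'
#' Minimal uncompressed VCFv4.2 with one `DS` value per sample;
#' REF/ALT are placeholder alleles (the simulator does not model
#' nucleotides).
#'
#' @param genotypes A [simulate_genotypes()] result, or a dosage matrix
#'   plus `map`.
#' @param path Output `.vcf` path.
#' @param map Data frame `snp_id, chr, pos` when `genotypes` is a bare
#'   matrix.
#' @export
write_vcf <- function(genotypes, path, map = NULL) {
  if (inherits(genotypes, "sim_genotypes")) {
    map <- genotypes$map
    dosage <- genotypes$dosage
  } else dosage <- genotypes
  if (is.null(map)) stop("SNP map required", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=metabogwas",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(dosage)), collapse = "\t")), con)
  # one line per SNP: collapse each dosage column across samples
  body <- apply(format(dosage, trim = TRUE), 2L, paste, collapse = "\t")
  writeLines(paste(map$chr, map$pos, map$snp_id, "A", "G", ".", ".",
                   ".", "DS", body, sep = "\t"), con)
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Lightweight reader for the uncompressed single-field VCFs written by
#' [write_vcf()] (one DS value per sample).
#'
#' @param path VCF path.
#' @return List `dosage` (individuals x SNPs), `map`
#'   (`snp_id, chr, pos`).
#' @export
read_vcf_dosage <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("malformed VCF header", call. = FALSE)
  cols <- strsplit(lines[hdr], "\t")[[1L]]
  samples <- cols[-(1:9)]
  parts <- strsplit(lines[-seq_len(hdr)], "\t")
  # SNPs x samples: pull the DS entry out of each sample field
  snp_rows <- vapply(parts, function(pp) {
    ds_pos <- match("DS", strsplit(pp[9L], ":")[[1L]])
    if (is.na(ds_pos)) stop("VCF record without DS field", call. = FALSE)
    as.numeric(vapply(strsplit(pp[-(1:9)], ":"), `[[`, "", ds_pos))
  }, numeric(length(samples)))
  map <- data.frame(
    snp_id = vapply(parts, `[[`, "", 3L),
    chr = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)))
  # vapply over SNPs returns samples x SNPs
  dosage <- matrix(snp_rows, nrow = length(samples))
  dimnames(dosage) <- list(samples, map$snp_id)
  list(dosage = dosage, map = map)
}

#' Read and write association summary statistics as TSV
#'
#' Columns: `snp_id chr pos feature beta se z p n` (plus any extras).
#'
#' @param records Data frame of association records.
#' @param path File path.
#' @export
write_associations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read and write pseudo-spectra as TSV
#'
#' Columns `feature_ppm z minus_log10_p`; the SNP id travels in a
#' `# snp_id=` comment line, making the round trip lossless.
#'
#' @param ps A [pseudo_spectrum()].
#' @param path File path.
#' @export
write_pseudo_spectrum <- function(ps, path) {
  stopifnot(inherits(ps, "pseudo_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# snp_id=%s", attr(ps, "snp_id")), con)
  utils::write.table(as.data.frame(ps), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pseudo_spectrum
#' @export
read_pseudo_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  snp_id <- sub("^# snp_id=", "", first)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  ps <- df[order(df$feature_ppm), ]
  rownames(ps) <- NULL
  attr(ps, "snp_id") <- snp_id
  class(ps) <- c("pseudo_spectrum", "data.frame")
  ps
}

#' Write a raw spectrum as a two-column TSV
#'
#' @param spectrum Two-column `(ppm, intensity)` matrix (e.g. from
#'   [spectrum_table()]).
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(as.data.frame(spectrum), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  as.matrix(utils::read.delim(path))
}
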