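# Standard-format I/O: FASTQ/FASTA through Biostrings, TSV through readr,
# JSON through jsonlite, plus a minimal VCF 4.2 writer for the call set.

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return Tibble with `id`, `bases`, `quals`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble::tibble(id = names(x), bases = unname(as.character(x)),
                 quals = unname(as.character(Biostrings::quality(x))))
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `id`, `bases`, `quals`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$bases, reads$id)),
    Biostrings::PhredQuality(reads$quals))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write a reference set to FASTA
#'
#' @param refs A `reference_set`.
#' @param path Output path.
#' @export
write_reference_fasta <- function(refs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(refs$seq, refs$contig_id)), path)
  invisible(path)
}

#' Read/write a sample sheet (TSV: sample_id, tag)
#'
#' @param sheet Sample sheet tibble.
#' @param path TSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Write an A/B/H matrix to TSV (missing coded `-`)
#'
#' @param abh An `abh_matrix`.
#' @param path TSV path.
#' @export
write_abh <- function(abh, path) {
  out <- tibble::as_tibble(abh)
  out[is.na(out)] <- "-"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an A/B/H matrix from TSV
#'
#' @param path TSV path written by [write_abh()].
#' @param parents,poptype Metadata to attach (see [abh_matrix()]).
#' @export
read_abh <- function(path, parents = NULL, poptype = c("bc1", "ril")) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  abh_matrix(x, parents = parents, poptype = match.arg(poptype))
}

#' Write called sites to a minimal VCF 4.2 file
#'
#' One record per biallelic site with `GT:DP:GQ:PL` per-sample fields
#' (positions 1-based, as VCF requires).
#'
#' @param calls A `site_calls`.
#' @param path Output `.vcf` path.
#' @export
write_vcf <- function(calls, path) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  g <- calls$geno |>
    dplyr::mutate(
      field = paste(
        dplyr::coalesce(gt_code[.data$gt], "./."), .data$dp,
        ifelse(is.na(.data$gq), ".", as.character(round(.data$gq))),
        ifelse(is.na(.data$pl_hom_ref), ".",
               paste(round(.data$pl_hom_ref), round(.data$pl_het),
                     round(.data$pl_hom_alt), sep = ",")),
        sep = ":")) |>
    dplyr::select("site_id", "sample_id", "field") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "field")
  g <- g[match(calls$sites$site_id, g$site_id), ]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sbgtools",
    "##INFO=<ID=SNPQ,Number=1,Type=Float,Description=\"Summed evidence against the all-major-homozygote configuration\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$samples), collapse = "\t"))
  body <- paste(
    calls$sites$contig_id, calls$sites$pos + 1L, calls$sites$site_id,
    calls$sites$ref, calls$sites$alt, round(calls$sites$snpq, 2), "PASS",
    paste0("SNPQ=", round(calls$sites$snpq, 2)), "GT:DP:GQ:PL",
    sep = "\t")
  sample_cols <- as.matrix(g[calls$samples])
  body <- paste(body, apply(sample_cols, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a linkage map to TSV
#'
#' @param map An `sbg_map`.
#' @param path TSV path.
#' @export
write_map <- function(map, path) {
  readr::write_tsv(map$markers, path)
  invisible(path)
}
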