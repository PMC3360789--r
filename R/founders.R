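#' Generate a pair of founder genomes differing at known SNP positions
#'
#' Builds a synthetic diploid-founder fixture: a set of chromosomes for
#' founder 1, plus a SNP table giving the positions at which founder 2
#' carries a different single-nucleotide allele. The two founders are
#' identical everywhere else, so every sequence difference downstream is a
#' known, recoverable marker. Defaults emulate an arabidopsis-like genome:
#' five chromosomes of 1 Mb and 125 cM each, with Col x Ler-like
#' polymorphism density.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_bp Physical length of each chromosome in bp.
#' @param chrom_cM Genetic length of each chromosome in centimorgan.
#' @param snp_density Expected SNPs per kb between the two founders.
#' @param gc GC fraction of the simulated background sequence.
#' @param seed Integer seed; identical seeds give byte-identical fixtures.
#'
#' @return An object of class `genome_fixture`: a list with `chromosomes`
#'   (character vector, founder 1), `chrom_cM`, `snp_table` (tibble with
#'   `snp_id`, `chrom`, `pos` 0-based, `allele1`, `allele2`), `gc`, `seed`.
#' @export
make_founders <- function(n_chrom = 5, chrom_bp = 1e6, chrom_cM = 125,
                          snp_density = 6, gc = 0.36, seed = 1) {
  abort_if(snp_density <= 0, "`snp_density` must be > 0")
  abort_if(chrom_bp < 1000, "`chrom_bp` must be at least 1 kb")
  n_snp <- round(snp_density * chrom_bp / 1000)
  abort_if(n_snp < 2, "`snp_density` must yield at least 2 SNPs per chromosome")
  abort_if(n_snp > chrom_bp, "`chrom_bp` too small for requested `snp_density`")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  withr::with_seed(seed, {
    chroms <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(DNA, chrom_bp, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    snp <- purrr::map_dfr(seq_len(n_chrom), function(i) {
      pos <- sort(sample.int(chrom_bp, n_snp)) - 1L
      a1 <- substring(chroms[i], pos + 1L, pos + 1L)
      a2 <- vapply(a1, function(b) sample(setdiff(DNA, b), 1L), character(1),
                   USE.NAMES = FALSE)
      tibble::tibble(chrom = i, pos = pos, allele1 = a1, allele2 = a2)
    })
  })
  snp <- dplyr::mutate(snp,
    snp_id = sprintf("S%d_%d", .data$chrom, .data$pos), .before = 1)
  structure(
    list(chromosomes = chroms, chrom_cM = rep(chrom_cM, n_chrom),
         chrom_bp = chrom_bp, snp_table = snp, gc = gc, seed = seed),
    class = "genome_fixture")
}

#' Materialize a founder's chromosome sequences
#'
#' @param fixture A `genome_fixture` from [make_founders()].
#' @param founder 1 (the backbone) or 2 (backbone with SNP alleles swapped in).
#' @return Character vector of chromosome sequences.
#' @export
founder_sequences <- function(fixture, founder = 1) {
  stopifnot(inherits(fixture, "genome_fixture"), founder %in% 1:2)
  if (founder == 1) return(fixture$chromosomes)
  vapply(seq_along(fixture$chromosomes), function(i) {
    s <- charToRaw(fixture$chromosomes[i])
    tab <- fixture$snp_table[fixture$snp_table$chrom == i, ]
    s[tab$pos + 1L] <- charToRaw(paste(tab$allele2, collapse = ""))
    rawToChar(s)
  }, character(1))
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf(
    "<genome_fixture> %d chromosome(s), %s bp / %.0f cM each, %d SNPs (seed %d)\n",
    length(x$chromosomes), format(x$chrom_bp, big.mark = ","),
    x$chrom_cM[1], nrow(x$snp_table), x$seed))
  invisible(x)
}
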