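# Parent-based co-dominant genotyping: keep SNPs where both parents are
# called homozygous for alternate alleles, then score every sample A
# (homozygous parent-1 allele), B (homozygous parent-2 allele) or H
# (heterozygous).

ABH_CODES <- c("A", "B", "H")

#' Construct an A/B/H genotype matrix
#'
#' @param m Matrix or data frame of codes in `A`/`B`/`H`/`NA` (rows = SNPs,
#'   columns = samples); any other value becomes missing. A `snp_id`
#'   column is honored when `m` is a data frame.
#' @param parents Optional named character vector `c(A = <sample>, B =
#'   <sample>)` identifying the parent columns.
#' @param poptype `"bc1"` or `"ril"`.
#' @return A tibble of class `abh_matrix` with a `snp_id` column followed
#'   by one column per sample.
#' @export
abh_matrix <- function(m, parents = NULL, poptype = c("bc1", "ril")) {
  poptype <- match.arg(poptype)
  if (is.data.frame(m)) {
    snp_id <- m$snp_id %||% as.character(seq_len(nrow(m)))
    m <- as.matrix(m[setdiff(names(m), "snp_id")])
  } else {
    snp_id <- rownames(m) %||% as.character(seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  m[!m %in% ABH_CODES] <- NA_character_
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(snp_id = snp_id), out)
  structure(out, class = c("abh_matrix", class(out)),
            parents = parents, poptype = poptype)
}

#' Sample columns of an A/B/H matrix
#' @param abh An `abh_matrix`.
#' @return Character vector of sample ids.
#' @export
abh_samples <- function(abh) setdiff(names(abh), "snp_id")

#' Extract the code matrix (SNP x sample) of an A/B/H matrix
#' @param abh An `abh_matrix`.
#' @return Character matrix with SNP ids as rownames.
#' @export
abh_codes <- function(abh) {
  m <- as.matrix(abh[abh_samples(abh)])
  rownames(m) <- abh$snp_id
  m
}

#' Long (tidy) form of an A/B/H matrix
#'
#' @param abh An `abh_matrix`.
#' @return Tibble with `snp_id`, `sample_id`, `code`.
#' @export
abh_long <- function(abh) {
  tidyr::pivot_longer(tibble::as_tibble(abh), -"snp_id",
                      names_to = "sample_id", values_to = "code")
}

#' Keep SNP sites informative for parent-based genotyping
#'
#' Retains sites where both parents are called (non-missing), both
#' homozygous, and homozygous for different alleles.
#'
#' @param calls A `site_calls` object.
#' @param parent1,parent2 Sample ids of the two parents.
#' @return A filtered `site_calls`.
#' @export
informative_sites <- function(calls, parent1, parent2) {
  stopifnot(inherits(calls, "site_calls"))
  abort_if(!all(c(parent1, parent2) %in% calls$samples),
           "unknown parent sample id")
  pg <- calls$geno |>
    dplyr::filter(.data$sample_id %in% c(parent1, parent2)) |>
    dplyr::mutate(role = ifelse(.data$sample_id == parent1, "p1", "p2")) |>
    dplyr::select("site_id", "role", "gt") |>
    tidyr::pivot_wider(names_from = "role", values_from = "gt")
  keep <- pg$site_id[!is.na(pg$p1) & !is.na(pg$p2) &
                       pg$p1 %in% c("hom_ref", "hom_alt") &
                       pg$p2 %in% c("hom_ref", "hom_alt") &
                       pg$p1 != pg$p2]
  structure(list(sites = calls$sites[calls$sites$site_id %in% keep, ],
                 geno = calls$geno[calls$geno$site_id %in% keep, ],
                 samples = calls$samples, thresholds = calls$thresholds),
            class = "site_calls")
}

#' Translate called genotypes into A/B/H codes
#'
#' At each (already informative) site, the homozygote matching parent 1
#' codes `A`, the homozygote matching parent 2 codes `B`, and the
#' heterozygote codes `H`; missing calls stay missing.
#'
#' @param calls A `site_calls`, typically from [informative_sites()].
#' @param parent1,parent2 Parent sample ids (A- and B-parent).
#' @param samples Samples to include as columns; defaults to all.
#' @param poptype `"bc1"` or `"ril"`.
#' @return An [abh_matrix()].
#' @export
to_abh <- function(calls, parent1, parent2, samples = NULL,
                   poptype = c("bc1", "ril")) {
  poptype <- match.arg(poptype)
  stopifnot(inherits(calls, "site_calls"))
  samples <- samples %||% calls$samples
  p1 <- calls$geno |>
    dplyr::filter(.data$sample_id == parent1) |>
    dplyr::select("site_id", p1_gt = "gt")
  g <- calls$geno |>
    dplyr::filter(.data$sample_id %in% samples) |>
    dplyr::left_join(p1, by = "site_id") |>
    dplyr::mutate(code = dplyr::case_when(
      is.na(.data$gt) ~ NA_character_,
      .data$gt == "het" ~ "H",
      .data$gt == .data$p1_gt ~ "A",
      TRUE ~ "B"))
  wide <- g |>
    dplyr::select("site_id", "sample_id", "code") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "code") |>
    dplyr::rename(snp_id = "site_id")
  wide <- wide[c("snp_id", intersect(samples, names(wide)))]
  abh_matrix(wide, parents = c(A = parent1, B = parent2),
             poptype = poptype)
}

#' Genotyping summary of an A/B/H matrix
#'
#' The standard accounting of a parent-based genotyping run: SNP count,
#' total non-missing genotypes, genotypes per SNP, and per-class counts
#' and percent frequencies over non-missing calls.
#'
#' @param x An `abh_matrix`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.abh_matrix <- function(x, ...) {
  m <- abh_codes(x)
  n_called <- sum(!is.na(m))
  cnt <- vapply(ABH_CODES, function(k) sum(m == k, na.rm = TRUE), integer(1))
  tibble::tibble(
    n_snps = nrow(m), n_genotypes = n_called,
    genotypes_per_snp = round(n_called / max(nrow(m), 1), 1),
    n_A = cnt[["A"]], freq_A = round(100 * cnt[["A"]] / max(n_called, 1), 1),
    n_B = cnt[["B"]], freq_B = round(100 * cnt[["B"]] / max(n_called, 1), 1),
    n_H = cnt[["H"]], freq_H = round(100 * cnt[["H"]] / max(n_called, 1), 1))
}

#' @exportS3Method generics::tidy
tidy.abh_matrix <- function(x, ...) abh_long(x)

#' @export
print.abh_matrix <- function(x, ...) {
  cat(sprintf("<abh_matrix> %d SNPs x %d samples (%s)\n",
              nrow(x), length(abh_samples(x)), attr(x, "poptype")))
  NextMethod()
}
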