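# False-positive SNP removal by missingness and genotypic-class frequency
# thresholds, with the standard BC1 and RIL presets.

#' Frequency/missingness filter presets
#'
#' BC1 preset: remove SNPs with more than 60% missing genotypes, a B or H
#' class frequency outside 25-75%, or an A (pedigree-impossible) class
#' frequency above 3% -- the A class acts as a direct error-rate proxy, so
#' the 3% cap guarantees at least 97% per-SNP accuracy. RIL preset: A and
#' B bounded to 25-75% and the residual heterozygote class capped at 15%.
#' "More than" thresholds are strict (`>`); range bounds are inclusive.
#'
#' @param pop `"bc1"` or `"ril"`.
#' @param max_missing Maximum missing fraction (default 0.60, strict).
#' @param bounds Named list of per-class `c(lower, upper)` frequency
#'   bounds overriding the preset.
#' @return A `filter_preset` list.
#' @export
filter_preset <- function(pop = c("bc1", "ril"), max_missing = 0.60,
                          bounds = NULL) {
  pop <- match.arg(pop)
  b <- if (pop == "bc1") {
    list(A = c(0, 0.03), B = c(0.25, 0.75), H = c(0.25, 0.75))
  } else {
    list(A = c(0.25, 0.75), B = c(0.25, 0.75), H = c(0, 0.15))
  }
  for (k in names(bounds)) b[[k]] <- bounds[[k]]
  for (k in names(b)) {
    abort_if(any(b[[k]] < 0 | b[[k]] > 1) || b[[k]][1] > b[[k]][2],
             "class frequency bounds must satisfy 0 <= lower <= upper <= 1")
  }
  structure(list(pop = pop, max_missing = max_missing, bounds = b),
            class = "filter_preset")
}

#' Filter an A/B/H matrix by missingness and class frequencies
#'
#' Class frequencies are computed over non-missing calls. A SNP is removed
#' when its missing fraction exceeds `max_missing` or any class frequency
#' falls outside its preset bounds; verdicts record every violated rule.
#'
#' @param abh An [abh_matrix()].
#' @param preset A [filter_preset()]; defaults to the matrix's population
#'   type.
#' @return Object of class `abh_filter`: list with `abh` (retained
#'   matrix), `verdicts` (tibble `snp_id`, `missing_frac`, `freq_A`,
#'   `freq_B`, `freq_H` as fractions, `retained`, `violations`), and
#'   `summary` (the [glance.abh_matrix()] of the retained set).
#' @export
filter_abh <- function(abh, preset = NULL) {
  stopifnot(inherits(abh, "abh_matrix"))
  preset <- preset %||% filter_preset(attr(abh, "poptype"))
  abort_if(preset$pop != attr(abh, "poptype"),
           "preset population type does not match the matrix")
  m <- abh_codes(abh)
  if (nrow(m) == 0L) {
    warning("empty A/B/H matrix", call. = FALSE)
  }
  n_s <- ncol(m)
  called <- rowSums(!is.na(m))
  miss <- (n_s - called) / n_s
  fr <- matrix(unlist(lapply(ABH_CODES, function(k) {
    rowSums(m == k, na.rm = TRUE) / pmax(called, 1L)
  })), nrow = nrow(m), ncol = 3L, dimnames = list(NULL, ABH_CODES))
  viol <- matrix(c(
    miss > preset$max_missing,
    unlist(lapply(ABH_CODES, function(k) {
      fr[, k] < preset$bounds[[k]][1] | fr[, k] > preset$bounds[[k]][2]
    }))), nrow = nrow(m), ncol = 4L,
    dimnames = list(NULL, c("missing", paste0("freq_", ABH_CODES))))
  retained <- rowSums(viol) == 0L
  verdicts <- tibble::tibble(
    snp_id = abh$snp_id, missing_frac = miss,
    freq_A = fr[, "A"], freq_B = fr[, "B"], freq_H = fr[, "H"],
    retained = retained,
    violations = vapply(seq_len(nrow(m)), function(i) {
      paste(colnames(viol)[viol[i, ]], collapse = ",")
    }, character(1)))
  kept <- abh[retained, ]
  kept <- abh_matrix(kept, parents = attr(abh, "parents"),
                     poptype = attr(abh, "poptype"))
  structure(list(abh = kept, verdicts = verdicts,
                 summary = glance.abh_matrix(kept), preset = preset),
            class = "abh_filter")
}

#' @exportS3Method generics::tidy
tidy.abh_filter <- function(x, ...) x$verdicts

#' @exportS3Method generics::glance
glance.abh_filter <- function(x, ...) x$summary

#' @export
print.abh_filter <- function(x, ...) {
  cat(sprintf("<abh_filter> %d of %d SNPs retained (%s preset)\n",
              sum(x$verdicts$retained), nrow(x$verdicts), x$preset$pop))
  invisible(x)
}
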