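# Reference construction by 100%-identity clustering: exact deduplication
# of full-length trimmed reads with occurrence counts, then abundance
# thresholding. Each retained unique sequence is its own cluster and its
# own representative contig.

#' Count unique full-length reads across all samples
#'
#' Reads whose length differs from `expected_length` (inserts shorter than
#' the read) are excluded from clustering and tallied separately.
#'
#' @param reads Tibble with a `bases` column (e.g. `run_demux()$assigned`)
#'   or a character vector of trimmed read sequences.
#' @param expected_length Full-length read size after tag trimming.
#' @return Object of class `unique_read_counts`: list with `counts`
#'   (tibble `seq`, `count`, descending), `total`, `full_length`,
#'   `not_full_length`.
#' @export
count_unique <- function(reads, expected_length) {
  abort_if(expected_length <= 0, "`expected_length` must be > 0")
  bases <- if (is.data.frame(reads)) reads$bases else reads
  full <- bases[nchar(bases) == expected_length]
  counts <- if (length(full)) {
    tibble::as_tibble(table(seq = full)) |>
      dplyr::rename(count = "n") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$seq)
  } else {
    tibble::tibble(seq = character(0), count = integer(0))
  }
  structure(list(counts = counts, total = length(bases),
                 full_length = length(full),
                 not_full_length = length(bases) - length(full),
                 expected_length = expected_length),
            class = "unique_read_counts")
}

#' Build reference contigs by abundance thresholding
#'
#' Keeps unique sequences observed between `lower` and `upper` times
#' (inclusive). The lower threshold is conventionally an approximation of
#' the population size: a real locus shared by the population should be
#' seen at least about once per sample, while rarer sequences are mostly
#' error variants; extremely abundant ones are repeats or organelle
#' leftovers. Contig ids are assigned by descending count (ties broken
#' lexicographically by sequence).
#'
#' @param counts A `unique_read_counts`.
#' @param lower Lower count threshold; defaults to `n_samples`.
#' @param upper Upper count threshold (default 100,000).
#' @param n_samples Population size used for the default `lower`.
#' @return Object of class `reference_set`: tibble (`contig_id`, `seq`,
#'   `count`) with the thresholds as attributes.
#' @export
build_reference <- function(counts, lower = NULL, upper = 1e5, n_samples = NULL) {
  stopifnot(inherits(counts, "unique_read_counts"))
  lower <- lower %||% n_samples
  abort_if(is.null(lower), "provide `lower` or `n_samples`")
  abort_if(lower > upper, "`lower` must be <= `upper`")
  kept <- dplyr::filter(counts$counts, .data$count >= lower, .data$count <= upper) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq) |>
    dplyr::mutate(contig_id = sprintf("SBG_%06d", dplyr::row_number()),
                  .before = 1)
  structure(kept, class = c("reference_set", class(kept)),
            lower = lower, upper = upper,
            read_length = counts$expected_length)
}

#' Table-1-style clustering summary
#'
#' @param counts A `unique_read_counts`.
#' @param refs The `reference_set` built from it.
#' @return One-row tibble: filtered reads, full-length reads and %, unique
#'   reads, reads used in clustering, number of clusters.
#' @export
clustering_summary <- function(counts, refs) {
  tibble::tibble(
    filtered_reads = counts$total,
    full_length_reads = counts$full_length,
    pct_full_length = round(100 * counts$full_length / max(counts$total, 1), 1),
    unique_reads = nrow(counts$counts),
    reads_in_clustering = sum(refs$count),
    n_clusters = nrow(refs))
}
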