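# Inline-tag demultiplexing and read quality control. Checks run in a
# fixed order so every rejected read has exactly one reason: tag ->
# remnant -> Ns -> homopolymer -> mean quality -> blocklist.

REJECT_REASONS <- c("no_tag", "no_remnant", "Ns", "homopolymer",
                    "low_quality", "blocklist_hit")

#' Design a set of sample identification tags
#'
#' Greedy code construction: all `4^length` candidate tags are scanned in
#' lexicographic order and accepted one by one when at Hamming distance >=
#' `min_dist` from every tag already accepted (for distance 2 this builds
#' the maximal parity-code of size `4^(length-1)`); the accepted code is
#' then shuffled under the seed and the first `n` tags issued. Distance 2
#' (the default) means a single sequencing error can never convert one
#' valid tag into another.
#'
#' @param n Number of tags required.
#' @param length Tag length in nt (default 5).
#' @param min_dist Minimum pairwise Hamming distance (default 2).
#' @param seed Integer seed for the shuffle.
#' @param ids Optional sample ids; defaults to `S001`, `S002`, ...
#' @return A sample sheet tibble (`sample_id`, `tag`).
#' @export
design_tags <- function(n, length = 5, min_dist = 2, seed = 1, ids = NULL) {
  abort_if(length > 8, "`length` > 8 not supported")
  abort_if(n < 1, "`n` must be >= 1")
  cand <- do.call(paste0, rev(expand.grid(rep(list(DNA), length),
                                          stringsAsFactors = FALSE)))
  cand <- sort(cand)
  cm <- matrix(unlist(strsplit(cand, "")), ncol = length, byrow = TRUE)
  sel <- integer(0)
  for (i in seq_along(cand)) {
    if (length(sel) == 0L) { sel <- i; next }
    d <- rowSums(cm[sel, , drop = FALSE] !=
                   matrix(cm[i, ], nrow = length(sel), ncol = length, byrow = TRUE))
    if (all(d >= min_dist)) sel <- c(sel, i)
  }
  abort_if(length(sel) < n, sprintf(
    "cannot build %d tags of length %d at distance %d; best achievable: %d",
    n, length, min_dist, length(sel)))
  tags <- withr::with_seed(seed, sample(cand[sel]))[seq_len(n)]
  tibble::tibble(sample_id = ids %||% sprintf("S%03d", seq_len(n)),
                 tag = tags)
}

#' Read-filtering configuration
#'
#' @param remnants Character vector of restriction-site remnants expected
#'   immediately after the tag (any one may match).
#' @param max_homopolymer Longest allowed single-nucleotide run.
#' @param max_n Maximum number of undetermined (N) bases.
#' @param min_mean_q Minimum mean Phred quality.
#' @param blocklist Optional FASTA path or character vector of contaminant
#'   sequences (organelle/repeat); reads sharing any k-mer are rejected.
#' @param blocklist_k k-mer length for blocklist screening.
#' @return A `qc_config` list.
#' @export
qc_config <- function(remnants, max_homopolymer = 10, max_n = 0,
                      min_mean_q = 20, blocklist = NULL, blocklist_k = 31) {
  abort_if(max_homopolymer < 0 || max_n < 0 || min_mean_q < 0,
           "thresholds must be >= 0")
  kmers <- NULL
  if (!is.null(blocklist)) {
    seqs <- if (length(blocklist) == 1L && file.exists(blocklist)) {
      as.character(Biostrings::readDNAStringSet(blocklist))
    } else blocklist
    kmers <- unique(unlist(lapply(seqs, function(s) {
      if (nchar(s) < blocklist_k) return(character(0))
      substring(s, seq_len(nchar(s) - blocklist_k + 1L),
                seq.int(blocklist_k, nchar(s)))
    })))
  }
  structure(list(remnants = remnants, max_homopolymer = max_homopolymer,
                 max_n = max_n, min_mean_q = min_mean_q,
                 blocklist_kmers = kmers, blocklist_k = blocklist_k),
            class = "qc_config")
}

# Vectorized classification; returns sample ids (NA when rejected),
# rejection reasons (NA when assigned) and tag-trimmed reads.
demux_classify <- function(bases, quals, sheet, qc) {
  n <- length(bases)
  tag_len <- nchar(sheet$tag[1])
  reason <- rep(NA_character_, n)
  sample_id <- sheet$sample_id[match(substring(bases, 1L, tag_len), sheet$tag)]
  reason[is.na(sample_id)] <- "no_tag"
  trimmed <- substring(bases, tag_len + 1L)
  tq <- substring(quals, tag_len + 1L)
  open <- is.na(reason)
  rem_ok <- rep(FALSE, n)
  for (r in qc$remnants) rem_ok <- rem_ok | startsWith(trimmed, r)
  reason[open & !rem_ok] <- "no_remnant"
  open <- is.na(reason)
  n_count <- nchar(trimmed) - nchar(gsub("N", "", trimmed, fixed = TRUE))
  reason[open & n_count > qc$max_n] <- "Ns"
  open <- is.na(reason)
  hp <- grepl(sprintf("([ACGTN])\\1{%d,}", qc$max_homopolymer), trimmed,
              perl = TRUE)
  reason[open & hp] <- "homopolymer"
  open <- is.na(reason)
  uq <- unique(tq[open])
  mq <- vapply(uq, function(s) mean(utf8ToInt(s)) - 33, numeric(1))
  reason[open][mq[match(tq[open], uq)] < qc$min_mean_q] <- "low_quality"
  if (!is.null(qc$blocklist_kmers)) {
    open <- is.na(reason)
    us <- unique(trimmed[open])
    hit <- vapply(us, function(s) {
      if (nchar(s) < qc$blocklist_k) return(FALSE)
      any(substring(s, seq_len(nchar(s) - qc$blocklist_k + 1L),
                    seq.int(qc$blocklist_k, nchar(s))) %in% qc$blocklist_kmers)
    }, logical(1))
    reason[open][hit[match(trimmed[open], us)]] <- "blocklist_hit"
  }
  sample_id[!is.na(reason)] <- NA_character_
  list(sample_id = sample_id, reason = reason, bases = trimmed, quals = tq)
}

#' Classify a single read against the sample sheet and QC filters
#'
#' Checks run in fixed order (tag, remnant, Ns, homopolymer, mean quality,
#' blocklist). On success the read is returned trimmed of the tag only; the
#' remnant stays as part of the locus sequence.
#'
#' @param read A one-row tibble or list with `bases` and `quals`.
#' @param sheet Sample sheet tibble (`sample_id`, `tag`).
#' @param qc A [qc_config()].
#' @return A list with `status` (`"assigned"` or a rejection reason), and
#'   on success `sample_id` and the trimmed `read`.
#' @export
classify_read <- function(read, sheet, qc) {
  cl <- demux_classify(read$bases, read$quals, sheet, qc)
  if (is.na(cl$reason)) {
    list(status = "assigned", sample_id = cl$sample_id,
         read = tibble::tibble(id = read$id %||% NA_character_,
                               bases = cl$bases, quals = cl$quals))
  } else {
    list(status = cl$reason)
  }
}

#' Demultiplex a read set
#'
#' Partitions every input read into exactly one category: one of the
#' samples, or one rejection reason. Assigned reads are tag-trimmed.
#'
#' @param reads An `sbg_reads` object, a tibble (`id`, `bases`, `quals`),
#'   or a FASTQ path.
#' @param sheet Sample sheet tibble.
#' @param qc A [qc_config()].
#' @param out_dir Optional directory; per-sample FASTQ files and a JSON
#'   report are written when given.
#' @return List with `assigned` (tibble `sample_id`, `id`, `bases`,
#'   `quals`), `assigned2` (paired mates of assigned reads, if present) and
#'   `report` (a `demux_report`).
#' @export
run_demux <- function(reads, sheet, qc, out_dir = NULL) {
  reads2 <- NULL
  if (inherits(reads, "sbg_reads")) {
    reads2 <- reads$reads2
    reads <- reads$reads
  } else if (is.character(reads)) {
    reads <- read_fastq(reads)
  }
  abort_if(anyDuplicated(sheet$tag) > 0, "tag collision in sample sheet")
  n <- nrow(reads)
  if (n == 0L) {
    cl <- list(sample_id = character(0), reason = character(0))
  } else {
    cl <- demux_classify(reads$bases, reads$quals, sheet, qc)
  }
  ok <- !is.na(cl$sample_id)
  assigned <- tibble::tibble(sample_id = cl$sample_id[ok], id = reads$id[ok],
                             bases = cl$bases[ok], quals = cl$quals[ok])
  assigned2 <- if (!is.null(reads2)) {
    reads2[match(assigned$id, reads2$id), ]
  }
  per_sample <- table(factor(cl$sample_id, levels = sheet$sample_id))
  rejects <- table(factor(cl$reason, levels = REJECT_REASONS))
  report <- structure(
    list(n_input = n, n_assigned = sum(ok),
         per_sample = tibble::tibble(sample_id = names(per_sample),
                                     n = as.integer(per_sample)),
         rejected = tibble::tibble(reason = names(rejects),
                                   n = as.integer(rejects))),
    class = "demux_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in unique(assigned$sample_id)) {
      write_fastq(assigned[assigned$sample_id == s, ],
                  file.path(out_dir, paste0(s, ".fastq")))
    }
    jsonlite::write_json(
      list(n_input = n, n_assigned = sum(ok),
           rejected = as.list(stats::setNames(as.integer(rejects), names(rejects)))),
      file.path(out_dir, "demux_report.json"), auto_unbox = TRUE)
  }
  list(assigned = assigned, assigned2 = assigned2, report = report)
}

#' @export
print.demux_report <- function(x, ...) {
  cat(sprintf("<demux_report> %s reads: %s assigned (%.1f%%)\n",
              format(x$n_input, big.mark = ","),
              format(x$n_assigned, big.mark = ","),
              if (x$n_input) 100 * x$n_assigned / x$n_input else 0))
  rej <- x$rejected[x$rejected$n > 0, ]
  if (nrow(rej)) {
    cat(paste(sprintf("  %-14s %d", rej$reason, rej$n), collapse = "\n"), "\n")
  }
  invisible(x)
}
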