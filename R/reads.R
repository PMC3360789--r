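# Multiplexed FASTQ simulation: inline-tagged reads from the rare-cut end
# of each selected restriction fragment, with optional paired reads from
# the frequent end, Poisson / negative-binomial per-fragment depth, and a
# constant-Phred substitution error model.

# Illumina-style adapter read-through used to pad reads from inserts
# shorter than the read length.
ADAPTER_PAD <- strrep("AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATCTCGGTGGTCGCCGTATCATT", 5)

#' Configure simulated sequencing
#'
#' @param read_length Cycles per read (default 76, single-end; use 100 with
#'   `paired = TRUE` for a paired-end design).
#' @param paired Also emit read 2 from the frequent-cut end (no tag).
#' @param mean_depth Mean reads per fragment per individual.
#' @param dispersion `NULL` for Poisson depth; otherwise the negative
#'   binomial dispersion (variance = mu + dispersion * mu^2).
#' @param qual Constant Phred quality of every base.
#' @param error_rate Per-base substitution probability; defaults to the
#'   rate implied by `qual` (`10^(-qual/10)`). Set 0 for noise-free reads.
#' @return A `read_config` list.
#' @export
read_config <- function(read_length = 76, paired = FALSE, mean_depth = 20,
                        dispersion = NULL, qual = 30, error_rate = NULL) {
  error_rate <- error_rate %||% 10^(-qual / 10)
  abort_if(error_rate < 0 || error_rate > 0.1, "`error_rate` must be in [0, 0.1]")
  abort_if(read_length < 10, "`read_length` too short")
  structure(list(read_length = as.integer(read_length), paired = paired,
                 mean_depth = mean_depth, dispersion = dispersion,
                 qual = qual, error_rate = error_rate),
            class = "read_config")
}

shared_fragments <- function(fixture, scheme) {
  f1 <- founder_sequences(fixture, 1)
  f2 <- founder_sequences(fixture, 2)
  purrr::map_dfr(seq_along(f1), function(i) {
    d1 <- digest_select(f1[i], scheme)
    d2 <- digest_select(f2[i], scheme)
    dplyr::inner_join(d1, d2, by = c("start", "end", "rare_end"),
                      suffix = c("1", "2")) |>
      dplyr::mutate(chrom = i, .before = 1)
  }) |>
    dplyr::mutate(frag_id = sprintf("F%d_%d_%d", .data$chrom, .data$start, .data$end))
}

frag_snp_table <- function(frags, fixture, read_span) {
  snp <- fixture$snp_table
  out <- dplyr::inner_join(frags, snp, by = "chrom",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos < .data$end)
  if (!nrow(out)) {
    return(tibble::tibble(frag_id = character(0), snp_id = character(0),
                          offset = integer(0), allele1 = character(0),
                          allele2 = character(0), in_read1 = logical(0)))
  }
  left <- out$rare_end == "left"
  offset <- ifelse(left, out$pos - out$start, out$end - 1L - out$pos)
  a1 <- ifelse(left, out$allele1, chartr("ACGT", "TGCA", out$allele1))
  a2 <- ifelse(left, out$allele2, chartr("ACGT", "TGCA", out$allele2))
  tibble::tibble(frag_id = out$frag_id, snp_id = out$snp_id,
                 offset = as.integer(offset), allele1 = a1, allele2 = a2,
                 in_read1 = offset < read_span)
}

pad_to <- function(x, len) {
  short <- which(nchar(x) < len)
  if (length(short)) {
    x[short] <- paste0(x[short],
                       substring(ADAPTER_PAD, 1L, len - nchar(x[short])))
  }
  substring(x, 1L, len)
}

apply_errors <- function(reads, rate) {
  if (rate == 0 || !length(reads)) return(reads)
  L <- nchar(reads[1])
  nerr <- stats::rbinom(length(reads), L, rate)
  for (j in which(nerr > 0L)) {
    rr <- charToRaw(reads[j])
    pos <- sample.int(L, nerr[j])
    for (p in pos) {
      rr[p] <- charToRaw(sample(setdiff(DNA, rawToChar(rr[p])), 1L))
    }
    reads[j] <- rawToChar(rr)
  }
  reads
}

#' Simulate tagged multiplexed reads for a population
#'
#' Read 1 is `[5-nt sample tag][fragment bases from the rare-cut end]`,
#' truncated/adapter-padded to the read length; the fragment's first bases
#' are the rare-site remnant. If `cfg$paired`, read 2 is the reverse
#' complement from the frequent-cut end (untagged). Per-individual,
#' per-fragment depth is Poisson (or negative binomial), reads drawn
#' equally from the individual's two haplotypes, and substitution errors
#' applied at the configured rate with a constant quality string.
#'
#' @param cross A `cross_truth` from [simulate_cross()].
#' @param scheme An [enzyme_scheme()].
#' @param sheet Sample sheet tibble (`sample_id`, `tag`) covering every
#'   simulated individual; tags must be unique.
#' @param cfg A [read_config()].
#' @param seed Integer seed.
#' @return Object of class `sbg_reads`: list with `reads` (tibble `id`,
#'   `bases`, `quals`), `reads2` (or `NULL`), and `truth` (fragment table,
#'   per-fragment SNP offsets, true genotype matrix). Read ids encode
#'   `fragment:individual:serial`.
#' @export
make_reads <- function(cross, scheme, sheet, cfg = read_config(), seed = 1) {
  stopifnot(inherits(cross, "cross_truth"), inherits(scheme, "enzyme_scheme"))
  abort_if(anyDuplicated(sheet$tag) > 0, "tag collision in sample sheet")
  ids <- names(cross$individuals)
  abort_if(!all(ids %in% sheet$sample_id),
           "sample sheet must contain a tag for every individual")
  tag_len <- nchar(sheet$tag[1])
  abort_if(cfg$read_length <= tag_len + nchar(scheme$rare_remnant),
           "`read_length` must exceed tag + remnant length")
  fixture <- cross$fixture
  frags <- shared_fragments(fixture, scheme)
  abort_if(nrow(frags) == 0, "digest produced no fragments")
  span1 <- cfg$read_length - tag_len
  frag_snps <- frag_snp_table(frags, fixture, span1)
  base1_1 <- pad_to(frags$seq1, span1)
  base1_2 <- pad_to(frags$seq2, span1)
  if (cfg$paired) {
    base2_1 <- pad_to(revcomp(frags$seq1), cfg$read_length)
    base2_2 <- pad_to(revcomp(frags$seq2), cfg$read_length)
  }
  mid_cM <- (frags$start + frags$end) / 2 / fixture$chrom_bp *
    fixture$chrom_cM[frags$chrom]
  tags <- sheet$tag[match(ids, sheet$sample_id)]
  nf <- nrow(frags)
  qual1 <- strrep(phred_to_char(cfg$qual), cfg$read_length)

  res <- withr::with_seed(seed, {
    per_ind <- lapply(seq_along(ids), function(k) {
      ind <- cross$individuals[[k]]
      o1 <- integer(nf); o2 <- integer(nf)
      for (i in seq_along(fixture$chromosomes)) {
        sel <- frags$chrom == i
        o1[sel] <- hap_at(ind[[i]][[1]], mid_cM[sel])
        o2[sel] <- hap_at(ind[[i]][[2]], mid_cM[sel])
      }
      d <- if (is.null(cfg$dispersion)) {
        stats::rpois(nf, cfg$mean_depth)
      } else {
        stats::rnbinom(nf, mu = cfg$mean_depth, size = 1 / cfg$dispersion)
      }
      nh1 <- stats::rbinom(nf, d, 0.5)
      cnt1 <- nh1 * (o1 == 1L) + (d - nh1) * (o2 == 1L)
      cnt2 <- d - cnt1
      sel1 <- which(cnt1 > 0L); sel2 <- which(cnt2 > 0L)
      fi <- c(sel1, sel2)
      n <- c(cnt1[sel1], cnt2[sel2])
      allele <- rep(c(1L, 2L), c(length(sel1), length(sel2)))
      list(k = k, frag = rep(fi, n), allele = rep(allele, n))
    })
    r1 <- character(0); r2 <- NULL; rid <- character(0)
    r1l <- vector("list", length(per_ind))
    r2l <- if (cfg$paired) vector("list", length(per_ind)) else NULL
    idl <- vector("list", length(per_ind))
    for (p in per_ind) {
      b <- ifelse(p$allele == 1L, base1_1[p$frag], base1_2[p$frag])
      r1l[[p$k]] <- paste0(tags[p$k], b)
      idl[[p$k]] <- paste0(frags$frag_id[p$frag], ":", ids[p$k], ":",
                           seq_along(p$frag))
      if (cfg$paired) {
        r2l[[p$k]] <- ifelse(p$allele == 1L, base2_1[p$frag], base2_2[p$frag])
      }
    }
    r1 <- apply_errors(unlist(r1l), cfg$error_rate)
    rid <- unlist(idl)
    if (cfg$paired) r2 <- apply_errors(unlist(r2l), cfg$error_rate)
    list(r1 = r1, r2 = r2, rid = rid)
  })

  reads <- tibble::tibble(id = res$rid, bases = res$r1, quals = qual1)
  reads2 <- if (cfg$paired) {
    tibble::tibble(id = res$rid, bases = res$r2, quals = qual1)
  }
  structure(list(reads = reads, reads2 = reads2,
                 truth = list(fragments = frags[c("frag_id", "chrom", "start",
                                                  "end", "rare_end")],
                              frag_snps = frag_snps, geno = cross$geno),
                 scheme = scheme, cfg = cfg, sheet = sheet, seed = seed),
            class = "sbg_reads")
}

#' @export
print.sbg_reads <- function(x, ...) {
  cat(sprintf("<sbg_reads> %s reads%s, %d fragments, %d samples\n",
              format(nrow(x$reads), big.mark = ","),
              if (!is.null(x$reads2)) " (paired)" else "",
              nrow(x$truth$fragments), nrow(x$sheet)))
  invisible(x)
}
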