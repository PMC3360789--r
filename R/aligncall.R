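# Native read-to-contig assignment and diploid genotype calling.
# Restriction fragments have fixed starts and uniform read length, so
# assignment is ungapped best-Hamming; genotypes come from a flat-prior
# Phred-based diploid likelihood model with coverage/GQ/site-quality
# thresholds.

#' Caller thresholds
#'
#' @param min_dp Minimum reads per genotype (genotype coverage; default 7).
#' @param min_gq Minimum Phred genotype quality (default 20).
#' @param min_snpq Minimum Phred site (SNP) quality (default 30).
#' @param max_mm Maximum mismatches for read assignment, and the contig
#'   merge radius for allelic variants of one locus (default 3).
#' @param error_floor Lower bound on the per-base error probability used in
#'   the likelihood model (guards against overconfident quality values).
#' @return A `caller_thresholds` list.
#' @export
caller_thresholds <- function(min_dp = 7, min_gq = 20, min_snpq = 30,
                              max_mm = 3, error_floor = 1e-4) {
  abort_if(any(c(min_dp, min_gq, min_snpq, max_mm, error_floor) < 0),
           "thresholds must be >= 0")
  structure(list(min_dp = min_dp, min_gq = min_gq, min_snpq = min_snpq,
                 max_mm = max_mm, error_floor = error_floor),
            class = "caller_thresholds")
}

#' Assign one read to its best-matching contig
#'
#' Ungapped Hamming comparison against every contig of matching length;
#' the unique best hit with at most `max_mm` mismatches wins, and ties for
#' best are left unassigned (paralog / allele-conflation guard).
#'
#' @param read_seq Read sequence (tag-trimmed).
#' @param refs A `reference_set`.
#' @param max_mm Maximum allowed mismatches.
#' @return List with `contig_id` (NA if unassigned), `mismatches`, and a
#'   `reason` when unassigned (`"length"`, `"too_many_mismatches"`,
#'   `"tie"`).
#' @export
assign_read <- function(read_seq, refs, max_mm = 3) {
  ok <- nchar(refs$seq) == nchar(read_seq)
  if (!any(ok)) {
    return(list(contig_id = NA_character_, mismatches = NA_integer_,
                reason = "length"))
  }
  d <- vapply(refs$seq[ok], hamming, integer(1), a = read_seq, USE.NAMES = FALSE)
  best <- min(d)
  if (best > max_mm) {
    return(list(contig_id = NA_character_, mismatches = NA_integer_,
                reason = "too_many_mismatches"))
  }
  if (sum(d == best) > 1L) {
    return(list(contig_id = NA_character_, mismatches = NA_integer_,
                reason = "tie"))
  }
  list(contig_id = refs$contig_id[ok][which.min(d)], mismatches = best,
       reason = NA_character_)
}

#' Assign many reads to contigs
#'
#' Equivalent to [assign_read()] applied to every read, but with an
#' exact-match fast path and a pigeonhole (`max_mm + 1` chunk) candidate
#' index so only plausible contigs are compared.
#'
#' @param reads Tibble with a `bases` column.
#' @param refs A `reference_set`.
#' @param max_mm Maximum allowed mismatches.
#' @return `reads` with `contig_id` and `mismatches` columns appended (NA
#'   where unassigned).
#' @export
assign_reads <- function(reads, refs, max_mm = 3) {
  ub <- unique(reads$bases)
  cid <- rep(NA_character_, length(ub))
  mm <- rep(NA_integer_, length(ub))
  L <- attr(refs, "read_length") %||% nchar(refs$seq[1])
  len_ok <- nchar(ub) == L
  ex <- match(ub, refs$seq)
  hitx <- len_ok & !is.na(ex)
  cid[hitx] <- refs$contig_id[ex[hitx]]
  mm[hitx] <- 0L
  todo <- which(len_ok & is.na(ex))
  if (length(todo) && nrow(refs)) {
    p <- max_mm + 1L
    cuts <- round(seq(0L, L, length.out = p + 1L))
    lookup <- lapply(seq_len(p), function(i) {
      split(seq_len(nrow(refs)),
            substring(refs$seq, cuts[i] + 1L, cuts[i + 1L]))
    })
    for (q in todo) {
      cand <- unique(unlist(lapply(seq_len(p), function(i) {
        lookup[[i]][[substring(ub[q], cuts[i] + 1L, cuts[i + 1L])]]
      })))
      if (is.null(cand) || !length(cand)) next
      d <- vapply(refs$seq[cand], hamming, integer(1), a = ub[q],
                  USE.NAMES = FALSE)
      best <- min(d)
      if (best <= max_mm && sum(d == best) == 1L) {
        cid[q] <- refs$contig_id[cand[which.min(d)]]
        mm[q] <- best
      }
    }
  }
  k <- match(reads$bases, ub)
  dplyr::mutate(reads, contig_id = cid[k], mismatches = mm[k])
}

#' Phred-scaled diploid genotype likelihoods for one biallelic pileup
#'
#' Per read with base b and error probability e = 10^(-Q/10):
#' P(b | hom-X) is 1 - e when b equals X and e/3 otherwise;
#' P(b | het) averages the two homozygous models. Log-likelihoods are
#' summed over reads and converted to normalized Phred-scaled PLs
#' (minimum 0); GQ is the second-smallest PL, capped at 99.
#'
#' @param count_ref,count_alt Reads supporting each allele.
#' @param quals Phred qualities, ordered ref reads then alt reads.
#' @param error_floor Lower bound on e.
#' @return List with `pl` (named: `hom_ref`, `het`, `hom_alt`), `gq`, and
#'   `gt` (the maximum-likelihood genotype).
#' @export
site_likelihoods <- function(count_ref, count_alt, quals, error_floor = 1e-4) {
  n <- count_ref + count_alt
  abort_if(n < 1, "empty pileup")
  abort_if(length(quals) != n, "`quals` must have one entry per read")
  e <- pmax(10^(-quals / 10), error_floor)
  is_ref <- seq_len(n) <= count_ref
  ll <- c(hom_ref = sum(log10(ifelse(is_ref, 1 - e, e / 3))),
          het = sum(log10(0.5 * (1 - e) + 0.5 * e / 3)),
          hom_alt = sum(log10(ifelse(is_ref, e / 3, 1 - e))))
  pl <- 10 * (max(ll) - ll)
  list(pl = pl, gq = min(sort(pl)[2], 99),
       gt = names(ll)[which.max(ll)])
}

GT_LEVELS <- c("hom_ref", "het", "hom_alt")

#' Call biallelic SNP genotypes from assigned reads
#'
#' Contigs within `max_mm` mismatches of each other are merged into one
#' locus (allelic variants of the same fragment cluster separately under
#' exact deduplication; the highest-count contig becomes the locus
#' reference). Within each locus, candidate sites are positions showing
#' at least two alleles; the two most frequent alleles are kept (sites
#' with more than two alleles above 5% of the pileup are dropped).
#' Genotypes are maximum-likelihood under [site_likelihoods()], set
#' missing below the depth or GQ thresholds. Site quality (SNPQ) is the
#' summed per-sample evidence against the all-major-homozygote
#' configuration, capped at 9999; sites below `min_snpq`, or with no
#' non-missing genotype other than the major homozygote, are dropped.
#'
#' @param assigned Tibble from [assign_reads()] with `sample_id`, `bases`,
#'   `quals`, `contig_id` (a `count` column of pre-aggregated multiplicities
#'   is honored).
#' @param refs The `reference_set` used for assignment.
#' @param th A [caller_thresholds()].
#' @param samples Character vector of all sample ids to report (defaults to
#'   those observed).
#' @return Object of class `site_calls`: list with `sites` (tibble
#'   `site_id`, `contig_id`, `pos` 0-based, `ref`, `alt`, `snpq`) and
#'   `geno` (tibble `site_id`, `sample_id`, `gt`, `dp`, `gq`,
#'   `pl_hom_ref`, `pl_het`, `pl_hom_alt`).
#' @export
call_variants <- function(assigned, refs, th = caller_thresholds(),
                          samples = NULL) {
  flt <- dplyr::filter(assigned, !is.na(.data$contig_id))
  agg <- if ("count" %in% names(flt)) {
    dplyr::count(flt, .data$sample_id, .data$contig_id, .data$bases,
                 .data$quals, wt = .data$count, name = "n")
  } else {
    dplyr::count(flt, .data$sample_id, .data$contig_id, .data$bases,
                 .data$quals, name = "n")
  }
  samples <- samples %||% sort(unique(assigned$sample_id))
  L <- attr(refs, "read_length") %||% nchar(refs$seq[1])
  # merge allelic-variant contigs into loci
  edges <- hamming_pairs(refs$seq, th$max_mm)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(refs) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  locus_ref_idx <- vapply(split(seq_len(nrow(refs)), comp), function(ix) {
    ix[which.max(refs$count[ix])]
  }, integer(1))
  locus_of <- stats::setNames(refs$contig_id[locus_ref_idx[comp]],
                              refs$contig_id)
  agg$locus <- locus_of[agg$contig_id]

  sites <- list(); geno <- list()
  for (loc in split(agg, agg$locus)) {
    useq <- unique(loc$bases)
    if (length(useq) < 2L) next
    ref_contig <- loc$locus[1]
    ref_seq <- refs$seq[match(ref_contig, refs$contig_id)]
    cm <- matrix(unlist(strsplit(useq, "", fixed = TRUE)),
                 ncol = L, byrow = TRUE)
    ui <- match(loc$bases, useq)
    dp_all <- rowsum(loc$n, loc$sample_id)
    total <- sum(loc$n)
    cand <- which(vapply(seq_len(L), function(p) {
      length(unique(cm[, p])) > 1L
    }, logical(1)))
    for (p in cand) {
      a <- cm[ui, p]
      wc <- sort(tapply(loc$n, a, sum), decreasing = TRUE)
      if (sum(wc / total > 0.05) > 2L) next  # multi-allelic: dropped
      keep <- names(wc)[1:2]
      refb <- substring(ref_seq, p, p)
      if (!refb %in% keep) next
      altb <- setdiff(keep, refb)
      inf <- a %in% keep
      q <- utf8ToInt(paste(substring(loc$quals[inf], p, p), collapse = "")) - 33L
      e <- pmax(10^(-q / 10), th$error_floor)
      is_ref <- a[inf] == refb
      n <- loc$n[inf]
      contrib <- cbind(
        hom_ref = n * log10(ifelse(is_ref, 1 - e, e / 3)),
        het = n * log10(0.5 * (1 - e) + 0.5 * e / 3),
        hom_alt = n * log10(ifelse(is_ref, e / 3, 1 - e)))
      ll <- rowsum(contrib, loc$sample_id[inf])
      pl <- 10 * (apply(ll, 1L, max) - ll)
      gq <- pmin(apply(pl, 1L, function(x) sort(x)[2]), 99)
      gt <- GT_LEVELS[max.col(ll, ties.method = "first")]
      dp <- dp_all[rownames(ll), 1]
      miss <- dp < th$min_dp | gq < th$min_gq
      major_gt <- if (wc[refb] >= wc[altb]) "hom_ref" else "hom_alt"
      snpq <- min(sum(pl[, major_gt]), 9999)
      if (snpq < th$min_snpq) next
      if (!any(!miss & gt != major_gt)) next
      site_id <- paste0(ref_contig, "_", p)
      sites[[site_id]] <- tibble::tibble(
        site_id = site_id, contig_id = ref_contig, pos = p - 1L,
        ref = refb, alt = altb, snpq = snpq)
      gt[miss] <- NA_character_
      gtab <- tibble::tibble(site_id = site_id, sample_id = rownames(ll),
                             gt = gt, dp = as.integer(dp), gq = gq,
                             pl_hom_ref = pl[, "hom_ref"],
                             pl_het = pl[, "het"],
                             pl_hom_alt = pl[, "hom_alt"])
      absent <- setdiff(samples, gtab$sample_id)
      if (length(absent)) {
        gtab <- dplyr::bind_rows(gtab, tibble::tibble(
          site_id = site_id, sample_id = absent, gt = NA_character_,
          dp = 0L, gq = NA_real_, pl_hom_ref = NA_real_, pl_het = NA_real_,
          pl_hom_alt = NA_real_))
      }
      geno[[site_id]] <- gtab
    }
  }
  structure(list(sites = dplyr::bind_rows(sites),
                 geno = dplyr::bind_rows(geno),
                 samples = samples, thresholds = th),
            class = "site_calls")
}

#' @export
print.site_calls <- function(x, ...) {
  cat(sprintf("<site_calls> %d biallelic sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}
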