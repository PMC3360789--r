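# Independent brute-force oracles and small shared fixtures.

# Exhaustive digest oracle: scan every position for every site, enumerate
# all adjacent cut intervals, then apply the selection rules step by step.
oracle_digest <- function(sequence, scheme) {
  L <- nchar(sequence)
  scan_site <- function(site) {
    w <- nchar(site)
    if (L < w) return(integer(0))
    which(substring(sequence, seq_len(L - w + 1L), seq.int(w, L)) == site)
  }
  sites <- rbind(
    data.frame(pos = scan_site(scheme$rare_site), rare = TRUE),
    data.frame(pos = scan_site(scheme$frequent_site), rare = FALSE))
  sites <- sites[order(sites$pos), ]
  dup <- sites$pos[duplicated(sites$pos)]
  sites <- sites[!sites$pos %in% dup, ]
  out <- list()
  if (nrow(sites) >= 2L) {
    for (k in seq_len(nrow(sites) - 1L)) {
      a <- sites[k, ]; b <- sites[k + 1L, ]
      if (a$rare == b$rare) next
      off_a <- if (a$rare) scheme$rare_offset else scheme$frequent_offset
      len_b <- if (b$rare) nchar(scheme$rare_site) else nchar(scheme$frequent_site)
      off_b <- if (b$rare) scheme$rare_offset else scheme$frequent_offset
      start <- a$pos - 1L + off_a
      end <- b$pos - 1L + len_b - off_b
      len <- end - start
      if (len < max(scheme$min_fragment_len, 1L) || len > scheme$max_fragment_len) next
      fs <- substring(sequence, start + 1L, end)
      if (!is.null(scheme$excluder_site) &&
          grepl(scheme$excluder_site, fs, fixed = TRUE)) next
      out[[length(out) + 1L]] <- data.frame(
        start = start, end = end, rare_end = if (a$rare) "left" else "right")
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      rare_end = character(0)))
  }
  do.call(rbind, out)
}

# Brute-force diploid likelihood oracle: explicit per-read probability
# products (no shared code with site_likelihoods).
oracle_likelihoods <- function(ref_quals, alt_quals, error_floor = 1e-4) {
  p_base <- function(q, matches) {
    e <- max(10^(-q / 10), error_floor)
    if (matches) 1 - e else e / 3
  }
  models <- list(
    hom_ref = function(q, is_ref) p_base(q, is_ref),
    het = function(q, is_ref) 0.5 * p_base(q, is_ref) + 0.5 * p_base(q, !is_ref),
    hom_alt = function(q, is_ref) p_base(q, !is_ref))
  ll <- vapply(models, function(f) {
    s <- 0
    for (q in ref_quals) s <- s + log10(f(q, TRUE))
    for (q in alt_quals) s <- s + log10(f(q, FALSE))
    s
  }, numeric(1))
  10 * (max(ll) - ll)
}

random_dna <- function(n, seed = NULL, gc = 0.4) {
  gen <- function() {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
gtools_perms <- all_perms

# Map called sites back to the simulator's true SNPs via fragment-prefix
# sequence keys (contig sequence == read-window prefix of one allele).
map_sites_to_truth <- function(run) {
  refs <- run$refs
  fr <- dplyr::inner_join(
    run$reads$truth$frag_snps,
    sbgtools:::shared_fragments(run$fixture, run$config$scheme),
    by = "frag_id")
  span <- run$config$read_cfg$read_length - 5L
  keys <- dplyr::bind_rows(
    dplyr::mutate(fr, seqkey = substring(fr$seq1, 1, span)),
    dplyr::mutate(fr, seqkey = substring(fr$seq2, 1, span)))
  dplyr::inner_join(
    dplyr::mutate(run$calls$sites,
                  seqkey = refs$seq[match(run$calls$sites$contig_id,
                                          refs$contig_id)]),
    keys, by = "seqkey", relationship = "many-to-many") |>
    dplyr::filter(.data$pos == .data$offset) |>
    dplyr::distinct(.data$site_id, .data$snp_id, .data$chrom)
}

# Small BC1 fixture + full pipeline run shared across test files (built
# once per test session).
mini_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sbg_config(
      pop = "bc1", n_offspring = 40,
      fixture_args = list(n_chrom = 2, chrom_bp = 2e5, chrom_cM = 60,
                          snp_density = 6),
      read_cfg = read_config(mean_depth = 12, error_rate = 0),
      map = map_config(n_orders = 40),
      do_map = TRUE, seed = 42)
    cache <<- run_sbg(cfg)
    cache
  }
})
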