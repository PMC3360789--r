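make_refs <- function(seqs, counts = rev(seq_along(seqs)) * 100) {
  cu <- count_unique(rep(seqs, counts), nchar(seqs[1]))
  build_reference(cu, lower = 1, upper = Inf)
}

test_that("single-read assignment picks the unique best contig", {
  set.seed(2)
  base <- random_dna(40)
  far <- vapply(1:5, function(i) random_dna(40), character(1))
  refs <- make_refs(c(base, far))
  # exact match
  hit <- assign_read(base, refs)
  expect_equal(hit$mismatches, 0L)
  expect_equal(refs$seq[refs$contig_id == hit$contig_id], base)
  # one mismatch, still unique best
  mut <- base
  substring(mut, 7, 7) <- setdiff(c("A", "C", "G", "T"), substring(base, 7, 7))[1]
  hit1 <- assign_read(mut, refs, max_mm = 3)
  expect_equal(hit1$mismatches, 1L)
  # over the mismatch budget
  mut4 <- base
  for (p in c(3, 9, 15, 21)) {
    substring(mut4, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substring(mut4, p, p))[1]
  }
  miss <- assign_read(mut4, refs, max_mm = 3)
  expect_true(is.na(miss$contig_id))
  expect_equal(miss$reason, "too_many_mismatches")
  # equidistant tie between two contigs
  a <- paste0("AA", substring(base, 3))
  b <- paste0("CC", substring(base, 3))
  refs2 <- make_refs(c(a, b))
  tie <- assign_read(paste0("AC", substring(base, 3)), refs2, max_mm = 3)
  expect_true(is.na(tie$contig_id))
  expect_equal(tie$reason, "tie")
  # length mismatch
  expect_equal(assign_read("ACGT", refs)$reason, "length")
})

test_that("bulk assignment agrees with the per-read brute force", {
  set.seed(5)
  refs <- make_refs(vapply(1:30, function(i) random_dna(36), character(1)))
  reads <- character(0)
  for (i in 1:120) {
    s <- refs$seq[sample.int(30, 1)]
    nmut <- sample(0:5, 1)
    for (p in sample.int(36, nmut)) {
      substring(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substring(s, p, p)), 1)
    }
    reads <- c(reads, s)
  }
  got <- assign_reads(tibble::tibble(bases = reads), refs, max_mm = 3)
  for (i in seq_along(reads)) {
    ref <- assign_read(reads[i], refs, max_mm = 3)
    expect_identical(got$contig_id[i], ref$contig_id)
    if (!is.na(ref$contig_id)) {
      expect_identical(got$mismatches[i], ref$mismatches)
    }
  }
})

test_that("genotype likelihoods match hand-computed values", {
  # 8 reads of one allele at Q30
  r <- site_likelihoods(8, 0, rep(30, 8))
  expect_equal(unname(r$pl["hom_ref"]), 0)
  expect_equal(unname(r$pl["het"]), 24.07, tolerance = 1e-3)
  expect_equal(unname(r$pl["hom_alt"]), 278.2, tolerance = 1e-3)
  expect_equal(r$gq, 24.07, tolerance = 1e-3)
  expect_equal(r$gt, "hom_ref")
  # 1 + 1 at equal quality: het is the maximum-likelihood genotype
  r11 <- site_likelihoods(1, 1, c(30, 30))
  expect_equal(r11$gt, "het")
  # balanced 4 + 4: het PL 0, homozygote PLs equal by symmetry
  r44 <- site_likelihoods(4, 4, rep(30, 8))
  expect_equal(unname(r44$pl["het"]), 0)
  expect_equal(unname(r44$pl["hom_ref"]), unname(r44$pl["hom_alt"]))
  expect_error(site_likelihoods(0, 0, numeric(0)), "empty")
})

test_that("likelihoods match the brute-force oracle for all small pileups", {
  quals_of <- function(n, offset) (c(20, 30, 40))[(seq_len(n) + offset) %% 3 + 1]
  for (n in 1:10) {
    for (nref in 0:n) {
      nalt <- n - nref
      if (n == 0) next
      qr <- quals_of(nref, 0)
      qa <- quals_of(nalt, 1)
      got <- site_likelihoods(nref, nalt, c(qr, qa))
      exp <- oracle_likelihoods(qr, qa)
      expect_equal(unname(got$pl), unname(exp), tolerance = 1e-6)
      expect_equal(unname(got$gq), unname(min(sort(exp)[2], 99)),
                   tolerance = 1e-6)
    }
  }
})

# A constructed two-allele locus: parents fixed for alternate alleles,
# one het offspring, one low-depth offspring.
call_fixture <- function(dp_het = 8, th = caller_thresholds()) {
  set.seed(77)
  a1 <- random_dna(30)
  p <- 11
  a2 <- a1
  substring(a2, p, p) <- setdiff(c("A", "C", "G", "T"), substring(a1, p, p))[1]
  reads <- dplyr::bind_rows(
    tibble::tibble(sample_id = "P1", bases = a1, quals = strrep("I", 30),
                   count = 10),
    tibble::tibble(sample_id = "P2", bases = a2, quals = strrep("I", 30),
                   count = 10),
    tibble::tibble(sample_id = "S1", bases = c(a1, a2),
                   quals = strrep("I", 30), count = dp_het / 2),
    tibble::tibble(sample_id = "S2", bases = c(a1, a2),
                   quals = strrep("I", 30), count = 3))
  refs <- make_refs(c(a1, a2), counts = c(500, 400))
  expanded <- reads[rep(seq_len(nrow(reads)), reads$count), ]
  expanded$count <- NULL
  asn <- assign_reads(expanded, refs, th$max_mm)
  call_variants(asn, refs, th, samples = c("P1", "P2", "S1", "S2"))
}

test_that("variant calling emits the constructed site with oracle-consistent values", {
  calls <- call_fixture(dp_het = 8)
  expect_equal(nrow(calls$sites), 1L)
  expect_equal(calls$sites$pos, 10L)  # 0-based
  g <- calls$geno
  expect_equal(g$gt[g$sample_id == "P1"], "hom_ref")
  expect_equal(g$gt[g$sample_id == "P2"], "hom_alt")
  expect_equal(g$gt[g$sample_id == "S1"], "het")
  # S2 at depth 6 < 7: genotype missing
  expect_true(is.na(g$gt[g$sample_id == "S2"]))
  expect_equal(g$dp[g$sample_id == "S2"], 6L)
  # het GQ matches the independent oracle (4 + 4 at Q40)
  exp <- oracle_likelihoods(rep(40, 4), rep(40, 4))
  expect_equal(unname(g$gq[g$sample_id == "S1"]), min(sort(exp)[2], 99),
               tolerance = 1e-6)
  # SNPQ is the summed evidence against the all-major-homozygote model
  expect_gt(calls$sites$snpq, calls$thresholds$min_snpq)
})

test_that("invariant sites are not emitted", {
  set.seed(9)
  a1 <- random_dna(30)
  refs <- make_refs(a1, counts = 500)
  reads <- tibble::tibble(sample_id = rep(c("P1", "P2"), each = 10),
                          bases = a1, quals = strrep("I", 30))
  asn <- assign_reads(reads, refs)
  calls <- call_variants(asn, refs, samples = c("P1", "P2"))
  expect_equal(nrow(calls$sites), 0L)
})

test_that("raising depth or GQ thresholds never rescues a missing genotype", {
  base <- call_fixture(dp_het = 8, th = caller_thresholds(min_dp = 4, min_gq = 10))
  stricter <- list(
    call_fixture(dp_het = 8, th = caller_thresholds(min_dp = 7, min_gq = 10)),
    call_fixture(dp_het = 8, th = caller_thresholds(min_dp = 4, min_gq = 30)))
  for (s in stricter) {
    joined <- dplyr::inner_join(base$geno, s$geno,
                                by = c("site_id", "sample_id"))
    expect_true(all(!(is.na(joined$gt.x) & !is.na(joined$gt.y))))
  }
})

test_that("genotype calls at GQ >= 20 are well calibrated on noisy reads", {
  fx <- make_founders(n_chrom = 1, chrom_bp = 3e5, chrom_cM = 80,
                      snp_density = 5, seed = 31)
  cr <- simulate_cross(fx, population_model("BC1", n_offspring = 30), seed = 32)
  sheet <- design_tags(32, ids = names(cr$individuals), seed = 33)
  rd <- make_reads(cr, scheme_ecori_msei(), sheet,
                   read_config(mean_depth = 15, qual = 30), seed = 34)
  dm <- run_demux(rd, sheet, qc_config(remnants = "AATTC"))
  refs <- build_reference(count_unique(dm$assigned, 71), n_samples = 32)
  asn <- assign_reads(dm$assigned, refs)
  calls <- call_variants(asn, refs, samples = names(cr$individuals))
  inf <- informative_sites(calls, "P1", "P2")
  abh <- to_abh(inf, "P1", "P2")
  truth <- truth_abh(cr)
  lg <- dplyr::filter(abh_long(abh), !is.na(.data$code),
                      !.data$sample_id %in% c("P1", "P2"))
  # map called sites back to true SNPs via the fragment SNP table
  fs <- rd$truth$frag_snps
  fr <- dplyr::inner_join(fs, sbgtools:::shared_fragments(fx, scheme_ecori_msei()),
                          by = "frag_id")
  keys <- dplyr::bind_rows(
    dplyr::mutate(fr, seqkey = substring(.data$seq1, 1, 71)),
    dplyr::mutate(fr, seqkey = substring(.data$seq2, 1, 71)))
  site_tab <- dplyr::inner_join(
    dplyr::mutate(calls$sites,
                  seqkey = refs$seq[match(.data$contig_id, refs$contig_id)]),
    keys, by = "seqkey", relationship = "many-to-many") |>
    dplyr::filter(.data$pos == .data$offset) |>
    dplyr::distinct(.data$site_id, .data$snp_id)
  lg <- dplyr::inner_join(lg, site_tab, by = c("snp_id" = "site_id"))
  tm <- abh_codes(truth)
  truth_code <- tm[cbind(lg$snp_id.y, lg$sample_id)]
  err <- mean(lg$code != truth_code)
  expect_gt(nrow(lg), 500)
  expect_lt(err, 0.011)
})
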