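# End-to-end orchestration: simulate -> demux -> refbuild -> call ->
# parent-based A/B/H -> frequency filter -> linkage map, with per-stage
# accounting and a single fanned-out seed.

#' Configure an end-to-end run
#'
#' Bundles every stage's parameter block. Each stochastic stage derives
#' its own child seed from the global `seed` and its stage name, so any
#' stage can be re-run standalone and reproduce the pipeline's result.
#'
#' @param pop `"bc1"` or `"ril"`.
#' @param n_offspring Offspring count (default 220, the arabidopsis-like
#'   design; use 85 for the lettuce-like RIL design).
#' @param generations RIL generation number (default 8).
#' @param fixture_args Arguments for [make_founders()].
#' @param scheme An [enzyme_scheme()].
#' @param read_cfg A [read_config()].
#' @param qc Optional [qc_config()]; defaults to the scheme's remnants
#'   with standard thresholds.
#' @param thresholds A [caller_thresholds()].
#' @param preset Optional [filter_preset()]; defaults to `pop`.
#' @param map A [map_config()].
#' @param do_map Build the linkage map (default TRUE).
#' @param seed Global integer seed.
#' @return An `sbg_config` list.
#' @export
sbg_config <- function(pop = c("bc1", "ril"), n_offspring = 220,
                       generations = 8, fixture_args = list(),
                       scheme = scheme_ecori_msei(),
                       read_cfg = read_config(), qc = NULL,
                       thresholds = caller_thresholds(), preset = NULL,
                       map = map_config(), do_map = TRUE, seed = 1) {
  pop <- match.arg(pop)
  structure(list(pop = pop, n_offspring = n_offspring,
                 generations = generations, fixture_args = fixture_args,
                 scheme = scheme, read_cfg = read_cfg, qc = qc,
                 thresholds = thresholds, preset = preset, map = map,
                 do_map = do_map, seed = seed),
            class = "sbg_config")
}

#' Run the full sequence-based genotyping pipeline
#'
#' @param config An [sbg_config()].
#' @param out_dir Optional directory for artifacts (FASTQ, reference
#'   FASTA, VCF, A/B/H TSV, map TSV, reports).
#' @return Object of class `sbg_run`: list with `fixture`, `cross`,
#'   `sheet`, `reads`, `demux`, `counts`, `refs`, `calls`, `abh`,
#'   `filtered`, `map` (or NULL) and `report` (per-stage counts).
#' @export
run_sbg <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sbg_config"))
  seed <- config$seed
  report <- list()
  note <- function(stage, n, what) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      stage = stage, n = n, what = what)
  }

  fixture <- do.call(make_founders,
                     c(config$fixture_args,
                       list(seed = child_seed(seed, "founders"))))
  model <- population_model(
    kind = if (config$pop == "bc1") "BC1" else "RIL_selfed",
    n_offspring = config$n_offspring, generations = config$generations,
    include_parents = TRUE)
  cross <- simulate_cross(fixture, model, seed = child_seed(seed, "cross"))
  note("simulate", nrow(fixture$snp_table), "true SNPs in fixture")

  ids <- names(cross$individuals)
  sheet <- design_tags(length(ids), seed = child_seed(seed, "tags"), ids = ids)
  reads <- make_reads(cross, config$scheme, sheet, config$read_cfg,
                      seed = child_seed(seed, "reads"))
  note("make_reads", nrow(reads$reads), "reads generated")

  qc <- config$qc %||% qc_config(remnants = config$scheme$rare_remnant)
  dem <- run_demux(reads, sheet, qc)
  note("demux", nrow(dem$assigned), "reads assigned")

  expected <- config$read_cfg$read_length - nchar(sheet$tag[1])
  counts <- count_unique(dem$assigned, expected)
  refs <- build_reference(counts, n_samples = nrow(sheet))
  note("refbuild", nrow(refs), "reference contigs")

  assigned <- assign_reads(dem$assigned, refs, config$thresholds$max_mm)
  note("assign", sum(!is.na(assigned$contig_id)), "reads assigned to contigs")
  calls <- call_variants(assigned, refs, config$thresholds, samples = ids)
  note("call", nrow(calls$sites), "biallelic sites called")

  inf <- informative_sites(calls, "P1", "P2")
  abh <- to_abh(inf, "P1", "P2", poptype = config$pop)
  note("parentgeno", nrow(abh), "informative SNPs scored A/B/H")

  filt <- filter_abh(abh, config$preset %||% filter_preset(config$pop))
  note("filter", nrow(filt$abh), "SNPs retained")

  map <- NULL
  if (config$do_map && nrow(filt$abh) >= 2L) {
    cfg <- config$map
    cfg$seed <- child_seed(seed, "map")
    map <- linkage_map(filt$abh, cfg)
    note("map", length(map$groups), "linkage groups")
  }

  run <- structure(list(fixture = fixture, cross = cross, sheet = sheet,
                        reads = reads, demux = dem, counts = counts,
                        refs = refs, calls = calls, abh = abh,
                        filtered = filt, map = map,
                        report = dplyr::bind_rows(report), config = config),
                   class = "sbg_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fastq(run$reads$reads, file.path(out_dir, "reads.fastq"))
  write_sample_sheet(run$sheet, file.path(out_dir, "sample_sheet.tsv"))
  write_reference_fasta(run$refs, file.path(out_dir, "reference.fasta"))
  write_vcf(run$calls, file.path(out_dir, "calls.vcf"))
  write_abh(run$abh, file.path(out_dir, "abh.tsv"))
  write_abh(run$filtered$abh, file.path(out_dir, "abh_filtered.tsv"))
  if (!is.null(run$map)) write_map(run$map, file.path(out_dir, "map.tsv"))
  readr::write_tsv(run$report, file.path(out_dir, "run_report.tsv"))
  jsonlite::write_json(run$filtered$summary,
                       file.path(out_dir, "genotyping_summary.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.sbg_run <- function(x, ...) {
  cat("<sbg_run>\n")
  print(x$report)
  invisible(x)
}
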