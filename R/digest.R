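# In-silico restriction digest with rare/frequent cutter selection, the
# AFLP-style complexity-reduction step: only fragments flanked by one rare
# and one frequent cut amplify with the two-adapter primer pair.

#' Define a restriction-digest complexity-reduction scheme
#'
#' Recognition sites must be palindromic (all defaults are), so a
#' single-strand scan finds every cut. `offset` is the cut position within
#' the site on the read-bearing strand; with the conventional offset of 1
#' the fragment read starts with the site remnant (e.g. `AATTC` for EcoRI).
#'
#' @param rare_site,frequent_site Recognition sequences.
#' @param rare_offset,frequent_offset Cut offset within each site.
#' @param excluder_site Optional third-enzyme site; fragments containing it
#'   are removed (further complexity reduction, as with MseI in the
#'   three-enzyme lettuce-style scheme).
#' @param rare_remnant,frequent_remnant Site remnant expected at the start
#'   of read 1 / read 2.
#' @param min_fragment_len,max_fragment_len Retained fragment length window
#'   in bp (size selection; short-fragment removal also eliminates adapter
#'   dimers).
#' @return An `enzyme_scheme` list.
#' @export
enzyme_scheme <- function(rare_site, rare_offset = 1L,
                          frequent_site, frequent_offset = 1L,
                          excluder_site = NULL,
                          rare_remnant = substring(rare_site, rare_offset + 1L),
                          frequent_remnant = substring(frequent_site, frequent_offset + 1L),
                          min_fragment_len = 0L, max_fragment_len = Inf) {
  abort_if(min_fragment_len < 0, "`min_fragment_len` must be >= 0")
  for (s in c(rare_site, frequent_site, excluder_site)) {
    abort_if(s != revcomp(s), sprintf("site %s is not palindromic", s))
  }
  structure(list(rare_site = rare_site, rare_offset = as.integer(rare_offset),
                 frequent_site = frequent_site,
                 frequent_offset = as.integer(frequent_offset),
                 excluder_site = excluder_site,
                 rare_remnant = rare_remnant, frequent_remnant = frequent_remnant,
                 min_fragment_len = min_fragment_len,
                 max_fragment_len = max_fragment_len),
            class = "enzyme_scheme")
}

#' @describeIn enzyme_scheme EcoRI/MseI two-enzyme scheme (arabidopsis-like
#'   single-end libraries) with an 80-2000 bp size-selection window.
#' @export
scheme_ecori_msei <- function(min_fragment_len = 80L, max_fragment_len = 2000L) {
  enzyme_scheme("GAATTC", 1L, "TTAA", 1L, NULL, "AATTC", "TAA",
                min_fragment_len, max_fragment_len)
}

#' @describeIn enzyme_scheme PstI/TaqI three-enzyme scheme with MseI as
#'   excluder (lettuce-like paired-end libraries); fragments below 200 bp
#'   are removed (adapter-dimer / size selection).
#' @export
scheme_psti_taqi_msei <- function(min_fragment_len = 200L, max_fragment_len = 2000L) {
  enzyme_scheme("CTGCAG", 1L, "TCGA", 1L, "TTAA", "TGCAG", "CGA",
                min_fragment_len, max_fragment_len)
}

find_sites <- function(sequence, site) {
  hits <- gregexpr(site, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Digest a sequence and select amplifiable rare-frequent fragments
#'
#' Cuts at every rare and frequent site and keeps only fragments flanked by
#' one rare-cut end and one frequent-cut end (rare-rare and
#' frequent-frequent fragments carry the same adapter at both ends and do
#' not amplify), with no internal excluder site, and with length inside the
#' scheme's window. Fragment coordinates are 0-based half-open on the
#' input. `seq` is oriented to start at the rare cut (reverse-complemented
#' when the rare end is on the right), so it always begins with the rare
#' remnant.
#'
#' @param sequence A nucleotide string.
#' @param scheme An [enzyme_scheme()].
#' @return Tibble with `start`, `end`, `rare_end` ("left"/"right"),
#'   `length`, `seq` (rare-end-oriented).
#' @export
digest_select <- function(sequence, scheme) {
  stopifnot(inherits(scheme, "enzyme_scheme"))
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          rare_end = character(0), length = integer(0),
                          seq = character(0))
  if (nchar(sequence) < min(nchar(scheme$rare_site), nchar(scheme$frequent_site))) {
    return(empty)
  }
  r <- find_sites(sequence, scheme$rare_site)
  f <- find_sites(sequence, scheme$frequent_site)
  sites <- rbind(
    if (length(r)) cbind(pos = r, rare = rep(1L, length(r))),
    if (length(f)) cbind(pos = f, rare = rep(0L, length(f))))
  if (is.null(sites) || nrow(sites) < 2L) return(empty)
  sites <- sites[order(sites[, "pos"]), , drop = FALSE]
  # duplicated cut coordinates across enzymes are degenerate; drop them
  dup <- duplicated(sites[, "pos"]) | duplicated(sites[, "pos"], fromLast = TRUE)
  sites <- sites[!dup, , drop = FALSE]
  if (nrow(sites) < 2L) return(empty)
  n <- nrow(sites)
  left <- sites[-n, , drop = FALSE]
  right <- sites[-1L, , drop = FALSE]
  keep <- left[, "rare"] != right[, "rare"]
  if (!any(keep)) return(empty)
  left <- left[keep, , drop = FALSE]
  right <- right[keep, , drop = FALSE]
  site_len <- function(rare) ifelse(rare == 1L, nchar(scheme$rare_site),
                                    nchar(scheme$frequent_site))
  offset <- function(rare) ifelse(rare == 1L, scheme$rare_offset,
                                  scheme$frequent_offset)
  # fragment spans [site_start - 1 + offset, site_start - 1 + len - offset)
  start <- left[, "pos"] - 1L + offset(left[, "rare"])
  end <- right[, "pos"] - 1L + site_len(right[, "rare"]) - offset(right[, "rare"])
  len <- end - start
  ok <- len >= max(scheme$min_fragment_len, 1L) & len <= scheme$max_fragment_len
  start <- start[ok]; end <- end[ok]
  rare_left <- left[ok, "rare"] == 1L
  if (!length(start)) return(empty)
  fs <- substring(sequence, start + 1L, end)
  if (!is.null(scheme$excluder_site)) {
    hit <- grepl(scheme$excluder_site, fs, fixed = TRUE)
    fs <- fs[!hit]; start <- start[!hit]; end <- end[!hit]
    rare_left <- rare_left[!hit]
    if (!length(start)) return(empty)
  }
  oriented <- fs
  oriented[!rare_left] <- revcomp(fs[!rare_left])
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 rare_end = ifelse(rare_left, "left", "right"),
                 length = as.integer(end - start), seq = oriented)
}
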