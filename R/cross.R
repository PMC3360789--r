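# Meiosis and mapping-population simulation under the Haldane
# (no-interference) model: crossover counts per chromosome are
# Poisson(length_cM / 100) with positions uniform on the cM scale.

#' Describe a mapping population to simulate
#'
#' @param kind `"BC1"` (F1 backcrossed to the recurrent parent, founder 2)
#'   or `"RIL_selfed"` (recombinant inbred lines by repeated selfing).
#' @param n_offspring Number of offspring individuals.
#' @param generations For RILs, the named generation (e.g. 8 for F8); the
#'   F1 is selfed `generations - 1` times. Must be >= 2.
#' @param include_parents Add the two founders themselves as samples
#'   `P1`/`P2` (as real experiments sequence the parental lines alongside).
#' @return A `population_model` list.
#' @export
population_model <- function(kind = c("BC1", "RIL_selfed"), n_offspring = 220,
                             generations = 8, include_parents = TRUE) {
  kind <- match.arg(kind)
  abort_if(n_offspring < 1, "`n_offspring` must be >= 1")
  abort_if(kind == "RIL_selfed" && generations < 2, "RIL `generations` must be >= 2")
  structure(list(kind = kind, n_offspring = n_offspring,
                 generations = generations, include_parents = include_parents),
            class = "population_model")
}

# A haplotype is a piecewise-constant founder-origin function on [0, L) cM:
# interior breakpoints (ascending) and one origin value per segment.
const_hap <- function(v) list(breaks = numeric(0), vals = v)

hap_at <- function(h, x) h$vals[findInterval(x, h$breaks) + 1L]

# One gamete from a diploid (h1, h2) on a chromosome of L cM.
gamete <- function(h1, h2, L) {
  k <- stats::rpois(1L, L / 100)
  xo <- sort(stats::runif(k, 0, L))
  start <- sample.int(2L, 1L)
  breaks <- sort(unique(c(h1$breaks, h2$breaks, xo)))
  mids <- (c(0, breaks) + c(breaks, L)) / 2
  active <- (start - 1L + findInterval(mids, xo)) %% 2L + 1L
  vals <- ifelse(active == 1L, hap_at(h1, mids), hap_at(h2, mids))
  chg <- which(vals[-1L] != vals[-length(vals)])
  list(breaks = breaks[chg], vals = vals[c(1L, chg + 1L)])
}

#' Simulate a mapping population from a founder fixture
#'
#' Gametes are drawn under Haldane's model (Poisson crossover counts, no
#' interference). BC1 offspring receive one F1 gamete and one recurrent
#' parent (founder 2) gamete; selfed RILs iterate selfing from the F1.
#' True genotypes at every SNP in the fixture's table are recorded.
#'
#' @param fixture A `genome_fixture`.
#' @param model A [population_model()].
#' @param seed Integer seed.
#' @return An object of class `cross_truth`: list with `individuals`
#'   (per-individual, per-chromosome haplotype mosaics), `geno` (integer
#'   matrix SNP x sample; 0 = hom founder-1, 1 = het, 2 = hom founder-2),
#'   `offspring`, `parents`, `model`, `fixture`.
#' @export
simulate_cross <- function(fixture, model, seed = 1) {
  stopifnot(inherits(fixture, "genome_fixture"), inherits(model, "population_model"))
  n_chr <- length(fixture$chromosomes)
  L <- fixture$chrom_cM
  f1 <- lapply(seq_len(n_chr), function(i) list(const_hap(1L), const_hap(2L)))
  inds <- withr::with_seed(seed, {
    lapply(seq_len(model$n_offspring), function(j) {
      if (model$kind == "BC1") {
        lapply(seq_len(n_chr), function(i) {
          list(gamete(f1[[i]][[1]], f1[[i]][[2]], L[i]), const_hap(2L))
        })
      } else {
        pair <- f1
        for (g in seq_len(model$generations - 1L)) {
          pair <- lapply(seq_len(n_chr), function(i) {
            list(gamete(pair[[i]][[1]], pair[[i]][[2]], L[i]),
                 gamete(pair[[i]][[1]], pair[[i]][[2]], L[i]))
          })
        }
        pair
      }
    })
  })
  ids <- sprintf("I%04d", seq_len(model$n_offspring))
  parents <- character(0)
  if (model$include_parents) {
    p1 <- lapply(seq_len(n_chr), function(i) list(const_hap(1L), const_hap(1L)))
    p2 <- lapply(seq_len(n_chr), function(i) list(const_hap(2L), const_hap(2L)))
    inds <- c(list(p1, p2), inds)
    parents <- c("P1", "P2")
    ids <- c(parents, ids)
  }
  names(inds) <- ids
  snp <- fixture$snp_table
  cm <- (snp$pos + 0.5) / fixture$chrom_bp * L[snp$chrom]
  geno <- vapply(inds, function(ind) {
    g <- integer(nrow(snp))
    for (i in seq_len(n_chr)) {
      sel <- snp$chrom == i
      g[sel] <- (hap_at(ind[[i]][[1]], cm[sel]) == 2L) +
                (hap_at(ind[[i]][[2]], cm[sel]) == 2L)
    }
    g
  }, integer(nrow(snp)))
  rownames(geno) <- snp$snp_id
  structure(list(individuals = inds, geno = geno,
                 offspring = setdiff(ids, parents), parents = parents,
                 model = model, fixture = fixture, seed = seed),
            class = "cross_truth")
}

#' True A/B/H matrix of a simulated cross
#'
#' Translates the simulator's truth genotypes directly into co-dominant
#' A/B/H codes (A = homozygous founder 1, B = homozygous founder 2,
#' H = heterozygous), bypassing sequencing. Useful as ground truth and for
#' genotype-level experiments such as error injection.
#'
#' @param cross A `cross_truth`.
#' @return An [abh_matrix()] including parent columns when simulated.
#' @export
truth_abh <- function(cross) {
  stopifnot(inherits(cross, "cross_truth"))
  codes <- c("A", "H", "B")
  m <- matrix(codes[cross$geno + 1L], nrow = nrow(cross$geno),
              dimnames = dimnames(cross$geno))
  parents <- if (length(cross$parents)) c(A = "P1", B = "P2") else NULL
  abh_matrix(m, parents = parents,
             poptype = if (cross$model$kind == "BC1") "bc1" else "ril")
}

#' @export
print.cross_truth <- function(x, ...) {
  cat(sprintf("<cross_truth> %s, %d offspring%s, %d SNPs (seed %d)\n",
              x$model$kind, length(x$offspring),
              if (length(x$parents)) " + 2 parents" else "",
              nrow(x$geno), x$seed))
  invisible(x)
}
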