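# Linkage-map construction from an A/B/H matrix: pairwise recombination
# fractions and LOD scores, shortest-path re-estimation of weak pairs,
# single-linkage grouping with anchored assignment of leftover markers,
# multi-start ordering with best-map selection on sum-of-adjacent-rf, and
# marker-order stability across the candidate orders.

#' Mapping configuration
#'
#' @param reestimate_threshold Pairs with rf above this are re-estimated
#'   through shortest paths over intermediate markers (default 0.4).
#' @param max_rf,min_lod Grouping edge criteria (default 0.4 / 4.0).
#' @param n_orders Candidate map orders per group (default 150).
#' @param anchor_margin Minimum rf gap between best and second-best group
#'   for unambiguous anchored assignment (default 0.05).
#' @param two_step Group on low-missingness markers first, then anchor the
#'   rest (for datasets with heavy missing data).
#' @param missing_primary,missing_ceiling Missingness split for the
#'   two-step mode: markers up to `missing_primary` build the groups,
#'   markers up to `missing_ceiling` are anchored (defaults 0.30 / 0.60).
#' @param seed Integer seed for order generation.
#' @return A `map_config` list.
#' @export
map_config <- function(reestimate_threshold = 0.4, max_rf = 0.4, min_lod = 4,
                       n_orders = 150, anchor_margin = 0.05,
                       two_step = FALSE, missing_primary = 0.30,
                       missing_ceiling = 0.60, seed = 1) {
  abort_if(reestimate_threshold <= 0 || reestimate_threshold >= 0.5,
           "`reestimate_threshold` must be in (0, 0.5)")
  abort_if(missing_primary > missing_ceiling,
           "`missing_primary` must be <= `missing_ceiling`")
  structure(list(reestimate_threshold = reestimate_threshold, max_rf = max_rf,
                 min_lod = min_lod, n_orders = n_orders,
                 anchor_margin = anchor_margin, two_step = two_step,
                 missing_primary = missing_primary,
                 missing_ceiling = missing_ceiling, seed = seed),
            class = "map_config")
}

RF_CAP <- 0.4999

# Numeric encoding for rf estimation. BC1: B = 0, H = 1; the
# pedigree-impossible A class carries no linkage information and is
# treated as missing. RIL: A = 0, B = 1; residual heterozygotes are
# phase-uninformative and treated as missing.
encode_abh <- function(abh, poptype = NULL) {
  poptype <- poptype %||% attr(abh, "poptype")
  m <- abh_codes(abh)
  enc <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (poptype == "bc1") {
    enc[m == "B"] <- 0; enc[m == "H"] <- 1
  } else {
    enc[m == "A"] <- 0; enc[m == "B"] <- 1
  }
  rownames(enc) <- abh$snp_id
  enc
}

rf_from_counts <- function(R, N, poptype) {
  Rhat <- ifelse(N > 0, R / N, 0.5)
  lod <- ifelse(N >= 2 & Rhat < 0.5,
                ifelse(R > 0, R * log10(pmin(Rhat, RF_CAP)), 0) +
                  ifelse(N - R > 0, (N - R) * log10(1 - pmin(Rhat, RF_CAP)), 0) -
                  N * log10(0.5),
                0)
  rf <- if (poptype == "bc1") Rhat else Rhat / pmax(2 * (1 - Rhat), 1e-9)
  rf <- pmin(rf, RF_CAP)
  rf[N < 2] <- 0.5
  list(rf = rf, lod = lod)
}

#' Pairwise recombination fraction and LOD for two markers
#'
#' Likelihood-based two-point estimate. BC1: informative pairs are jointly
#' non-missing B/H calls, rf is the discordant fraction (capped at
#' 0.4999), and LOD is the log10 likelihood ratio of the estimate against
#' independence (rf = 0.5). RIL: heterozygotes are treated as missing,
#' the observed discordance is corrected to a map rf by r = R/(2(1-R))
#' (inbred-by-selfing correction), and LOD is computed on the observed
#' discordance.
#'
#' @param g1,g2 A/B/H code vectors for the two markers.
#' @param poptype `"bc1"` or `"ril"`.
#' @return One-row tibble: `rf`, `lod`, `n_informative`, `reestimated`.
#' @export
pair_rf <- function(g1, g2, poptype = c("bc1", "ril")) {
  poptype <- match.arg(poptype)
  enc <- encode_abh(abh_matrix(rbind(g1, g2), poptype = poptype),
                    poptype = poptype)
  ok <- !is.na(enc[1, ]) & !is.na(enc[2, ])
  N <- sum(ok)
  R <- sum(enc[1, ok] != enc[2, ok])
  est <- rf_from_counts(R, N, poptype)
  tibble::tibble(rf = est$rf, lod = est$lod, n_informative = N,
                 reestimated = FALSE)
}

#' All-pairs recombination fractions and LOD scores
#'
#' @param abh An [abh_matrix()]. Parent columns (if recorded) are dropped:
#'   the parents are trivially concordant at every pair and carry no
#'   segregation information.
#' @param poptype Override the matrix's population type.
#' @return Object of class `rf_set`: list of symmetric matrices `rf`,
#'   `lod`, `n` (marker x marker), plus `reestimated` (logical).
#' @export
rf_matrix <- function(abh, poptype = NULL) {
  poptype <- poptype %||% attr(abh, "poptype")
  parents <- attr(abh, "parents")
  if (!is.null(parents)) {
    abh <- abh[setdiff(names(abh), unname(parents))]
  }
  enc <- encode_abh(abh, poptype)
  M0 <- (!is.na(enc) & enc == 0) * 1
  M1 <- (!is.na(enc) & enc == 1) * 1
  Mi <- M0 + M1
  N <- Mi %*% t(Mi)
  R <- M0 %*% t(M1) + M1 %*% t(M0)
  est <- rf_from_counts(R, N, poptype)
  rf <- matrix(est$rf, nrow(enc), dimnames = list(rownames(enc), rownames(enc)))
  lod <- matrix(est$lod, nrow(enc), dimnames = dimnames(rf))
  diag(rf) <- 0; diag(lod) <- 0
  structure(list(rf = rf, lod = lod, n = N,
                 reestimated = matrix(FALSE, nrow(enc), ncol = nrow(enc),
                                      dimnames = dimnames(rf)),
                 poptype = poptype),
            class = "rf_set")
}

#' Re-estimate weak recombination fractions through shortest paths
#'
#' Direct two-point rf estimates above `threshold` are unreliable (rf near
#' 0.5 barely distinguishes linkage from independence). Pairs connected by
#' chains of well-estimated intermediates are re-estimated: edges with
#' rf <= threshold are weighted by their Haldane map distance, the
#' shortest-path distance replaces the weak pair, and the result is mapped
#' back through the inverse Haldane function. Pairs with no path keep
#' rf = 0.5.
#'
#' @param rfs An `rf_set`.
#' @param threshold Re-estimation trigger (default 0.4).
#' @return The `rf_set` with updated `rf` and `reestimated` matrices.
#' @export
reestimate_long <- function(rfs, threshold = 0.4) {
  stopifnot(inherits(rfs, "rf_set"))
  rf <- rfs$rf
  n <- nrow(rf)
  idx <- which(upper.tri(rf) & rf <= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$weight <- haldane_cM(rf[idx])
  }
  D <- igraph::distances(g)
  weak <- upper.tri(rf) & rf > threshold
  new_rf <- rf
  new_rf[weak] <- ifelse(is.finite(D[weak]), inv_haldane(D[weak]), 0.5)
  new_rf[lower.tri(new_rf)] <- t(new_rf)[lower.tri(new_rf)]
  re <- rfs$reestimated
  re[weak] <- is.finite(D[weak])
  re[lower.tri(re)] <- t(re)[lower.tri(re)]
  rfs$rf <- new_rf
  rfs$reestimated <- re
  rfs
}

#' Assign markers to linkage groups
#'
#' Single-linkage connected components over edges with rf <= `max_rf` and
#' LOD >= `min_lod`; singleton components are reported as ungrouped. The
#' partition is evaluated at `min_lod` and one LOD unit either side, and
#' the threshold maximizing mean within-group LOD is kept (a simple
#' merge/split optimization of the initial groups).
#'
#' @param rfs An `rf_set` (after [reestimate_long()] if desired).
#' @param max_rf,min_lod Edge criteria.
#' @param optimize_lod Evaluate `min_lod` +/- 1 and keep the best
#'   partition (default TRUE).
#' @return List with `groups` (named list of marker-id vectors, largest
#'   first), `ungrouped` (character), `min_lod_used`.
#' @export
group_markers <- function(rfs, max_rf = 0.4, min_lod = 4, optimize_lod = TRUE) {
  stopifnot(inherits(rfs, "rf_set"))
  markers <- rownames(rfs$rf)
  partition_at <- function(th) {
    adj <- (rfs$rf <= max_rf & rfs$lod >= th) * 1
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    split(markers, comp)
  }
  score <- function(parts) {
    lods <- unlist(lapply(parts, function(ms) {
      if (length(ms) < 2L) return(NULL)
      sub <- rfs$lod[ms, ms]
      sub[upper.tri(sub)]
    }))
    if (is.null(lods)) -Inf else mean(lods)
  }
  cands <- if (optimize_lod) unique(pmax(min_lod + c(-1, 0, 1), 0)) else min_lod
  parts_list <- lapply(cands, partition_at)
  best <- which.max(vapply(parts_list, score, numeric(1)))
  parts <- parts_list[[best]]
  sizes <- lengths(parts)
  groups <- parts[sizes >= 2L]
  groups <- groups[order(-lengths(groups))]
  names(groups) <- sprintf("LG%d", seq_along(groups))
  list(groups = groups,
       ungrouped = unlist(parts[sizes == 1L], use.names = FALSE) %||% character(0),
       min_lod_used = cands[best])
}

#' Anchor leftover markers to existing groups
#'
#' Each ungrouped marker is assigned to the group holding its minimum-rf
#' partner, provided that best rf is within `max_rf` and beats the
#' second-best group by at least `margin` (otherwise the assignment is
#' ambiguous and the marker stays ungrouped).
#'
#' @param groups Named list of marker-id vectors (the anchors).
#' @param ungrouped Character vector of markers to place.
#' @param rfs An `rf_set` covering all markers involved.
#' @param max_rf Maximum rf for assignment.
#' @param margin Required gap between best and second-best group rf.
#' @return List with augmented `groups` and remaining `ungrouped`.
#' @export
anchor_assign <- function(groups, ungrouped, rfs, max_rf = 0.4, margin = 0.05) {
  abort_if(!length(groups), "`groups` must be non-empty")
  for (mk in ungrouped) {
    best_rf <- vapply(groups, function(ms) min(rfs$rf[mk, ms]), numeric(1))
    o <- order(best_rf)
    second <- if (length(groups) > 1L) best_rf[o[2]] else Inf
    if (best_rf[o[1]] <= max_rf && (second - best_rf[o[1]]) >= margin) {
      groups[[o[1]]] <- c(groups[[o[1]]], mk)
      ungrouped <- setdiff(ungrouped, mk)
    }
  }
  list(groups = groups, ungrouped = ungrouped)
}

sarf <- function(ord, rf) sum(rf[cbind(ord[-length(ord)], ord[-1])])

greedy_chain <- function(start, rf, randomize = FALSE) {
  n <- nrow(rf)
  ord <- integer(n)
  ord[1] <- start
  left <- rep(TRUE, n)
  left[start] <- FALSE
  for (i in seq_len(n - 1L)) {
    d <- rf[ord[i], ]
    d[!left] <- Inf
    nxt <- if (randomize && sum(left) > 1L) {
      top <- order(d)[1:2]
      top[sample.int(2L, 1L, prob = c(0.8, 0.2))]
    } else {
      which.min(d)
    }
    ord[i + 1L] <- nxt
    left[nxt] <- FALSE
  }
  ord
}

# 2-opt local search minimizing sum of adjacent rf along the path.
two_opt <- function(ord, rf) {
  n <- length(ord)
  if (n < 4L) return(ord)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  repeat {
    prev <- ifelse(i > 1L, ord[pmax(i - 1L, 1L)], NA)
    nxt <- ifelse(j < n, ord[pmin(j + 1L, n)], NA)
    d_new <- ifelse(is.na(prev), 0, rf[cbind(prev, ord[j])]) +
      ifelse(is.na(nxt), 0, rf[cbind(ord[i], nxt)])
    d_old <- ifelse(is.na(prev), 0, rf[cbind(prev, ord[i])]) +
      ifelse(is.na(nxt), 0, rf[cbind(ord[j], nxt)])
    delta <- d_new - d_old
    k <- which.min(delta)
    if (delta[k] > -1e-12) break
    ord[i[k]:j[k]] <- rev(ord[i[k]:j[k]])
  }
  ord
}

#' Order the markers of one linkage group
#'
#' Generates `n_orders` candidate orders by seeded multi-start greedy
#' nearest-neighbor chaining, each refined by 2-opt local search
#' minimizing the sum of adjacent recombination fractions (SARF). The best
#' map is the candidate with minimal SARF, ties broken by maximal sum of
#' adjacent LOD scores; orientation is normalized so the first marker id
#' sorts before the last.
#'
#' @param members Marker ids of the group.
#' @param rfs An `rf_set`.
#' @param n_orders Number of candidate orders (default 150).
#' @param seed Integer seed.
#' @return Object of class `map_order`: list with `order` (marker ids),
#'   `sarf`, `salod`, `candidates` (list of candidate id vectors),
#'   `stability` (named per-marker stability in \[0, 1\]).
#' @export
order_group <- function(members, rfs, n_orders = 150, seed = 1) {
  n <- length(members)
  rf <- rfs$rf[members, members, drop = FALSE]
  lod <- rfs$lod[members, members, drop = FALSE]
  if (n <= 2L) {
    ord <- sort(members)
    return(structure(list(order = ord, sarf = if (n == 2L) rf[1, 2] else 0,
                          salod = if (n == 2L) lod[1, 2] else 0,
                          candidates = list(ord),
                          stability = stats::setNames(rep(1, n), ord)),
                     class = "map_order"))
  }
  dimnames(rf) <- dimnames(lod) <- list(NULL, NULL)
  cands <- withr::with_seed(seed, {
    lapply(seq_len(n_orders), function(k) {
      start <- (k - 1L) %% n + 1L
      ord <- greedy_chain(start, rf, randomize = k > n)
      ord <- two_opt(ord, rf)
      if (members[ord[1]] > members[ord[n]]) ord <- rev(ord)
      ord
    })
  })
  sarfs <- vapply(cands, sarf, numeric(1), rf = rf)
  salods <- vapply(cands, sarf, numeric(1), rf = lod)
  best_k <- order(sarfs, -salods)[1]
  best <- cands[[best_k]]
  stab <- order_stability(lapply(cands, function(o) members[o]), members[best])
  structure(list(order = members[best], sarf = sarfs[best_k],
                 salod = salods[best_k],
                 candidates = lapply(cands, function(o) members[o]),
                 stability = stab),
            class = "map_order")
}

#' Per-marker stability across candidate orders
#'
#' The fraction of candidate orders in which a marker's rank differs from
#' its rank in the best map by at most one position. Near 1 everywhere
#' means the selected order is stable; local drops flag co-segregating or
#' conflicting markers.
#'
#' @param candidates List of candidate orders (marker-id vectors).
#' @param best The selected best order.
#' @return Named numeric vector of stabilities in \[0, 1\].
#' @export
order_stability <- function(candidates, best) {
  abort_if(length(candidates) < 2L, "need at least 2 candidate orders")
  rank_best <- match(best, best)
  ranks <- vapply(candidates, function(o) match(best, o), numeric(length(best)))
  stats::setNames(rowMeans(abs(ranks - rank_best) <= 1), best)
}

#' Cumulative cM positions along an ordered group
#'
#' Position 0 at the first marker; each step adds the Haldane map distance
#' of the adjacent pair's recombination fraction.
#'
#' @param order Marker ids in map order.
#' @param rfs An `rf_set`.
#' @return Tibble with `marker`, `position` (cM, non-decreasing).
#' @export
map_positions <- function(order, rfs) {
  if (length(order) == 1L) {
    return(tibble::tibble(marker = order, position = 0))
  }
  adj <- rfs$rf[cbind(order[-length(order)], order[-1])]
  tibble::tibble(marker = order, position = c(0, cumsum(haldane_cM(adj))))
}

#' Construct a linkage map from an A/B/H matrix
#'
#' Runs the full mapping pipeline: pairwise rf/LOD estimation,
#' shortest-path re-estimation of weak pairs, single-linkage grouping
#' (optionally two-step: group on low-missingness markers, anchor the
#' rest), per-group ordering with best-map selection, cM positioning, and
#' stability analysis.
#'
#' @param abh An [abh_matrix()].
#' @param config A [map_config()].
#' @return Object of class `sbg_map`: list with `markers` (tibble
#'   `marker`, `group`, `position`, `stability`, `anchored`), `groups`,
#'   `ungrouped`, `orders` (per-group `map_order`s), `rfs`, `config`.
#' @export
linkage_map <- function(abh, config = map_config()) {
  stopifnot(inherits(abh, "abh_matrix"))
  abort_if(nrow(abh) < 2L, "need at least 2 markers to build a map")
  m <- abh_codes(abh)
  miss <- rowMeans(is.na(m))
  names(miss) <- abh$snp_id
  usable <- abh$snp_id[miss <= config$missing_ceiling]
  abh_use <- abh[match(usable, abh$snp_id), ]
  abh_use <- abh_matrix(abh_use, parents = attr(abh, "parents"),
                        poptype = attr(abh, "poptype"))
  rfs <- rf_matrix(abh_use)
  rfs <- reestimate_long(rfs, config$reestimate_threshold)
  if (config$two_step) {
    primary <- usable[miss[usable] <= config$missing_primary]
    sub <- rfs
    sub$rf <- rfs$rf[primary, primary]
    sub$lod <- rfs$lod[primary, primary]
    grp <- group_markers(sub, config$max_rf, config$min_lod)
    to_place <- c(grp$ungrouped, setdiff(usable, primary))
  } else {
    grp <- group_markers(rfs, config$max_rf, config$min_lod)
    to_place <- grp$ungrouped
  }
  if (!length(grp$groups)) {
    warning("no linkage groups formed at the current rf/LOD criteria",
            call. = FALSE)
    return(structure(list(
      markers = tibble::tibble(marker = character(0), group = character(0),
                               position = numeric(0), stability = numeric(0),
                               anchored = logical(0)),
      groups = list(), ungrouped = usable, orders = list(), rfs = rfs,
      config = config), class = "sbg_map"))
  }
  anc <- anchor_assign(grp$groups, to_place, rfs, config$max_rf,
                       config$anchor_margin)
  orders <- lapply(anc$groups, order_group, rfs = rfs,
                   n_orders = config$n_orders, seed = config$seed)
  markers <- purrr::imap_dfr(orders, function(o, gname) {
    pos <- map_positions(o$order, rfs)
    dplyr::mutate(pos, group = gname, stability = o$stability[.data$marker],
                  anchored = FALSE)
  })
  anchored_set <- setdiff(unlist(anc$groups), unlist(grp$groups))
  markers$anchored <- markers$marker %in% anchored_set
  structure(list(markers = markers[c("marker", "group", "position",
                                     "stability", "anchored")],
                 groups = anc$groups, ungrouped = anc$ungrouped,
                 orders = orders, rfs = rfs, config = config),
            class = "sbg_map")
}

#' @exportS3Method generics::tidy
tidy.sbg_map <- function(x, ...) x$markers

#' Per-group summary of a linkage map
#'
#' @param x An `sbg_map`.
#' @param ... Unused.
#' @return Tibble with one row per linkage group: marker count, map length
#'   in cM, mean stability, plus the count of unplaced markers as an
#'   attribute.
#' @exportS3Method generics::glance
glance.sbg_map <- function(x, ...) {
  if (!nrow(x$markers)) {
    out <- tibble::tibble(group = character(0), n_markers = integer(0),
                          length_cM = numeric(0), mean_stability = numeric(0))
    attr(out, "n_ungrouped") <- length(x$ungrouped)
    return(out)
  }
  out <- x$markers |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     length_cM = max(.data$position),
                     mean_stability = mean(.data$stability))
  attr(out, "n_ungrouped") <- length(x$ungrouped)
  out
}

#' @export
print.sbg_map <- function(x, ...) {
  g <- glance.sbg_map(x)
  cat(sprintf("<sbg_map> %d linkage groups, %d markers mapped, %d ungrouped\n",
              nrow(g), nrow(x$markers), length(x$ungrouped)))
  print(g)
  invisible(x)
}
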