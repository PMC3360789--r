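rf_set_of <- function(rf, lod = NULL) {
  n <- nrow(rf)
  ids <- rownames(rf) %||% sprintf("M%02d", seq_len(n))
  dimnames(rf) <- list(ids, ids)
  if (is.null(lod)) { lod <- 10 * (0.5 - rf); diag(lod) <- 0 }
  dimnames(lod) <- dimnames(rf)
  structure(list(rf = rf, lod = lod,
                 n = matrix(100, n, n, dimnames = dimnames(rf)),
                 reestimated = matrix(FALSE, n, n, dimnames = dimnames(rf)),
                 poptype = "bc1"),
            class = "rf_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("two-point BC1 estimates match the closed-form likelihood", {
  pr <- pair_rf(c("B", "B", "H", "H", "B"), c("B", "H", "H", "H", "B"), "bc1")
  expect_equal(pr$rf, 0.2)
  expect_equal(pr$n_informative, 5L)
  expect_equal(pr$lod, log10(0.2 * 0.8^4 / 0.5^5), tolerance = 1e-6)
  # perfect cosegregation
  same <- pair_rf(rep(c("B", "H"), 5), rep(c("B", "H"), 5), "bc1")
  expect_equal(same$rf, 0)
  expect_equal(same$lod, 10 * log10(2), tolerance = 1e-6)
  # A calls are uninformative in BC1 and drop out of N
  with_a <- pair_rf(c("A", "B", "H"), c("B", "B", "H"), "bc1")
  expect_equal(with_a$n_informative, 2L)
  # too few informative pairs
  weak <- pair_rf(c("B", NA, NA), c("B", NA, NA), "bc1")
  expect_equal(weak$rf, 0.5)
  expect_equal(weak$lod, 0)
})

test_that("RIL estimates apply the inbred-by-selfing correction", {
  # 2 discordant of 6 informative: observed R = 1/3 -> map rf = 0.25
  g1 <- c("A", "A", "A", "B", "B", "B", "H")
  g2 <- c("A", "A", "B", "A", "B", "B", "A")
  pr <- pair_rf(g1, g2, "ril")
  expect_equal(pr$n_informative, 6L)  # H treated as missing
  expect_equal(pr$rf, (1 / 3) / (2 * (1 - 1 / 3)), tolerance = 1e-9)
  # discordance 0.5 -> unlinked, LOD 0
  un <- pair_rf(c("A", "B", "A", "B"), c("A", "A", "B", "B"), "ril")
  expect_equal(un$rf, 0.4999)
  expect_equal(un$lod, 0)
})

test_that("the all-pairs rf matrix agrees with pair_rf", {
  run <- mini_run()
  abh <- run$filtered$abh
  rfs <- rf_matrix(abh)
  m <- abh_codes(abh)[, setdiff(abh_samples(abh), c("P1", "P2"))]
  set.seed(3)
  for (k in 1:15) {
    ij <- sample(nrow(m), 2)
    pr <- pair_rf(m[ij[1], ], m[ij[2], ], "bc1")
    expect_equal(rfs$rf[ij[1], ij[2]], pr$rf)
    expect_equal(rfs$lod[ij[1], ij[2]], pr$lod, tolerance = 1e-9)
    expect_equal(rfs$n[ij[1], ij[2]], pr$n_informative)
  }
  expect_true(isSymmetric(rfs$rf))
  expect_true(all(rfs$rf >= 0 & rfs$rf <= 0.5))
})

test_that("weak pairs are re-estimated through Haldane-additive chains", {
  rf <- matrix(c(0, 0.2, 0.45,
                 0.2, 0, 0.2,
                 0.45, 0.2, 0), 3, byrow = TRUE)
  rfs <- rf_set_of(rf)
  out <- reestimate_long(rfs, threshold = 0.4)
  d <- -50 * log(1 - 2 * 0.2)
  expected <- 0.5 * (1 - exp(-2 * (2 * d) / 100))
  expect_equal(out$rf[1, 3], expected, tolerance = 1e-9)
  expect_true(out$reestimated[1, 3])
  expect_equal(out$rf[1, 2], 0.2)  # below threshold: unchanged
  # all pairs below threshold: matrix unchanged
  rf2 <- matrix(c(0, 0.1, 0.1, 0, 0, 0.1, 0.1, 0.1, 0), 3)
  rf2 <- (rf2 + t(rf2)) / 2; diag(rf2) <- 0
  out2 <- reestimate_long(rf_set_of(rf2), 0.4)
  expect_equal(out2$rf, rf_set_of(rf2)$rf)
  # disconnected components keep rf 0.5
  rf3 <- matrix(0.5, 4, 4); diag(rf3) <- 0
  rf3[1, 2] <- rf3[2, 1] <- 0.05
  rf3[3, 4] <- rf3[4, 3] <- 0.05
  out3 <- reestimate_long(rf_set_of(rf3), 0.4)
  expect_equal(out3$rf[1, 3], 0.5)
  expect_false(out3$reestimated[1, 3])
})

test_that("grouping forms single-linkage components under both criteria", {
  rf <- matrix(0.5, 5, 5); diag(rf) <- 0
  rf[1, 2] <- rf[2, 1] <- 0.01
  rf[2, 3] <- rf[3, 2] <- 0.05
  rf[4, 5] <- rf[5, 4] <- 0.02
  rfs <- rf_set_of(rf)
  grp <- group_markers(rfs, max_rf = 0.4, min_lod = 3, optimize_lod = FALSE)
  expect_equal(lengths(grp$groups), c(LG1 = 3L, LG2 = 2L))
  expect_equal(length(grp$ungrouped), 0L)
  # an infinite LOD requirement leaves every marker ungrouped
  none <- group_markers(rfs, max_rf = 0.4, min_lod = Inf, optimize_lod = FALSE)
  expect_equal(length(none$groups), 0L)
  expect_equal(length(none$ungrouped), 5L)
})

test_that("anchored assignment demands an unambiguous best group", {
  rf <- matrix(0.5, 6, 6); diag(rf) <- 0
  ids <- sprintf("M%02d", 1:6)
  dimnames(rf) <- list(ids, ids)
  rf["M01", "M02"] <- rf["M02", "M01"] <- 0.01
  rf["M03", "M04"] <- rf["M04", "M03"] <- 0.01
  # M05: rf 0.05 to group 1, 0.48 to group 2 -> assigned
  rf["M05", c("M01", "M02")] <- rf[c("M01", "M02"), "M05"] <- 0.05
  rf["M05", c("M03", "M04")] <- rf[c("M03", "M04"), "M05"] <- 0.48
  # M06: 0.30 vs 0.33 with margin 0.1 -> ambiguous
  rf["M06", c("M01", "M02")] <- rf[c("M01", "M02"), "M06"] <- 0.30
  rf["M06", c("M03", "M04")] <- rf[c("M03", "M04"), "M06"] <- 0.33
  rfs <- rf_set_of(rf)
  groups <- list(LG1 = c("M01", "M02"), LG2 = c("M03", "M04"))
  res <- anchor_assign(groups, c("M05", "M06"), rfs, max_rf = 0.4, margin = 0.1)
  expect_true("M05" %in% res$groups$LG1)
  expect_equal(res$ungrouped, "M06")
  expect_error(anchor_assign(list(), "M05", rfs), "non-empty")
})

test_that("ordering recovers the chain and matches exhaustive optima", {
  # 3-marker chain
  rf <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.1, 0.2, 0.1, 0), 3, byrow = TRUE)
  ids <- c("a", "b", "c")
  dimnames(rf) <- list(ids, ids)
  rfs <- rf_set_of(rf)
  ord <- order_group(ids, rfs, n_orders = 10, seed = 1)
  expect_equal(ord$order, c("a", "b", "c"))  # orientation-normalized
  expect_equal(ord$sarf, 0.2)
  # group of 2 and singleton
  expect_equal(order_group(c("b", "a"), rfs, seed = 1)$order, c("a", "b"))
  expect_equal(order_group("a", rfs, seed = 1)$order, "a")
  # exhaustive-permutation oracle for random matrices up to size 8
  sarf_of <- function(perm, rf) sum(rf[cbind(perm[-length(perm)], perm[-1])])
  for (n in c(4, 6, 8)) {
    for (rep in 1:3) {
      set.seed(n * 10 + rep)
      sym <- matrix(stats::runif(n * n, 0.01, 0.5), n)
      sym <- (sym + t(sym)) / 2; diag(sym) <- 0
      ids <- sprintf("M%d", seq_len(n))
      dimnames(sym) <- list(ids, ids)
      rfs_n <- rf_set_of(sym)
      got <- order_group(ids, rfs_n, n_orders = 60, seed = rep)
      perms <- gtools_perms(n)
      best <- min(apply(perms, 1, sarf_of, rf = sym))
      expect_equal(got$sarf, best, tolerance = 1e-9)
    }
  }
})

test_that("cM positions accumulate Haldane distances", {
  rf <- matrix(c(0, 0.2, 0.5, 0.2, 0, 0.2, 0.5, 0.2, 0), 3, byrow = TRUE)
  ids <- c("a", "b", "c"); dimnames(rf) <- list(ids, ids)
  rfs <- rf_set_of(rf)
  pos <- map_positions(c("a", "b"), rfs)
  expect_equal(pos$position, c(0, -50 * log(0.6)), tolerance = 1e-9)
  expect_equal(map_positions("a", rfs)$position, 0)
  # rf 0 adds no distance
  rf0 <- rf; rf0[1, 2] <- rf0[2, 1] <- 0
  expect_equal(map_positions(c("a", "b"), rf_set_of(rf0))$position[2], 0)
})

test_that("stability is 1 for identical candidates and ~3/n for shuffled markers", {
  best <- sprintf("M%02d", 1:20)
  all_same <- order_stability(rep(list(best), 50), best)
  expect_true(all(all_same == 1))
  set.seed(4)
  shuffled <- lapply(1:400, function(i) sample(best))
  st <- order_stability(shuffled, best)
  # interior markers: expected 3/20; allow binomial noise
  expect_lt(abs(mean(st) - 3 / 20), 0.03)
  expect_error(order_stability(list(best), best), "at least 2")
})

test_that("the full mapping pipeline recovers simulated chromosomes", {
  run <- mini_run()
  expect_false(is.null(run$map))
  g <- glance(run$map)
  expect_equal(nrow(g), 2L)  # two simulated chromosomes
  markers <- run$map$markers
  expect_gt(min(g$mean_stability), 0.5)
  expect_true(all(markers$position >= 0))
  # chromosome purity: markers of one group come from one true chromosome
  truth <- map_sites_to_truth(run)
  joined <- dplyr::inner_join(markers, truth,
                              by = c("marker" = "site_id"))
  purity <- vapply(split(joined$chrom, joined$group), function(ch) {
    max(table(ch)) / length(ch)
  }, numeric(1))
  expect_gte(min(purity), 0.99)
})
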