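random_dist <- function(n, scale = 1) {
  m <- matrix(runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("i", 1:n), paste0("i", 1:n))
  m
}

test_that("Mantel r is exact under perfect linear dependence", {
  set.seed(61)
  geo <- random_dist(10)
  gen <- 2.5 * geo
  res <- mantel_test(geo, gen, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)
  expect_error(mantel_test(geo, gen[1:9, 1:9]), "same isolates|square")
  expect_error(mantel_test(geo * 0, gen), "constant")
})

test_that("sampled Mantel p agrees with exhaustive 4! enumeration", {
  set.seed(62)
  for (rep in 1:3) {
    geo <- random_dist(4)
    gen <- random_dist(4)
    exact <- mantel_exact_oracle(geo, gen)
    res <- mantel_test(geo, gen, n_perm = 4999, seed = rep)
    tol <- 3 * sqrt(exact * (1 - exact) / 4999) + 1 / 4999
    expect_lt(abs(res$p - exact), tol + 1e-12)
  }
})

test_that("Mantel r is invariant under common relabeling and reproducible", {
  set.seed(63)
  geo <- random_dist(8)
  gen <- random_dist(8)
  r1 <- mantel_test(geo, gen, n_perm = 99, seed = 5)
  pm <- sample(8)
  r2 <- mantel_test(geo[pm, pm], gen[pm, pm], n_perm = 99, seed = 5)
  expect_equal(r1$r, r2$r)
  expect_identical(mantel_test(geo, gen, n_perm = 99, seed = 9)$p,
                   mantel_test(geo, gen, n_perm = 99, seed = 9)$p)
})

test_that("Mantel r equals the vegan implementation on the same matrices", {
  skip_if_not_installed("vegan")
  set.seed(64)
  geo <- random_dist(12)
  gen <- random_dist(12)
  res <- mantel_test(geo, gen, n_perm = 99, seed = 2)
  vg <- vegan::mantel(as.dist(geo), as.dist(gen), permutations = 99)
  expect_equal(res$r, unname(vg$statistic), tolerance = 1e-12)
})

test_that("per-scale mean distances equal brute-force averages", {
  sheet <- make_sheet(2, 2, 2, 2, 2)[1:10, ]
  set.seed(65)
  seqs <- random_seqs(10, 40)
  names(seqs) <- sheet$isolate_id
  d <- genetic_distances(seqs)
  curve <- scale_distance_curve(d, sheet, order = 1)
  for (k in seq_along(kinscape:::SCALE_LEVELS)) {
    sc <- kinscape:::SCALE_LEVELS[k]
    tot <- c()
    for (i in 1:9) for (j in (i + 1):10) {
      if (as.character(pair_scale(sheet$isolate_id[i],
                                  sheet$isolate_id[j])) == sc) {
        tot <- c(tot, d[i, j])
      }
    }
    if (length(tot)) {
      expect_equal(curve$means$mean_distance[k], mean(tot))
      expect_equal(curve$means$n_pairs[k], length(tot))
    } else {
      expect_true(is.na(curve$means$mean_distance[k]))
    }
  }

  # identical sequences: flat zero curve (full two-site design, all scales)
  full <- make_sheet(2, 2, 2, 2, 2)
  same <- setNames(rep(strrep("A", 30), nrow(full)), full$isolate_id)
  d0 <- genetic_distances(same)
  expect_equal(scale_distance_curve(d0, full)$means$mean_distance,
               rep(0, 5))

  # single-site design: kilometre scale has no pairs and is flagged NA
  sheet1 <- make_sheet(1, 2, 2, 2, 2)[1:8, ]
  seqs1 <- setNames(random_seqs(8, 40), sheet1$isolate_id)
  cv <- scale_distance_curve(genetic_distances(seqs1), sheet1, order = 1)
  expect_equal(cv$means$n_pairs[5], 0L)
  expect_true(is.na(cv$means$mean_distance[5]))
})

test_that("clade-restricted curves only use within-clade pairs", {
  sheet <- make_sheet(2, 2, 1, 2, 2)
  set.seed(66)
  seqs <- setNames(random_seqs(nrow(sheet), 40), sheet$isolate_id)
  d <- genetic_distances(seqs)
  clades <- setNames(rep(c(1, 2), length.out = nrow(sheet)),
                     sheet$isolate_id)
  cl <- scale_distance_curve(d, sheet, scope = "clade", clades = clades,
                             clade = 1, order = 1)
  ids <- names(clades)[clades == 1]
  tot <- 0; cnt <- 0
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    if (as.character(pair_scale(ids[i], ids[j])) == "kilometre") {
      tot <- tot + d[ids[i], ids[j]]; cnt <- cnt + 1
    }
  }
  expect_equal(cl$means$mean_distance[5], tot / cnt)
})

test_that("exact binomial clade tests match direct mass summation", {
  # clade at pooled frequency 0.5, absent from a 3-isolate site: p = 1/8
  sheet <- sample_sheet_from_ids(c("GH1.1.1A", "GH1.1.1B", "GH1.1.2A",
                                   "KF1.1.1A", "KF1.1.1B", "KF1.1.2A"))
  clades <- setNames(c("X", "X", "X", "Y", "Y", "Y"), sheet$isolate_id)
  res <- clade_absence_test(clades, sheet, "X", "KF")
  expect_equal(res$p, 0.125)
  expect_equal(res$observed, 0L)

  # f = 0.2, n = 10, observed 0: p = 0.8^10
  ids10 <- paste0("KF1.1.", 1:10, "A")
  sheet2 <- sample_sheet_from_ids(c(paste0("GH1.1.", 1:40, "A"), ids10))
  clades2 <- setNames(c(rep("X", 10), rep("Y", 30), rep("Y", 10)),
                      sheet2$isolate_id)
  res2 <- clade_absence_test(clades2, sheet2, "X", "KF")
  expect_equal(res2$p, 0.8^10, tolerance = 1e-12)
  expect_equal(res2$p, binom_tail_oracle(0, 10, 0.2), tolerance = 1e-12)

  # observation at the expectation keeps most of the lower tail
  clades3 <- clades2
  clades3[ids10[1:2]] <- "X"
  res3 <- clade_absence_test(clades3, sheet2, "X", "KF")
  expect_gt(res3$p, 0.5)
  expect_equal(res3$p, binom_tail_oracle(res3$observed, 10, res3$f),
               tolerance = 1e-12)
  expect_error(clade_absence_test(clades, sheet, "Z", "KF"), "absent")
})

test_that("two-clade frequency tests are exact and two-sided", {
  ids <- c(paste0("GH1.1.", 1:10, "A"), paste0("KF1.1.", 1:10, "A"))
  sheet <- sample_sheet_from_ids(ids)
  # perfectly balanced: site exactly at the pooled proportion
  clades <- setNames(rep(c("C1", "C2"), 10), sheet$isolate_id)
  expect_equal(clade_frequency_test(clades, sheet, "GH", c("C1", "C2"))$p, 1)
  # all-or-nothing site at pooled proportion 0.5: p = 2 * 0.5^10
  clades2 <- setNames(c(rep("C1", 10), rep("C2", 10)), sheet$isolate_id)
  res <- clade_frequency_test(clades2, sheet, "GH", c("C1", "C2"))
  expect_equal(res$p, 2 * 0.5^10, tolerance = 1e-12)
})

test_that("nearest-ST pairing matches exhaustive scan and detects structure", {
  d <- matrix(c(0, 1, 5, 6,
                1, 0, 5, 6,
                5, 5, 0, 2,
                6, 6, 2, 0), 4, 4,
              dimnames = list(paste0("st", 1:4), paste0("st", 1:4)))
  sites <- list(st1 = "GH", st2 = "GH", st3 = "KF", st4 = "KF")
  res <- nearest_st_concordance(d, sites, seed = 1)
  expect_equal(res$pairings$nearest, c("st2", "st1", "st4", "st3"))
  expect_equal(res$observed, 1)
  # analytic expectation: 2 co-sited pairs of the 6 distinct ST pairs
  expect_equal(res$expected, 2 / 6)
  expect_lt(res$p, 0.15)

  # all STs at one site: concordance is forced and uninformative
  sites1 <- list(st1 = "GH", st2 = "GH", st3 = "GH", st4 = "GH")
  res1 <- nearest_st_concordance(d, sites1, seed = 1)
  expect_equal(res1$observed, 1)
  expect_equal(res1$expected, 1)
  expect_equal(res1$p, 1)

  # site-private clusters across more STs: observed > expected, small p
  set.seed(67)
  n <- 12
  centers <- rep(c(0, 10, 20), each = 4)
  dd <- abs(outer(centers + runif(n, 0, 1), centers + runif(n, 0, 1), "-"))
  dd <- (dd + t(dd)) / 2
  diag(dd) <- 0
  dimnames(dd) <- list(paste0("st", 1:n), paste0("st", 1:n))
  sites2 <- setNames(as.list(rep(c("GH", "KF", "MC"), each = 4)),
                     paste0("st", 1:n))
  res2 <- nearest_st_concordance(dd, sites2, seed = 2)
  expect_gt(res2$observed, res2$expected)
  expect_lt(res2$p, 0.01)
})

test_that("within- vs among-site Wilcoxon has exact small-sample behaviour", {
  # 5 STs at GH, 4 at KF: plenty of within and among pairs
  d <- random_dist(9)
  dimnames(d) <- list(paste0("st", 1:9), paste0("st", 1:9))
  clades <- setNames(rep("C1", 9), paste0("st", 1:9))
  sites <- setNames(as.list(rep(c("GH", "KF"), c(5, 4))), paste0("st", 1:9))

  # complete separation: among all larger than within gives the minimal
  # exact two-sided p for 4 vs 4, namely 2 / C(8,4)
  dsep <- d
  within_mask <- outer(1:9, 1:9, function(i, j)
    (i <= 5 & j <= 5) | (i > 5 & j > 5))
  dsep[within_mask] <- dsep[within_mask] / 100
  diag(dsep) <- 0
  res <- within_vs_among_site_test(dsep, clades, sites, "C1", n_draws = 4,
                                   seed = 3)
  expect_equal(res$p, 2 / choose(8, 4), tolerance = 1e-12)

  # exact p equals enumeration of all C(8,4) rank splits
  set.seed(68)
  res2 <- within_vs_among_site_test(d, clades, sites, "C1", n_draws = 4,
                                    seed = 4)
  expect_equal(res2$p, wilcoxon_exact_oracle(res2$within, res2$among),
               tolerance = 1e-10)

  expect_error(within_vs_among_site_test(d, clades, sites, "C1",
                                         n_draws = 50, seed = 1),
               "insufficient")
})

test_that("geographic distances reflect scale categories", {
  sheet <- make_sheet(2, 2, 1, 2, 2)
  g <- geographic_distances(sheet)
  expect_equal(g["GH1.1.1A", "GH1.1.1B"], 3.3e-5)
  expect_equal(g["GH1.1.1A", "GH1.1.2A"], 0.003)
  expect_equal(g["GH1.1.1A", "GH2.1.1A"], 18)
  expect_equal(g["GH1.1.1A", "KF1.1.1A"], 11000)
  expect_equal(g, t(g))
})
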