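toy_alignments <- function() {
  list(
    locus_1 = c(i1 = "ACGTACGTAC", i2 = "ACGTACGTAT", i3 = "ACGTACGTAC"),
    locus_2 = c(i1 = "GGGCC", i2 = "GGGCC", i3 = "GGACC")
  )
}

test_that("concatemer length is the sum of locus alignment lengths", {
  cc <- concatenate_loci(toy_alignments())
  expect_equal(unname(nchar(cc)), rep(15L, 3))
  expect_equal(attr(cc, "locus_lengths"),
               c(locus_1 = 10L, locus_2 = 5L))
  expect_identical(unname(cc["i1"]), "ACGTACGTACGGGCC")
})

test_that("isolates missing a locus and ragged alignments are rejected", {
  aln <- toy_alignments()
  aln$locus_2 <- aln$locus_2[c("i1", "i2")]
  expect_error(concatenate_loci(aln), "locus_2: i3")
  expect_silent(locus_alignment_set(aln, intersect_isolates = TRUE))
  aln2 <- toy_alignments()
  aln2$locus_1["i2"] <- "ACGT"
  expect_error(concatenate_loci(aln2), "ragged")
  aln3 <- toy_alignments()
  aln3$locus_1["i2"] <- "ACGTACGTAX"
  expect_error(concatenate_loci(aln3), "outside")
})

test_that("sequence types partition by exact identity, in order of first use", {
  st <- assign_sequence_types(c(a = "AAA", b = "AAA", c = "AAT"))
  expect_equal(unname(st$st), c(1L, 1L, 2L))
  expect_equal(st$n_st, 2L)
  expect_error(assign_sequence_types(character(0)), "no concatemers")

  # reorder invariance: the induced partition is identical up to relabeling,
  # and matches a brute-force sort-and-group oracle
  set.seed(11)
  seqs <- random_seqs(20, 6, alphabet = c("A", "C"))
  st1 <- assign_sequence_types(seqs)$st
  ord <- sample(20)
  st2 <- assign_sequence_types(seqs[ord])$st[names(seqs)]
  expect_true(all(outer(st1, st1, "==") == outer(st2, st2, "==")))
  canon <- function(g) {
    g <- lapply(g, sort)
    unname(g[order(vapply(g, `[[`, character(1), 1L))])
  }
  expect_identical(canon(split(names(seqs), unname(seqs))),
                   canon(split(names(st1), st1)))
})

test_that("nucleotide diversity matches hand values and the brute-force oracle", {
  expect_equal(nucleotide_diversity(c(a = "AAAA", b = "AAAA", c = "AAAA"))$pi, 0)
  expect_equal(nucleotide_diversity(c(a = "AAAA", b = "AAAT"))$pi, 0.25)
  expect_error(nucleotide_diversity(c(a = "AAAA")), "at least 2")
  expect_error(nucleotide_diversity(c(a = "NNNN", b = "AAAA", c = "AAAA")),
               "no comparable sites.*a vs")

  set.seed(3)
  for (rep in 1:5) {
    seqs <- random_seqs(5, 40, alphabet = c("A", "C", "G", "T", "N", "-"))
    expect_equal(nucleotide_diversity(seqs)$pi, pi_oracle(seqs))
  }
})

test_that("pairwise distances match closed-form oracles for every model", {
  expect_equal(pairwise_distance("ACGT", "ACGT", "p"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGT", "JC69"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGT", "K2P"), 0)

  # p = 0.1 under JC69: closed form -0.75 log(1 - 0.4/3)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  expect_equal(pairwise_distance(a, b, "p"), 0.1)
  expect_equal(pairwise_distance(a, b, "JC69"), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-10)

  # A<->C is a transversion: a transversion-only pair exercises the K2P
  # two-parameter limit, checked against independent formula evaluation
  expect_equal(pairwise_distance(a, b, "K2P"), k2p_oracle(a, b),
               tolerance = 1e-10)
  set.seed(5)
  for (rep in 1:5) {
    # moderately diverged pair: mutate 15% of sites so corrections stay defined
    s1 <- strsplit(random_seqs(1, 200)[[1]], "")[[1]]
    s2 <- s1
    pos <- sample(200, 30)
    s2[pos] <- vapply(s2[pos], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    x <- c(paste(s1, collapse = ""), paste(s2, collapse = ""))
    expect_equal(pairwise_distance(x[[1]], x[[2]], "p"),
                 p_dist_oracle(x[[1]], x[[2]]), tolerance = 1e-10)
    expect_equal(pairwise_distance(x[[1]], x[[2]], "K2P"),
                 k2p_oracle(x[[1]], x[[2]]), tolerance = 1e-10)
    # JC69 inflates p over its whole valid range
    p <- p_dist_oracle(x[[1]], x[[2]])
    expect_gt(pairwise_distance(x[[1]], x[[2]], "JC69"), p)
  }
})

test_that("saturated JC69 distances follow the configured policy", {
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(rep("C", 20), collapse = "")  # p = 1 >= 0.75
  expect_error(pairwise_distance(a, b, "JC69"), "saturated")
  expect_identical(pairwise_distance(a, b, "JC69", saturated = "inf"), Inf)
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(9)
  anc <- strsplit(random_seqs(1, 60)[[1]], "")[[1]]
  seqs <- vapply(1:6, function(i) {
    x <- anc
    pos <- sample(60, 8)
    x[pos] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:6)
  for (model in c("p", "JC69", "K2P")) {
    d <- genetic_distances(seqs, model = model)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_true(all(d >= 0))
  }
})

test_that("diversity table mirrors per-group recomputation and edge cases", {
  sheet <- make_sheet(2, 2, 1, 2, 2)
  set.seed(21)
  concat <- random_seqs(nrow(sheet), 30)
  names(concat) <- sheet$isolate_id
  tab <- diversity_table(sheet, concat)

  overall <- tab[tab$level == "overall", ]
  expect_equal(overall$n, nrow(sheet))
  expect_equal(overall$pi, nucleotide_diversity(concat)$pi)
  expect_equal(overall$st_count, assign_sequence_types(concat)$n_st)

  # consistency under slicing: any group row equals recomputation on the subset
  row <- tab[tab$level == "core" & tab$group == "GH1.1", ]
  ids <- sheet$isolate_id[sheet$site == "GH" & sheet$transect == 1 &
                            sheet$core == 1]
  expect_equal(row$n, length(ids))
  expect_equal(row$pi, nucleotide_diversity(concat[ids])$pi)

  # monomorphic group: one ST and zero diversity
  concat2 <- concat
  concat2[ids] <- concat2[ids[1]]
  tab2 <- diversity_table(sheet, concat2)
  row2 <- tab2[tab2$level == "core" & tab2$group == "GH1.1", ]
  expect_equal(row2$st_count, 1L)
  expect_equal(row2$pi, 0)

  # n < 2 groups report NA diversity but keep counts
  sheet1 <- sample_sheet_from_ids(c("GH1.1.1A", "GH1.1.2A", "KF1.1.1A"))
  tab3 <- diversity_table(sheet1, c(GH1.1.1A = "AC", GH1.1.2A = "AG",
                                    KF1.1.1A = "AT"))
  kf_fb <- tab3[tab3$level == "fruiting_body" & tab3$group == "KF1.1.1", ]
  expect_equal(kf_fb$n, 1L)
  expect_true(is.na(kf_fb$pi))
})
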