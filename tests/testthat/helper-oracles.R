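# Fixture builders and independent brute-force oracles used across tests.

# Fully factorial sample sheet: every clone of every fruiting body present.
make_sheet <- function(n_sites = 2, n_transects = 2, n_cores = 2, n_fbs = 2,
                       n_clones = 2, sites = NULL) {
  if (is.null(sites)) sites <- c("GH", "KF", "MC", "ZZ")[seq_len(n_sites)]
  ids <- character(0)
  for (s in sites) for (t in seq_len(n_transects))
    for (co in seq_len(n_cores)) for (f in seq_len(n_fbs))
      ids <- c(ids, paste0(s, t, ".", co, ".", f, LETTERS[seq_len(n_clones)]))
  sample_sheet_from_ids(ids)
}

random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T"),
                        names_prefix = "s") {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0(names_prefix, seq_len(n))
  seqs
}

# Exhaustive double-loop nucleotide diversity with pairwise deletion.
pi_oracle <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  n <- nrow(m)
  tot <- 0
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    tot <- tot + sum(m[i, ok] != m[j, ok]) / sum(ok)
    cnt <- cnt + 1
  }
  tot / cnt
}

# Proportion of mismatches over comparable sites for one pair.
p_dist_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  mean(x[ok] != y[ok])
}

# Kimura two-parameter distance from transition/transversion proportions.
k2p_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  purine <- c("A", "G")
  ti <- mean(x != y & (x %in% purine) == (y %in% purine))
  tv <- mean(x != y & (x %in% purine) != (y %in% purine))
  -0.5 * log(1 - 2 * ti - tv) - 0.25 * log(1 - 2 * tv)
}

# Maximum number of mutually disjoint pairs of a given scale, by exhaustive
# branch-and-bound over isolates (feasible for <= 12 isolates).
max_pairs_oracle <- function(sheet, scale) {
  n <- nrow(sheet)
  pairs <- utils::combn(n, 2)
  keep <- vapply(seq_len(ncol(pairs)), function(k) {
    as.character(pair_scale(sheet[pairs[1, k], , drop = FALSE],
                            sheet[pairs[2, k], , drop = FALSE])) == scale
  }, logical(1))
  pairs <- pairs[, keep, drop = FALSE]
  best <- 0
  recurse <- function(avail, count) {
    best <<- max(best, count)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (avail[i] && avail[j]) {
        avail2 <- avail
        avail2[c(i, j)] <- FALSE
        recurse(avail2, count + 1)
      }
    }
  }
  recurse(rep(TRUE, n), 0)
  best
}

# Exact Mantel permutation p over all n! relabelings (two-sided on |r|).
mantel_exact_oracle <- function(geo, gen) {
  n <- nrow(geo)
  ut <- upper.tri(geo)
  r_obs <- cor(geo[ut], gen[ut])
  perms <- kinscape:::all_permutations(n)
  rs <- apply(perms, 1, function(p) cor(geo[ut], gen[p, p][ut]))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Definitional one-way ANOVA + equal-n Tukey HSD from first principles.
anova_tukey_oracle <- function(values, groups) {
  k <- length(unique(groups))
  n <- length(values) / k
  gm <- tapply(values, groups, mean)
  msb <- n * sum((gm - mean(values))^2) / (k - 1)
  msw <- sum((values - gm[groups])^2) / (length(values) - k)
  f <- msb / msw
  df <- length(values) - k
  cmb <- utils::combn(names(gm), 2)
  p_adj <- apply(cmb, 2, function(pr) {
    q <- abs(gm[pr[1]] - gm[pr[2]]) / sqrt(msw / n)
    1 - stats::ptukey(q, k, df)
  })
  list(f = f, p = 1 - stats::pf(f, k - 1, df),
       tukey = data.frame(i = cmb[1, ], j = cmb[2, ], p_adj = p_adj))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all C(n1+n2, n1)
# assignments of ranks to the first sample.
wilcoxon_exact_oracle <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  splits <- utils::combn(length(all_v), length(x))
  ws <- apply(splits, 2, function(i)
    sum(r[i]) - length(x) * (length(x) + 1) / 2)
  mu <- length(x) * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Lower-tail exact binomial probability by direct mass summation.
binom_tail_oracle <- function(obs, n, p) {
  sum(vapply(0:obs, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

# Pair set with prescribed per-scale identity counts: 3 replicates x 4
# pairs per scale; `genetic` / `social` give identical-pair counts out of 12.
counted_pairs <- function(genetic, social) {
  rows <- list()
  st <- integer(0)
  kd <- list()
  n <- 0
  for (k in seq_along(kinscape:::SCALE_LEVELS)) {
    sc <- kinscape:::SCALE_LEVELS[k]
    for (i in 1:12) {
      n <- n + 1
      a <- sprintf("GH%d.%d.%d%s", k, i, 1, "A")
      b <- switch(sc,
        micrometre = sprintf("GH%d.%d.%d%s", k, i, 1, "B"),
        millimetre = sprintf("GH%d.%d.%d%s", k, i, 2, "A"),
        centimetre = sprintf("GH%d.%d.%d%s", k, i + 20, 1, "A"),
        metre = sprintf("GH%d.%d.%d%s", k + 10, i, 1, "A"),
        kilometre = sprintf("KF%d.%d.%d%s", k, i, 1, "A"))
      rows[[length(rows) + 1]] <- data.frame(
        replicate = ((i - 1) %/% 4) + 1, scale = sc,
        isolate_a = a, isolate_b = b)
      same_st <- i <= genetic[k]
      st[a] <- n * 2
      st[b] <- if (same_st) n * 2 else n * 2 + 1
      kd[[length(kd) + 1]] <- data.frame(
        isolate_a = a, isolate_b = b,
        obs1 = as.integer(i > social[k]), obs2 = as.integer(i > social[k]),
        obs3 = as.integer(i > social[k]))
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$scale <- factor(pairs$scale, levels = kinscape:::SCALE_LEVELS,
                        ordered = TRUE)
  list(pairs = pairs, st = st, kd = do.call(rbind, kd))
}
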