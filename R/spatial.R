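check_square_dist <- function(m, what = "distance matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(what, " must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop(what, " must carry identical row and column names")
  }
  if (any(abs(diag(m)) > 1e-12)) stop(what, " must have a zero diagonal")
  if (any(abs(m - t(m)) > 1e-10)) stop(what, " must be symmetric")
  invisible(TRUE)
}

#' Mantel permutation test of matrix correlation
#'
#' Tests for isolation by distance: the Pearson correlation `r` between the
#' off-diagonal upper-triangle entries of a geographic and a genetic
#' distance matrix, with significance from simultaneous row/column
#' permutations of one matrix. The two-sided permutation p-value uses the
#' add-one estimator `(#{|r_perm| >= |r_obs|} + 1) / (n_perm + 1)`. A
#' parametric alternative (t-test on r over the n(n-1)/2 pairs) is
#' available for comparison but ignores the non-independence of pairwise
#' distances.
#'
#' @param geo,genetic Symmetric zero-diagonal matrices over the same
#'   isolates in the same order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param method `"permutation"` (default) or `"parametric"`.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `n`, `method`.
#' @export
mantel_test <- function(geo, genetic, n_perm = 9999L, seed = NULL,
                        method = c("permutation", "parametric")) {
  method <- match.arg(method)
  check_square_dist(geo, "geographic matrix")
  check_square_dist(genetic, "genetic matrix")
  if (!identical(dim(geo), dim(genetic)) ||
      !identical(rownames(geo), rownames(genetic))) {
    stop("matrices must be over the same isolates in the same order")
  }
  n <- nrow(geo)
  ut <- upper.tri(geo)
  x <- geo[ut]
  y <- genetic[ut]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant matrix: Mantel correlation undefined")
  }
  r_obs <- stats::cor(x, y)
  if (method == "parametric") {
    m <- length(x)
    tstat <- r_obs * sqrt(m - 2) / sqrt(1 - r_obs^2)
    p <- 2 * stats::pt(-abs(tstat), df = m - 2)
    res <- list(r = r_obs, p = p, n_perm = NA_integer_, n = n,
                method = method)
    class(res) <- "mantel_result"
    return(res)
  }
  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      r_perm <- stats::cor(x, genetic[pm, pm][ut])
      if (abs(r_perm) >= abs(r_obs) - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  res <- list(r = r_obs, p = p, n_perm = n_perm, n = n, method = method)
  class(res) <- "mantel_result"
  res
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (n = %d%s)\n",
              x$method, x$r, x$p, x$n,
              if (is.na(x$n_perm)) "" else
                sprintf(", %d permutations", x$n_perm)))
  invisible(x)
}

#' Geographic distance matrix from the nested design
#'
#' Pairwise distances between isolates are the representative metric
#' distance of their spatial-scale category (see [scale_distance()]).
#'
#' @param sheet Sample sheet.
#' @param geometry A [scale_geometry()].
#' @param log10 Return log10 distances (often used for plotting/fits);
#'   default FALSE.
#' @return Symmetric matrix of distances in metres, isolates as dimnames.
#' @export
geographic_distances <- function(sheet, geometry = scale_geometry(),
                                 log10 = FALSE) {
  n <- nrow(sheet)
  m <- matrix(0, n, n, dimnames = list(sheet$isolate_id, sheet$isolate_id))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  sc <- pair_scale(sheet[idx[, 1L], , drop = FALSE],
                   sheet[idx[, 2L], , drop = FALSE])
  d <- scale_distance(sc, geometry)
  if (log10) d <- log10(d)
  m[upper.tri(m)] <- d
  m <- m + t(m)
  m
}

#' Mean pairwise genetic distance by spatial scale, with a fitted trend
#'
#' For each scale category, the mean genetic distance over all qualifying
#' isolate pairs (every pair, not an independent subsample), either for the
#' whole data set or restricted to pairs within one phylogenetic clade. A
#' least-squares polynomial (order 1 or 2) in log10 representative distance
#' is fitted through the per-scale means.
#'
#' @param distances Genetic distance matrix over isolates
#'   ([genetic_distances()]).
#' @param sheet Sample sheet covering the matrix isolates.
#' @param scope `"overall"` or `"clade"`.
#' @param clades Named vector isolate -> clade label (required for
#'   `scope = "clade"`).
#' @param clade Focal clade label for `scope = "clade"`.
#' @param order Polynomial order of the fit (1 or 2).
#' @param geometry A [scale_geometry()] giving representative distances.
#' @return List with `means` (data frame: scale, distance_m, n_pairs,
#'   mean_distance; scales with no qualifying pair are kept with `NA` and
#'   excluded from the fit), `fit_coef` (polynomial coefficients,
#'   increasing order) and `scope`.
#' @export
scale_distance_curve <- function(distances, sheet,
                                 scope = c("overall", "clade"),
                                 clades = NULL, clade = NULL, order = 2L,
                                 geometry = scale_geometry()) {
  scope <- match.arg(scope)
  stopifnot(order %in% c(1L, 2L))
  check_square_dist(distances, "genetic matrix")
  sheet <- sheet[match(rownames(distances), sheet$isolate_id), , drop = FALSE]
  if (anyNA(sheet$isolate_id)) stop("distance matrix has isolates absent from sheet")
  keep <- rep(TRUE, nrow(sheet))
  if (scope == "clade") {
    if (is.null(clades) || is.null(clade)) {
      stop("scope = \"clade\" needs `clades` and `clade`")
    }
    keep <- clades[sheet$isolate_id] == clade
    if (sum(keep, na.rm = TRUE) < 2L) stop("fewer than 2 isolates in clade ", clade)
    keep[is.na(keep)] <- FALSE
  }
  sub <- sheet[keep, , drop = FALSE]
  dm <- distances[sub$isolate_id, sub$isolate_id, drop = FALSE]
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  sc <- pair_scale(sub[idx[, 1L], , drop = FALSE],
                   sub[idx[, 2L], , drop = FALSE])
  vals <- dm[upper.tri(dm)]
  means <- data.frame(
    scale = scale_factor(SCALE_LEVELS),
    distance_m = scale_distance(SCALE_LEVELS, geometry),
    n_pairs = as.integer(tabulate(sc, nbins = 5L)),
    mean_distance = as.numeric(tapply(vals, sc, mean)[SCALE_LEVELS])
  )
  have <- means$n_pairs > 0L
  fit_coef <- NULL
  if (sum(have) >= order + 1L) {
    lx <- log10(means$distance_m[have])
    fit <- stats::lm(means$mean_distance[have] ~ stats::poly(lx, order,
                                                             raw = TRUE))
    fit_coef <- unname(stats::coef(fit))
  }
  list(means = means, fit_coef = fit_coef, scope = scope,
       clade = if (scope == "clade") clade else NA, order = order)
}

#' Exact binomial test for a clade's absence (or deficit) at a site
#'
#' With the clade's frequency `f` estimated from all sites pooled, the
#' probability of observing at most the observed number of clade members
#' among the focal site's `n` isolates if membership were binomial at rate
#' `f` (lower-tail exact binomial probability).
#'
#' @param clades Named vector isolate -> clade label.
#' @param sheet Sample sheet.
#' @param clade Focal clade label.
#' @param site Focal site label.
#' @return List: `p`, `observed`, `n`, `f`.
#' @export
clade_absence_test <- function(clades, sheet, clade, site) {
  cl <- clades[sheet$isolate_id]
  if (anyNA(cl)) stop("isolate(s) without clade assignment")
  f <- mean(cl == clade)
  if (f == 0) stop("clade ", clade, " absent from the pooled sample: ",
                   "expected frequency undefined")
  at_site <- sheet$site == site
  if (!any(at_site)) stop("no isolates at site ", site)
  n <- sum(at_site)
  observed <- sum(cl[at_site] == clade)
  list(p = stats::pbinom(observed, n, f), observed = observed, n = n, f = f)
}

#' Exact binomial test of two clades' frequency split at a site
#'
#' Compares the focal site's counts of two clades with the split expected
#' from the pooled (all-site) frequencies of those clades, by a two-sided
#' exact binomial test.
#'
#' @param clades Named vector isolate -> clade label.
#' @param sheet Sample sheet.
#' @param site Focal site label.
#' @param clade_pair Length-2 vector of clade labels.
#' @return List: `p`, `observed` (count of the first clade at the site),
#'   `n` (site count of both clades), `expected_prop`.
#' @export
clade_frequency_test <- function(clades, sheet, site, clade_pair) {
  stopifnot(length(clade_pair) == 2L)
  cl <- clades[sheet$isolate_id]
  pooled <- c(sum(cl == clade_pair[1L]), sum(cl == clade_pair[2L]))
  if (any(pooled == 0)) stop("clade(s) absent from the pooled sample")
  p0 <- pooled[1L] / sum(pooled)
  at_site <- sheet$site == site
  x <- sum(cl[at_site] == clade_pair[1L])
  n <- x + sum(cl[at_site] == clade_pair[2L])
  if (n == 0L) stop("site ", site, " has no members of either focal clade")
  list(p = stats::binom.test(x, n, p0, alternative = "two.sided")$p.value,
       observed = x, n = n, expected_prop = p0)
}

#' Co-site concordance of phylogenetically nearest sequence types
#'
#' Pairs every sequence type (ST) with its genetically nearest distinct ST
#' (ties broken uniformly at random under `seed`) and asks how often the
#' two members of a pairing co-occur at a kilometre-scale site. Under no
#' spatial structure the expected concordance is the probability that two
#' distinct STs drawn at random share a site, computed analytically from
#' the site ST lists; a label-permutation expectation is reported alongside
#' it. Significance is an exact binomial test of the observed concordant
#' count against the analytic expectation.
#'
#' @param st_dist Symmetric distance matrix over distinct STs (dimnames are
#'   ST labels).
#' @param st_sites Named list: ST label -> character vector of site(s)
#'   where the ST occurs.
#' @param seed Integer seed (tie-breaking and the permutation expectation).
#' @param alternative `"greater"` (default; spatial clustering inflates
#'   concordance) or `"two.sided"`.
#' @param n_perm Permutations for the permutation expectation (0 to skip).
#' @return List: `observed` (fraction), `expected` (analytic),
#'   `expected_perm`, `p`, `pairings` (data frame st, nearest, co_sited).
#' @export
nearest_st_concordance <- function(st_dist, st_sites, seed = NULL,
                                   alternative = c("greater", "two.sided"),
                                   n_perm = 999L) {
  alternative <- match.arg(alternative)
  check_square_dist(st_dist, "ST distance matrix")
  sts <- rownames(st_dist)
  if (length(sts) < 2L) stop("need at least 2 distinct STs")
  missing <- setdiff(sts, names(st_sites))
  if (length(missing)) stop("ST(s) without site map: ",
                            paste(missing, collapse = ", "))
  share_site <- function(a, b) length(intersect(st_sites[[a]], st_sites[[b]])) > 0L
  with_seed(seed, {
    nearest <- vapply(sts, function(s) {
      d <- st_dist[s, setdiff(sts, s)]
      sample_from(names(d)[d == min(d)])
    }, character(1))
    co <- mapply(share_site, sts, nearest)
    # analytic no-structure expectation: P(two random distinct STs co-sited)
    pairs_idx <- utils::combn(sts, 2L)
    expected <- mean(apply(pairs_idx, 2L, function(p) share_site(p[1L], p[2L])))
    expected_perm <- NA_real_
    if (n_perm > 0L) {
      expected_perm <- mean(vapply(seq_len(n_perm), function(b) {
        shuf <- st_sites[sample.int(length(sts))]
        names(shuf) <- sts
        mean(mapply(function(a, b2)
          length(intersect(shuf[[a]], shuf[[b2]])) > 0L, sts, nearest))
      }, numeric(1)))
    }
    p <- if (expected >= 1) {
      1
    } else {
      stats::binom.test(sum(co), length(sts), expected,
                        alternative = alternative)$p.value
    }
    list(observed = mean(co), expected = expected,
         expected_perm = expected_perm, p = p,
         pairings = data.frame(st = sts, nearest = nearest,
                               co_sited = unname(co)))
  })
}

#' Within- vs among-site genetic distances by constrained resampling
#'
#' Draws `n_draws` within-site and `n_draws` among-site pairwise distances
#' between distinct sequence types of one clade, never reusing an ST pair,
#' and compares the two samples with a two-sided Wilcoxon rank-sum test
#' (exact null when sample sizes permit and there are no ties; normal
#' approximation with tie correction otherwise, as in
#' [stats::wilcox.test()]).
#'
#' @param st_dist Symmetric distance matrix over distinct STs.
#' @param st_clades Named vector ST -> clade label.
#' @param st_sites Named list ST -> site(s) of occurrence (an ST pair is
#'   within-site if the two STs share a site).
#' @param clade Focal clade label.
#' @param n_draws Distances per group (the analysis used 50, 30 or 15
#'   depending on clade size).
#' @param seed Integer seed.
#' @return List: `w`, `p`, `within`, `among` (the drawn distances),
#'   `capacity` (available within/among ST-pair counts).
#' @export
within_vs_among_site_test <- function(st_dist, st_clades, st_sites, clade,
                                      n_draws, seed = NULL) {
  check_square_dist(st_dist, "ST distance matrix")
  sts <- rownames(st_dist)
  members <- sts[st_clades[sts] == clade & !is.na(st_clades[sts])]
  if (length(members) < 2L) stop("fewer than 2 STs in clade ", clade)
  prs <- utils::combn(members, 2L)
  within <- apply(prs, 2L, function(p)
    length(intersect(st_sites[[p[1L]]], st_sites[[p[2L]]])) > 0L)
  capacity <- c(within = sum(within), among = sum(!within))
  if (any(capacity < n_draws)) {
    stop("insufficient distinct ST pairs for clade ", clade, ": available ",
         "within-site ", capacity["within"], ", among-site ",
         capacity["among"], ", requested ", n_draws, " each")
  }
  d <- st_dist[t(prs)]
  dim(d) <- NULL
  with_seed(seed, {
    wi <- sample_from(d[within], n_draws)
    am <- sample_from(d[!within], n_draws)
    wt <- suppressWarnings(stats::wilcox.test(wi, am,
                                              alternative = "two.sided"))
    list(w = unname(wt$statistic), p = wt$p.value, within = wi, among = am,
         capacity = capacity)
  })
}

#' Sequence-type site map and representative distances
#'
#' Helpers linking STs to the kilometre-scale sites where they occur and
#' building an ST-level distance matrix by taking each ST's representative
#' concatemer.
#'
#' @param sheet Sample sheet.
#' @param st Named vector isolate -> ST label.
#' @return `st_site_map()`: named list ST -> sites. `st_distances()`:
#'   distance matrix over ST labels.
#' @export
st_site_map <- function(sheet, st) {
  st <- st[sheet$isolate_id]
  lapply(split(sheet$site, as.character(st)), unique)
}

#' @rdname st_site_map
#' @param concatemers Named concatemer vector.
#' @inheritParams genetic_distances
#' @export
st_distances <- function(concatemers, st, model = "p",
                         site_handling = "pairwise") {
  reps <- names(st)[!duplicated(st)]
  seqs <- concatemers[reps]
  names(seqs) <- as.character(st[reps])
  genetic_distances(seqs, model = model, site_handling = site_handling)
}
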