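build_identity_curve <- function(pairs, identical, kind) {
  stopifnot(length(identical) == nrow(pairs), all(identical %in% c(0, 1)))
  reps <- stats::aggregate(identical,
                           by = list(scale = pairs$scale,
                                     replicate = pairs$replicate),
                           FUN = function(x) c(n = length(x), p = mean(x)))
  replicates <- data.frame(scale = reps$scale, replicate = reps$replicate,
                           n_pairs = reps$x[, "n"], proportion = reps$x[, "p"])
  replicates <- replicates[order(replicates$scale, replicates$replicate), ]
  rownames(replicates) <- NULL
  pooled <- stats::aggregate(identical, by = list(scale = pairs$scale), mean)
  sds <- stats::aggregate(proportion ~ scale, replicates, stats::sd)
  summary <- data.frame(scale = pooled$scale, pooled = pooled$x,
                        sd = sds$proportion[match(pooled$scale, sds$scale)])
  summary <- summary[order(summary$scale), ]
  rownames(summary) <- NULL
  structure(list(kind = kind, replicates = replicates, summary = summary),
            class = "identity_curve")
}

#' @export
print.identity_curve <- function(x, ...) {
  cat(sprintf("%s identity-decay curve (%d replicates per scale)\n",
              x$kind, max(x$replicates$replicate)))
  print(x$summary, ...)
  invisible(x)
}

#' Per-scale probability of genetic identity
#'
#' For each replicate and scale of an independent pair set, the proportion
#' of pairs whose two isolates share a sequence type (genetic identity),
#' plus the pooled proportion and across-replicate standard deviation per
#' scale. This is the genetic identity-decay curve: the probability that
#' two randomly sampled isolates separated by a given scale are genetically
#' identical.
#'
#' @param pairs A `pair_set` from [sample_independent_pairs()].
#' @param st Named integer vector isolate -> sequence type, as in
#'   [assign_sequence_types()]`$st`.
#' @return An `identity_curve` object: list with `kind`, `replicates`
#'   (scale, replicate, n_pairs, proportion) and `summary` (scale, pooled,
#'   sd).
#' @export
genetic_identity_curve <- function(pairs, st) {
  ids <- c(pairs$isolate_a, pairs$isolate_b)
  missing <- setdiff(ids, names(st))
  if (length(missing)) {
    stop("no sequence type for isolate(s): ", paste(missing, collapse = ", "))
  }
  same <- as.integer(st[pairs$isolate_a] == st[pairs$isolate_b])
  build_identity_curve(pairs, same, "genetic")
}

#' Per-scale probability of social identity
#'
#' As [genetic_identity_curve()], but identity means membership in the same
#' social allotype: no kin-discrimination phenotype at the colony interface
#' (see [score_kd()]).
#'
#' @param pairs A `pair_set`.
#' @param kd Scored kin-discrimination table ([score_kd()]) covering every
#'   pair, or a pair set already carrying a `social_identity` column.
#' @return An `identity_curve` object.
#' @export
social_identity_curve <- function(pairs, kd = NULL) {
  if (!"social_identity" %in% names(pairs)) {
    if (is.null(kd)) stop("supply scored kin-discrimination records")
    pairs <- social_identity(pairs, kd)
  }
  build_identity_curve(pairs, pairs$social_identity, "social")
}

#' One-way ANOVA with Tukey HSD contrasts across scales
#'
#' Tests whether replicate-level identity proportions differ among spatial
#' scales: a one-way ANOVA on the replicate proportions grouped by scale,
#' followed by Tukey's honestly-significant-difference contrasts between
#' every pair of scales (studentized-range adjustment, Tukey-Kramer when
#' replicates are unbalanced). The unit of analysis is the replicate
#' proportion, not the individual pair.
#'
#' @param curve An `identity_curve`.
#' @return List with `f` and `p` (ANOVA), `tukey` (data frame: scale_i,
#'   scale_j, mean_diff, p_adj) and `exact_separation` (TRUE when every
#'   scale has zero within-scale variance while means differ, in which case
#'   F is undefined and `f`/`p` are NA).
#' @export
anova_tukey <- function(curve) {
  d <- curve$replicates
  lev <- intersect(SCALE_LEVELS, unique(as.character(d$scale)))
  d$scale <- factor(as.character(d$scale), levels = lev)
  if (length(lev) < 2L) stop("need >= 2 scales")
  if (min(table(d$scale)) < 2L) stop("need >= 2 replicates per scale")
  within_var <- stats::aggregate(proportion ~ scale, d, stats::var)$proportion
  if (all(within_var == 0)) {
    means <- stats::aggregate(proportion ~ scale, d, mean)$proportion
    if (stats::var(means) > 0) {
      return(list(f = NA_real_, p = NA_real_, tukey = NULL,
                  exact_separation = TRUE))
    }
    # all observations identical everywhere: no differences at all
    tk <- expand.grid(j = levels(d$scale), i = levels(d$scale))
    tk <- tk[as.integer(tk$i) < as.integer(tk$j), c("i", "j")]
    return(list(f = 0, p = 1,
                tukey = data.frame(scale_i = tk$i, scale_j = tk$j,
                                   mean_diff = 0, p_adj = 1),
                exact_separation = FALSE))
  }
  fit <- stats::aov(proportion ~ scale, data = d)
  an <- summary(fit)[[1L]]
  hsd <- stats::TukeyHSD(fit)$scale
  nm <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tukey <- data.frame(
    scale_i = vapply(nm, `[`, character(1), 2L),
    scale_j = vapply(nm, `[`, character(1), 1L),
    mean_diff = -hsd[, "diff"],
    p_adj = hsd[, "p adj"]
  )
  rownames(tukey) <- NULL
  list(f = an[["F value"]][1L], p = an[["Pr(>F)"]][1L], tukey = tukey,
       exact_separation = FALSE)
}

#' Correlation between genetic and social identity-decay curves
#'
#' Pearson correlation of the five pooled per-scale proportions of the two
#' curves. The optional significance is either the exhaustive permutation
#' test over all 5! = 120 orderings of one curve (two-sided on |r|) or the
#' parametric t-test on `r` with n-2 degrees of freedom.
#'
#' @param genetic,social `identity_curve` objects over the same scales.
#' @param p_method `"none"`, `"permutation"` or `"t"`.
#' @return List with `r`, `p` (NA when `p_method = "none"`) and `method`.
#'   `r` is NA with a warning when either curve has zero variance.
#' @export
curve_correlation <- function(genetic, social,
                              p_method = c("none", "permutation", "t")) {
  p_method <- match.arg(p_method)
  g <- genetic$summary
  s <- social$summary
  if (!identical(as.character(g$scale), as.character(s$scale))) {
    stop("curves are not over the same scales")
  }
  x <- g$pooled
  y <- s$pooled
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance in a curve: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, method = p_method))
  }
  r <- stats::cor(x, y)
  p <- NA_real_
  if (p_method == "permutation") {
    perms <- all_permutations(length(x))
    rs <- apply(perms, 1L, function(pm) stats::cor(x[pm], y))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else if (p_method == "t") {
    n <- length(x)
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, method = p_method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Write identity-curve tables
#'
#' Replicate-level TSV (`scale`, `replicate`, `n_pairs`, `proportion`) and,
#' alongside it, a `*_summary.tsv` with the pooled proportions and
#' across-replicate standard deviations.
#'
#' @param curve An `identity_curve`.
#' @param path Path of the replicate-level TSV.
#' @export
write_identity_curve <- function(curve, path) {
  utils::write.table(curve$replicates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spath <- sub("(\\.[^.]*)?$", "_summary\\1", path)
  utils::write.table(curve$summary, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
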