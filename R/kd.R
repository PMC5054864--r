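#' Majority call over an odd panel of binary observer scores
#'
#' Each observer scores a colony-encounter assay 1 if the interface between
#' the two colonies is visibly altered relative to self-self control
#' interfaces (a kin-discrimination phenotype) and 0 if the colonies merge
#' freely. An odd panel guarantees a strict majority.
#'
#' @param scores Binary vector (0/1) of odd length.
#' @return List with `call` (0/1 majority) and `unanimous` (logical).
#' @export
#' @examples
#' majority_call(c(1, 1, 0))  # call 1, not unanimous
majority_call <- function(scores) {
  if (length(scores) %% 2L == 0L) {
    stop("even number of observers (", length(scores),
         "): majority is undefined; use an odd panel")
  }
  if (!all(scores %in% c(0, 1))) stop("scores must be binary 0/1")
  list(call = as.integer(sum(scores) > length(scores) / 2),
       unanimous = length(unique(scores)) == 1L)
}

#' Score a kin-discrimination assay table by observer majority
#'
#' Adds `majority`, `unanimous` and `social_identity` columns to a table of
#' per-pair observer scores. Social identity is the complement of the
#' majority call: two isolates belong to the same social allotype exactly
#' when no kin-discrimination phenotype is seen at their interface.
#' Self-self control rows (`isolate_a == isolate_b`) must have majority 0;
#' scoring is defined relative to those control interfaces.
#'
#' @param kd Data frame with columns `isolate_a`, `isolate_b` and an odd
#'   number of observer columns `obs1`, `obs2`, ... (binary).
#' @return The input with `majority`, `unanimous`, `social_identity` added.
#' @export
score_kd <- function(kd) {
  obs_cols <- grep("^obs[0-9]+$", names(kd), value = TRUE)
  if (length(obs_cols) < 1L) stop("no observer columns (obs1, obs2, ...)")
  if (length(obs_cols) %% 2L == 0L) {
    stop("even number of observer columns (", length(obs_cols),
         "): majority is undefined")
  }
  m <- as.matrix(kd[, obs_cols, drop = FALSE])
  if (!all(m %in% c(0, 1))) stop("observer scores must be binary 0/1")
  kd$majority <- as.integer(rowSums(m) > length(obs_cols) / 2)
  kd$unanimous <- rowSums(m) %in% c(0L, length(obs_cols))
  control <- kd$isolate_a == kd$isolate_b
  if (any(control & kd$majority == 1L)) {
    stop("self-self control(s) scored as kin discrimination: ",
         paste(kd$isolate_a[control & kd$majority == 1L], collapse = ", "))
  }
  kd$social_identity <- 1L - kd$majority
  kd
}

#' Attach social-identity labels to a pair set
#'
#' Looks up each pair of a [sample_independent_pairs()] pair set in a
#' scored kin-discrimination table (order of `isolate_a`/`isolate_b` within
#' a pair does not matter) and returns the pair set with per-pair
#' `social_identity` (1 = same allotype, 0 = distinct allotypes).
#'
#' @param pairs A `pair_set`.
#' @param kd_scored Output of [score_kd()] covering every pair.
#' @return `pairs` with a `social_identity` column.
#' @export
social_identity <- function(pairs, kd_scored) {
  if (!"social_identity" %in% names(kd_scored)) kd_scored <- score_kd(kd_scored)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  idx <- match(key(pairs$isolate_a, pairs$isolate_b),
               key(kd_scored$isolate_a, kd_scored$isolate_b))
  if (anyNA(idx)) {
    miss <- paste(pairs$isolate_a[is.na(idx)], pairs$isolate_b[is.na(idx)],
                  sep = " vs ")
    stop("pair(s) without kin-discrimination scores: ",
         paste(miss, collapse = "; "))
  }
  pairs$social_identity <- kd_scored$social_identity[idx]
  pairs
}

#' Read or write a kin-discrimination score table
#'
#' Tab-separated columns `isolate_a`, `isolate_b`, `obs1`, `obs2`, `obs3`
#' (plus any columns added by [score_kd()]).
#'
#' @param path File path.
#' @param kd Data frame to write.
#' @export
read_kd_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_kd_table
#' @export
write_kd_table <- function(kd, path) {
  utils::write.table(kd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
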