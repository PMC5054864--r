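# Grouping keys for pair construction: at each scale a pair joins two
# distinct subunits of one unit (for micrometre, two distinct clones of one
# fruiting body; for kilometre, two distinct sites of the whole landscape).
scale_keys <- function(sheet) {
  fb <- paste0(sheet$site, sheet$transect, ".", sheet$core, ".",
               sheet$fruiting_body)
  core <- paste0(sheet$site, sheet$transect, ".", sheet$core)
  transect <- paste0(sheet$site, sheet$transect)
  list(
    micrometre = list(unit = fb, sub = sheet$isolate_id),
    millimetre = list(unit = core, sub = fb),
    centimetre = list(unit = transect, sub = core),
    metre = list(unit = sheet$site, sub = transect),
    kilometre = list(unit = rep("all", nrow(sheet)), sub = sheet$site)
  )
}

draw_scale_pair <- function(avail, unit, sub) {
  i <- which(avail)
  if (length(i) < 2L) return(NULL)
  # units offering at least two distinct available subunits
  ok <- vapply(split(sub[i], unit[i]), function(s) length(unique(s)) >= 2L,
               logical(1))
  if (!any(ok)) return(NULL)
  u <- sample_from(names(ok)[ok])
  iu <- i[unit[i] == u]
  subs <- sample_from(unique(sub[iu]), 2L)
  c(sample_from(iu[sub[iu] == subs[1L]]), sample_from(iu[sub[iu] == subs[2L]]))
}

#' Draw fully independent isolate pairs per spatial scale
#'
#' Samples `n_replicates` replicate sets of `n_per_scale` isolate pairs for
#' each of the five spatial-scale categories, under the defining constraint
#' that no isolate appears in more than one pair anywhere in the output
#' (across all replicates and all scales), so that every pair is
#' statistically independent of every other. Construction is a randomized
#' greedy fill ordered from the most-constrained scale (micrometre, which
#' needs two clones of one fruiting body) to the least, with random
#' restarts on dead ends.
#'
#' @param sheet Sample sheet (see [parse_isolate_id()]).
#' @param n_per_scale Pairs per scale per replicate (default 4).
#' @param n_replicates Replicates (default 3; the default demand is
#'   3 x 5 x 4 = 60 pairs over 120 distinct isolates).
#' @param seed Integer seed; the same seed reproduces the same pair set.
#' @param max_restarts Random restarts before declaring the demand
#'   infeasible (default 1000). Infeasibility is always an error, never a
#'   silent relaxation.
#' @return Data frame of class `pair_set` with columns `replicate`,
#'   `scale`, `isolate_a`, `isolate_b`; attributes record `seed`,
#'   `n_per_scale` and `n_replicates`.
#' @seealso [feasibility_report()] for per-scale capacity bounds.
#' @export
sample_independent_pairs <- function(sheet, n_per_scale = 4L,
                                     n_replicates = 3L, seed = NULL,
                                     max_restarts = 1000L) {
  stopifnot(n_per_scale >= 1L, n_replicates >= 1L)
  keys <- scale_keys(sheet)
  need <- n_per_scale * n_replicates
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      avail <- rep(TRUE, nrow(sheet))
      out <- vector("list", length(SCALE_LEVELS))
      names(out) <- SCALE_LEVELS
      failed <- NULL
      for (sc in SCALE_LEVELS) {
        rows <- matrix(NA_integer_, nrow = need, ncol = 2L)
        for (k in seq_len(need)) {
          p <- draw_scale_pair(avail, keys[[sc]]$unit, keys[[sc]]$sub)
          if (is.null(p)) { failed <- sc; break }
          rows[k, ] <- p
          avail[p] <- FALSE
        }
        if (!is.null(failed)) break
        out[[sc]] <- rows
      }
      if (is.null(failed)) {
        res <- do.call(rbind, lapply(SCALE_LEVELS, function(sc) {
          data.frame(
            replicate = rep(seq_len(n_replicates), each = n_per_scale),
            scale = sc,
            isolate_a = sheet$isolate_id[out[[sc]][, 1L]],
            isolate_b = sheet$isolate_id[out[[sc]][, 2L]]
          )
        }))
        res$scale <- scale_factor(res$scale)
        attr(res, "seed") <- seed
        attr(res, "n_per_scale") <- n_per_scale
        attr(res, "n_replicates") <- n_replicates
        class(res) <- c("pair_set", class(res))
        return(res)
      }
    }
    stop("could not construct disjoint pairs after ", max_restarts,
         " restarts; first scale that could not be filled on the last ",
         "attempt: ", failed, " (", sum(avail),
         " isolates still eligible). See feasibility_report().")
  })
}

#' Per-scale capacity bounds for independent pair sampling
#'
#' For each scale, an upper bound on the number of mutually disjoint pairs
#' the design can supply: within each unit the pair graph is complete
#' multipartite over its subunits, whose maximum matching is
#' `min(floor(n/2), n - largest subunit)`; unit capacities add. The bounds
#' are per-scale; scales compete for the same isolates, so meeting every
#' bound does not by itself guarantee joint feasibility.
#'
#' @inheritParams sample_independent_pairs
#' @return Data frame with columns `scale`, `capacity`, `demand`,
#'   `sufficient`.
#' @export
feasibility_report <- function(sheet, n_per_scale = 4L, n_replicates = 3L) {
  keys <- scale_keys(sheet)
  demand <- n_per_scale * n_replicates
  capacity <- vapply(SCALE_LEVELS, function(sc) {
    k <- keys[[sc]]
    sum(vapply(split(k$sub, k$unit), function(s) {
      n <- length(s)
      min(n %/% 2L, n - max(table(s)))
    }, numeric(1)))
  }, numeric(1))
  data.frame(scale = scale_factor(SCALE_LEVELS),
             capacity = as.integer(capacity),
             demand = demand,
             sufficient = capacity >= demand)
}

#' Validate a pair set against its defining constraints
#'
#' Checks global disjointness (no isolate in more than one pair anywhere)
#' and that each entry's labelled scale equals [pair_scale()] of its two
#' addresses.
#'
#' @param pairs A `pair_set` (or any data frame with its columns).
#' @param sheet Sample sheet covering every paired isolate.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_pair_set <- function(pairs, sheet) {
  ids <- c(pairs$isolate_a, pairs$isolate_b)
  if (anyDuplicated(ids)) {
    stop("isolate(s) used in more than one pair: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing <- setdiff(ids, sheet$isolate_id)
  if (length(missing)) {
    stop("paired isolate(s) absent from sample sheet: ",
         paste(missing, collapse = ", "))
  }
  lab <- pair_scale(pairs$isolate_a, pairs$isolate_b)
  bad <- as.character(lab) != as.character(pairs$scale)
  if (any(bad)) {
    stop("mislabelled pair scale for: ",
         paste(paste(pairs$isolate_a[bad], pairs$isolate_b[bad]),
               collapse = "; "))
  }
  invisible(TRUE)
}

#' Read or write a pair table
#'
#' Tab-separated columns `replicate`, `scale`, `isolate_a`, `isolate_b`;
#' the seed is recorded in a `#`-prefixed header comment.
#'
#' @param pairs A `pair_set`.
#' @param path File path.
#' @export
write_pair_set <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(pairs, "seed")
  writeLines(paste0("# seed=", if (is.null(seed)) "NA" else seed), con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_set
#' @export
read_pair_set <- function(path) {
  p <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  p$scale <- scale_factor(p$scale)
  class(p) <- c("pair_set", class(p))
  p
}
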