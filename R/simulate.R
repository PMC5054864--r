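#' Configuration of the simulated sampling landscape
#'
#' Describes the nested hierarchy to simulate and how lineages move through
#' it. The defaults mirror a three-site, five-level 3^5 design thinned by
#' fruiting-body missingness and clone genotyping failure to about 147
#' analysable isolates, with 82% of fruiting bodies founded by a single
#' lineage.
#'
#' @param n_sites,transects_per_site,cores_per_transect Numbers of units
#'   per level (defaults 3, 3, 3).
#' @param fruiting_bodies_per_core,clones_per_fruiting_body Defaults 3, 3.
#' @param fb_missing Probability a fruiting body is absent (no fruiting
#'   bodies formed / not sampled); default 0.28.
#' @param clone_failure Probability an individual clone fails genotyping
#'   and is excluded; default 0.15.
#' @param founder_clonality Probability a fruiting body is founded by a
#'   single lineage (default 0.82).
#' @param migration Named probabilities that a unit's resident lineage is a
#'   migrant drawn from the site's circulating pool rather than inherited
#'   from its parent unit: `site` (long-range migrant from outside the
#'   site's own pool), `transect`, `core`, `fb`.
#' @param site_pool_size Lineages circulating within each site (default 4).
#' @param site_labels Optional uppercase site labels (defaults GH, KF, MC,
#'   then S4, S5, ...).
#' @return Object of class `landscape_config`.
#' @export
landscape_config <- function(n_sites = 3L, transects_per_site = 3L,
                             cores_per_transect = 3L,
                             fruiting_bodies_per_core = 3L,
                             clones_per_fruiting_body = 3L,
                             fb_missing = 0.28, clone_failure = 0.15,
                             founder_clonality = 0.82,
                             migration = c(site = 0.1, transect = 0.45,
                                           core = 0.35, fb = 0.25),
                             site_pool_size = 4L, site_labels = NULL) {
  counts <- c(n_sites, transects_per_site, cores_per_transect,
              fruiting_bodies_per_core, clones_per_fruiting_body,
              site_pool_size)
  stopifnot(all(counts >= 1L))
  probs <- c(fb_missing, clone_failure, founder_clonality, migration)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(c("site", "transect", "core", "fb") %in% names(migration)))
  if (is.null(site_labels)) {
    site_labels <- c("GH", "KF", "MC", paste0("S", seq_len(n_sites)))[
      seq_len(n_sites)]
  }
  stopifnot(length(site_labels) == n_sites, !anyDuplicated(site_labels),
            all(grepl("^[A-Z]+$", site_labels)))
  structure(list(n_sites = n_sites, transects_per_site = transects_per_site,
                 cores_per_transect = cores_per_transect,
                 fruiting_bodies_per_core = fruiting_bodies_per_core,
                 clones_per_fruiting_body = clones_per_fruiting_body,
                 fb_missing = fb_missing, clone_failure = clone_failure,
                 founder_clonality = founder_clonality,
                 migration = migration, site_pool_size = site_pool_size,
                 site_labels = site_labels),
            class = "landscape_config")
}

#' Configuration of simulated sequence evolution
#'
#' @param locus_lengths Alignment length of each locus (default five loci
#'   of 289 bp, summing to 1445 sites).
#' @param n_clades Deeply divergent founder clades (default 3).
#' @param clade_divergence Proportion of sites differing between clade
#'   founders (default 0.08).
#' @param within_clade_divergence Proportion of sites separating lineages
#'   of the same clade in the global pool (default 0.005).
#' @param pool_size Lineages in the global pool (default 12).
#' @param site_imprint_mut Private substitutions imprinted on a lineage the
#'   first time it enters a site (default 2; makes sequence types
#'   site-private, as observed in nature).
#' @param transect_mut Private substitutions per transect resident
#'   (default 1).
#' @param mu_clone Per-site substitution probability per clone
#'   (default 1e-5).
#' @param rho_rel Recombination events per mutation event (default 0.26,
#'   the rho/theta scale); donors are lineages circulating in the same
#'   site.
#' @param tract_mean Mean recombination tract length in nucleotides
#'   (default 12).
#' @param fixed_gap_columns Number of alignment columns set to `-` in all
#'   sequences (default 0; gaps do not evolve).
#' @return Object of class `evolution_config`.
#' @export
evolution_config <- function(locus_lengths = rep(289L, 5L), n_clades = 3L,
                             clade_divergence = 0.08,
                             within_clade_divergence = 0.005,
                             pool_size = 12L, site_imprint_mut = 2L,
                             transect_mut = 1L, mu_clone = 1e-5,
                             rho_rel = 0.26, tract_mean = 12,
                             fixed_gap_columns = 0L) {
  stopifnot(length(locus_lengths) >= 1L, all(locus_lengths >= 1L),
            n_clades >= 1L, pool_size >= n_clades,
            clade_divergence >= 0, clade_divergence <= 1,
            within_clade_divergence >= 0, mu_clone >= 0, rho_rel >= 0,
            tract_mean >= 1, site_imprint_mut >= 0, transect_mut >= 0,
            fixed_gap_columns >= 0,
            fixed_gap_columns < sum(locus_lengths))
  structure(list(locus_lengths = as.integer(locus_lengths),
                 n_clades = n_clades, clade_divergence = clade_divergence,
                 within_clade_divergence = within_clade_divergence,
                 pool_size = pool_size, site_imprint_mut = site_imprint_mut,
                 transect_mut = transect_mut, mu_clone = mu_clone,
                 rho_rel = rho_rel, tract_mean = tract_mean,
                 fixed_gap_columns = fixed_gap_columns),
            class = "evolution_config")
}

#' Configuration of the simulated kin-discrimination assay
#'
#' The probability that a pair of isolates exhibits a kin-discrimination
#' phenotype is logistic in their pairwise genetic distance `d`:
#' `plogis(intercept + slope * d)`. The defaults give a probability near
#' zero at `d = 0` (clonemates merge freely) rising steeply across the
#' range of within-clade distances. Each of the `n_observers` binary calls
#' flips independently with probability `epsilon`.
#'
#' @param intercept,slope Logistic coefficients (defaults -6 and 8000).
#' @param epsilon Per-call observer error rate (default 0.02, the rate
#'   implied by 3 disagreements in 150 triple-scored assays).
#' @param n_observers Odd panel size (default 3).
#' @return Object of class `kd_model_config`.
#' @export
kd_model_config <- function(intercept = -6, slope = 8000, epsilon = 0.02,
                            n_observers = 3L) {
  stopifnot(epsilon >= 0, epsilon <= 1, n_observers >= 1L,
            n_observers %% 2L == 1L)
  structure(list(intercept = intercept, slope = slope, epsilon = epsilon,
                 n_observers = n_observers), class = "kd_model_config")
}

BASES <- c("A", "C", "G", "T")

mutate_hap <- function(hap, n_mut) {
  n_mut <- min(n_mut, length(hap))
  if (n_mut == 0L) return(hap)
  pos <- sample.int(length(hap), n_mut)
  hap[pos] <- ((hap[pos] - 1L + sample.int(3L, n_mut, replace = TRUE)) %% 4L) + 1L
  hap
}

recombine_hap <- function(hap, donor, tract_mean) {
  len <- min(1L + stats::rgeom(1L, 1 / tract_mean), length(hap))
  start <- sample.int(length(hap) - len + 1L, 1L)
  idx <- start:(start + len - 1L)
  hap[idx] <- donor[idx]
  hap
}

# Introduce n_mut substitutions and the coupled number of recombination
# tracts (Poisson with mean rho_rel * n_mut, donors drawn by donor_fun).
evolve_hap <- function(hap, n_mut, evo, donor_fun = NULL) {
  hap <- mutate_hap(hap, n_mut)
  if (!is.null(donor_fun) && evo$rho_rel > 0 && n_mut > 0L) {
    n_rec <- stats::rpois(1L, evo$rho_rel * n_mut)
    for (i in seq_len(n_rec)) {
      hap <- recombine_hap(hap, donor_fun(), evo$tract_mean)
    }
  }
  hap
}

#' Simulate a hierarchically structured bacterial landscape
#'
#' Generates a complete synthetic input set for the pipeline: a clade-
#' structured pool of multilocus genotypes, a nested landscape colonized by
#' distance-limited lineage movement (each unit inherits its parent unit's
#' resident lineage or, with the level's migration probability, recruits a
#' lineage circulating in the site), fruiting bodies that are single-
#' founder with probability `founder_clonality`, and per-clone mutation
#' with site-restricted recombination tracts. Deterministic given `seed`.
#'
#' @param landscape A [landscape_config()].
#' @param evolution An [evolution_config()].
#' @param seed Integer seed.
#' @param dir Optional output directory: writes one FASTA per locus
#'   (`locus_<k>.fasta`), `sample_sheet.tsv`, `st_truth.tsv`,
#'   `clade_truth.tsv` and `manifest.json`.
#' @return List with `sheet` (sample sheet), `alignments`
#'   (`locus_alignment_set`), `concatemers`, `st` (true sequence-type map,
#'   as [assign_sequence_types()]), `clades` (named vector isolate ->
#'   clade label), `manifest`.
#' @export
simulate_landscape <- function(landscape = landscape_config(),
                               evolution = evolution_config(),
                               seed = 1L, dir = NULL) {
  stopifnot(inherits(landscape, "landscape_config"),
            inherits(evolution, "evolution_config"))
  lc <- landscape
  evo <- evolution
  L <- sum(evo$locus_lengths)
  res <- with_seed(seed, {
    base <- sample.int(4L, L, replace = TRUE)
    # clade founders are mutually equidistant: each clade mutates its own
    # disjoint set of sites, so any two founders differ at ~clade_divergence
    # of sites
    per_clade <- min(round(evo$clade_divergence * L / 2),
                     L %/% evo$n_clades)
    pos <- sample.int(L, per_clade * evo$n_clades)
    founders <- lapply(seq_len(evo$n_clades), function(cl) {
      own <- pos[seq_len(per_clade) + (cl - 1L) * per_clade]
      hap <- base
      hap[own] <- ((hap[own] - 1L +
                      sample.int(3L, length(own), replace = TRUE)) %% 4L) + 1L
      hap
    })
    pool_clade <- rep(seq_len(evo$n_clades), length.out = evo$pool_size)
    pool <- lapply(seq_len(evo$pool_size), function(l) {
      mutate_hap(founders[[pool_clade[l]]],
                 round(evo$within_clade_divergence * L))
    })
    site_pools <- lapply(seq_len(lc$n_sites), function(s) {
      sample.int(evo$pool_size, lc$site_pool_size,
                 replace = lc$site_pool_size > evo$pool_size)
    })
    # site-private variant of each lineage, created lazily on first entry
    variants <- new.env(parent = emptyenv())
    site_donor <- function(s) {
      keys <- grep(paste0("^", s, "\\."), ls(variants), value = TRUE)
      if (length(keys)) get(sample_from(keys), envir = variants)$hap
      else pool[[sample_from(site_pools[[s]])]]
    }
    site_variant <- function(s, l) {
      key <- paste0(s, ".", l)
      if (!exists(key, envir = variants)) {
        hap <- evolve_hap(pool[[l]], evo$site_imprint_mut, evo,
                          donor_fun = function() site_donor(s))
        assign(key, list(hap = hap, clade = pool_clade[l]), envir = variants)
      }
      get(key, envir = variants)
    }
    draw_site_lineage <- function(s) {
      l <- if (stats::runif(1) < lc$migration[["site"]]) {
        sample.int(evo$pool_size, 1L)
      } else {
        sample_from(site_pools[[s]])
      }
      site_variant(s, l)
    }
    ids <- character(0)
    haps <- list()
    clades <- integer(0)
    for (s in seq_len(lc$n_sites)) {
      r_site <- draw_site_lineage(s)
      for (t in seq_len(lc$transects_per_site)) {
        tr_base <- if (stats::runif(1) < lc$migration[["transect"]]) {
          draw_site_lineage(s)
        } else r_site
        r_tr <- list(hap = evolve_hap(tr_base$hap, evo$transect_mut, evo,
                                      function() site_donor(s)),
                     clade = tr_base$clade)
        for (co in seq_len(lc$cores_per_transect)) {
          r_core <- if (stats::runif(1) < lc$migration[["core"]]) {
            draw_site_lineage(s)
          } else r_tr
          for (f in seq_len(lc$fruiting_bodies_per_core)) {
            if (stats::runif(1) < lc$fb_missing) next
            founder_a <- if (stats::runif(1) < lc$migration[["fb"]]) {
              draw_site_lineage(s)
            } else r_core
            single <- stats::runif(1) < lc$founder_clonality
            founder_b <- if (!single) draw_site_lineage(s) else NULL
            survivors <- which(stats::runif(lc$clones_per_fruiting_body) >=
                                 lc$clone_failure)
            m <- length(survivors)
            if (m == 0L) next
            fnd <- rep(list(founder_a), m)
            if (!single && m >= 2L) {
              fnd[[2L]] <- founder_b
              if (m > 2L) {
                pick <- stats::runif(m - 2L) < 0.5
                fnd[3:m][pick] <- list(founder_b)
              }
            }
            for (j in seq_len(m)) {
              hap <- evolve_hap(fnd[[j]]$hap, stats::rpois(1L, evo$mu_clone * L),
                                evo, function() site_donor(s))
              id <- paste0(lc$site_labels[s], t, ".", co, ".", f,
                           LETTERS[survivors[j]])
              ids <- c(ids, id)
              haps[[id]] <- hap
              clades[id] <- fnd[[j]]$clade
            }
          }
        }
      }
    }
    if (length(ids) == 0L) stop("simulated landscape produced no isolates")
    gap_cols <- if (evo$fixed_gap_columns > 0L) {
      sort(sample.int(L, evo$fixed_gap_columns))
    } else integer(0)
    list(ids = ids, haps = haps, clades = clades, gap_cols = gap_cols)
  })
  seq_chr <- vapply(res$haps, function(h) {
    x <- BASES[h]
    if (length(res$gap_cols)) x[res$gap_cols] <- "-"
    paste(x, collapse = "")
  }, character(1))
  bounds <- cumsum(c(0L, evo$locus_lengths))
  loci <- paste0("locus_", seq_along(evo$locus_lengths))
  alignments <- lapply(seq_along(evo$locus_lengths), function(k) {
    substr(seq_chr, bounds[k] + 1L, bounds[k + 1L])
  })
  names(alignments) <- loci
  alignments <- locus_alignment_set(alignments)
  concat <- concatenate_loci(alignments)
  sheet <- sample_sheet_from_ids(res$ids)
  st <- assign_sequence_types(concat)
  manifest <- list(command = "simulate_landscape", seed = seed,
                   landscape = unclass(lc), evolution = unclass(evo),
                   n_isolates = length(res$ids), n_st = st$n_st)
  out <- list(sheet = sheet, alignments = alignments, concatemers = concat,
              st = st, clades = res$clades, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(alignments)) {
      Biostrings::writeXStringSet(
        Biostrings::BStringSet(alignments[[k]]),
        file.path(dir, paste0(loci[k], ".fasta")))
    }
    write_sample_sheet(sheet, file.path(dir, "sample_sheet.tsv"))
    utils::write.table(
      data.frame(isolate_id = names(st$st), st = unname(st$st)),
      file.path(dir, "st_truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(isolate_id = names(res$clades), clade = unname(res$clades)),
      file.path(dir, "clade_truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate kin-discrimination assays for a pair set
#'
#' For each pair, the true kin-discrimination state is drawn from the
#' logistic-in-genetic-distance model of [kd_model_config()]; each observer
#' then reports the true state flipped independently with probability
#' `epsilon`. Self-self control pairs (distance 0 by definition) are
#' supported.
#'
#' @param pairs Data frame with `isolate_a`, `isolate_b` (e.g. a
#'   `pair_set`).
#' @param distances Genetic distance matrix covering all paired isolates.
#' @param kd A [kd_model_config()].
#' @param seed Integer seed.
#' @return Data frame `isolate_a`, `isolate_b`, `true_kd`, `obs1..obsK`.
#' @export
simulate_kd <- function(pairs, distances, kd = kd_model_config(),
                        seed = 1L) {
  stopifnot(inherits(kd, "kd_model_config"))
  ids <- unique(c(pairs$isolate_a, pairs$isolate_b))
  missing <- setdiff(ids, rownames(distances))
  if (length(missing)) {
    stop("no distances for isolate(s): ", paste(missing, collapse = ", "))
  }
  d <- distances[cbind(pairs$isolate_a, pairs$isolate_b)]
  p_kd <- stats::plogis(kd$intercept + kd$slope * d)
  with_seed(seed, {
    true_kd <- stats::rbinom(length(p_kd), 1L, p_kd)
    obs <- vapply(seq_len(kd$n_observers), function(k) {
      flip <- stats::rbinom(length(true_kd), 1L, kd$epsilon)
      as.integer(xor(true_kd, flip))
    }, integer(length(true_kd)))
    obs <- matrix(obs, nrow = length(true_kd))
    colnames(obs) <- paste0("obs", seq_len(kd$n_observers))
    cbind(data.frame(isolate_a = pairs$isolate_a,
                     isolate_b = pairs$isolate_b, true_kd = true_kd),
          as.data.frame(obs))
  })
}
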