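default_config <- function() {
  list(
    seed = 1L,
    out_dir = "kinscape_run",
    simulate = TRUE,
    input = NULL,  # list(sample_sheet=, loci=named FASTA paths, kd=, clades=)
    landscape = list(), evolution = list(), kd_model = list(),
    pairs = list(n_per_scale = 4L, n_replicates = 3L, max_restarts = 1000L),
    genotype = list(model = "p", site_handling = "pairwise"),
    spatial = list(n_perm = 9999L)
  )
}

merge_config <- function(user, defaults = default_config()) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      utils::modifyList(defaults[[k]], user[[k]])
    } else user[[k]]
  }
  defaults
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("stage [%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full nested-scale relatedness analysis
#'
#' Orchestrates simulate (or load) -> genotype -> independent pairs ->
#' kin-discrimination scoring -> identity-decay curves -> spatial tests,
#' writing every table, a JSON record of the test statistics, a
#' human-readable report and a run manifest to `out_dir`. Any stage error
#' aborts the run naming the stage.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one. Recognised sections: `seed`, `out_dir`, `simulate` (logical),
#'   `input` (paths: `sample_sheet`, named `loci` FASTAs, optional `kd`,
#'   `clades`), `landscape`, `evolution`, `kd_model` (arguments of the
#'   respective config constructors), `pairs` (`n_per_scale`,
#'   `n_replicates`, `max_restarts`), `genotype` (`model`,
#'   `site_handling`), `spatial` (`n_perm`).
#' @return Invisibly, a list bundle with every intermediate object
#'   (`sheet`, `concatemers`, `st`, `distances`, `pairs`, `kd`, `curves`,
#'   `comparison`, `correlation`, `spatial`, `manifest`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  seed <- as.integer(cfg$seed)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  sim <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- run_stage("simulate", {
      simulate_landscape(do.call(landscape_config, cfg$landscape),
                         do.call(evolution_config, cfg$evolution),
                         seed = seed, dir = file.path(out, "inputs"))
    })
    sheet <- sim$sheet
    alignments <- sim$alignments
    clades <- sim$clades
  } else {
    inp <- cfg$input
    for (f in c("sample_sheet", "loci")) {
      if (is.null(inp[[f]])) stop("config input$", f, " is required when ",
                                  "simulate is FALSE")
    }
    sheet <- run_stage("load", read_sample_sheet(inp$sample_sheet))
    alignments <- run_stage("load_loci",
                            read_locus_alignments(unlist(inp$loci)))
    clades <- NULL
    if (!is.null(inp$clades)) {
      cl <- utils::read.delim(inp$clades, stringsAsFactors = FALSE)
      clades <- stats::setNames(cl$clade, cl$isolate_id)
    }
  }

  geno <- run_stage("genotype", {
    concat <- concatenate_loci(alignments)
    st <- assign_sequence_types(concat[sheet$isolate_id])
    dist <- genetic_distances(concat[sheet$isolate_id],
                              model = cfg$genotype$model,
                              site_handling = cfg$genotype$site_handling)
    div <- diversity_table(sheet, concat,
                           site_handling = cfg$genotype$site_handling)
    utils::write.table(
      data.frame(isolate_id = names(st$st), st = unname(st$st)),
      file.path(out, "st_assignment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(div, file.path(out, "diversity_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(dist),
                       file.path(out, "genetic_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    list(concat = concat, st = st, dist = dist, div = div)
  })

  pairs <- run_stage("pairs", {
    p <- sample_independent_pairs(sheet,
                                  n_per_scale = cfg$pairs$n_per_scale,
                                  n_replicates = cfg$pairs$n_replicates,
                                  seed = seed + 1L,
                                  max_restarts = cfg$pairs$max_restarts)
    write_pair_set(p, file.path(out, "pairs.tsv"))
    p
  })

  kd <- run_stage("kd_score", {
    raw <- if (isTRUE(cfg$simulate)) {
      simulate_kd(pairs, geno$dist, do.call(kd_model_config, cfg$kd_model),
                  seed = seed + 2L)
    } else {
      if (is.null(cfg$input$kd)) stop("config input$kd is required when ",
                                      "simulate is FALSE")
      read_kd_table(cfg$input$kd)
    }
    scored <- score_kd(raw)
    write_kd_table(scored, file.path(out, "kd_scores.tsv"))
    scored
  })

  identity <- run_stage("identity", {
    gc <- genetic_identity_curve(pairs, geno$st$st)
    sc <- social_identity_curve(pairs, kd)
    write_identity_curve(gc, file.path(out, "genetic_curve.tsv"))
    write_identity_curve(sc, file.path(out, "social_curve.tsv"))
    comparison <- anova_tukey(gc)
    if (!is.null(comparison$tukey)) {
      utils::write.table(comparison$tukey, file.path(out, "tukey.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    corr <- curve_correlation(gc, sc, p_method = "permutation")
    list(genetic = gc, social = sc, comparison = comparison,
         correlation = corr)
  })

  spatial <- run_stage("spatial", {
    geo <- geographic_distances(sheet)
    mant <- mantel_test(geo, geno$dist, n_perm = cfg$spatial$n_perm,
                        seed = seed + 3L)
    curve_all <- scale_distance_curve(geno$dist, sheet, scope = "overall")
    res <- list(mantel = list(r = mant$r, p = mant$p,
                              n_perm = mant$n_perm, n = mant$n),
                scale_curve = curve_all$means,
                fit_coef = curve_all$fit_coef)
    if (!is.null(clades)) {
      st_named <- geno$st$st
      sites_map <- st_site_map(sheet, st_named)
      stdist <- st_distances(geno$concat[sheet$isolate_id], st_named,
                             model = cfg$genotype$model)
      conc <- nearest_st_concordance(stdist, sites_map, seed = seed + 4L)
      res$nearest_st <- list(observed = conc$observed,
                             expected = conc$expected, p = conc$p)
      # per-clade absence tests at sites where the clade was never seen
      cl_levels <- sort(unique(clades[sheet$isolate_id]))
      absent <- list()
      for (cl in cl_levels) {
        for (s in unique(sheet$site)) {
          n_cl <- sum(clades[sheet$isolate_id][sheet$site == s] == cl)
          if (n_cl == 0L) {
            a <- clade_absence_test(clades, sheet, cl, s)
            absent[[paste0("clade", cl, "_absent_", s)]] <-
              list(p = a$p, n = a$n, f = a$f)
          }
        }
      }
      res$clade_absence <- absent
    }
    jsonlite::write_json(res, file.path(out, "spatial_tests.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    res
  })

  manifest <- run_stage("manifest", {
    inputs <- list.files(file.path(out, "inputs"), full.names = TRUE)
    mf <- list(command = "run_pipeline",
               version = as.character(utils::packageVersion("kinscape")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = seed, config = cfg,
               input_md5 = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(mf, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    mf
  })

  report <- c(
    "kinscape pipeline report",
    sprintf("isolates: %d; sequence types: %d", nrow(sheet), geno$st$n_st),
    "",
    "genetic identity-decay curve (pooled per scale):",
    utils::capture.output(print(identity$genetic$summary)),
    "",
    "social identity-decay curve (pooled per scale):",
    utils::capture.output(print(identity$social$summary)),
    "",
    sprintf("genetic curve ANOVA: F = %s, p = %s%s",
            format(identity$comparison$f), format(identity$comparison$p),
            if (isTRUE(identity$comparison$exact_separation))
              " (exact separation: zero within-scale variance)" else ""),
    sprintf("genetic vs social curve correlation: r = %.3f (permutation p = %.3f)",
            identity$correlation$r, identity$correlation$p),
    sprintf("Mantel test: r = %.3f, p = %.4g (%s permutations)",
            spatial$mantel$r, spatial$mantel$p, spatial$mantel$n_perm)
  )
  writeLines(report, file.path(out, "report.txt"))

  invisible(list(sheet = sheet, concatemers = geno$concat, st = geno$st,
                 diversity = geno$div, distances = geno$dist, pairs = pairs,
                 kd = kd, curves = list(genetic = identity$genetic,
                                        social = identity$social),
                 comparison = identity$comparison,
                 correlation = identity$correlation, spatial = spatial,
                 clades = clades, manifest = manifest))
}
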