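# End-to-end driver: simulate -> map -> call -> annotate -> prioritize ->
# popgen -> tfbs -> stats.  Each stage writes its outputs under the run
# directory and never mutates an upstream artifact, so a downstream stage
# can be re-run alone from the cached files.

#' Build a run configuration
#'
#' Flat named list of every pipeline threshold, validated against the module
#' preconditions.  `simulation` carries the [SimulationConfig-class] used
#' when the run starts from synthetic data.
#'
#' @param simulation A [SimulationConfig-class].
#' @param k Seed length for the mapper.
#' @param scoring A [ScoringScheme-class].
#' @param min_depth,min_fraction Genotype-calling thresholds.
#' @param phastcons_min,case_freq_max,exclude_known Prioritization filter.
#' @param z_min PWM scan z threshold.
#' @param confidence Confidence level of the Poisson frequency bound.
#' @param max_candidates,min_score Mapper candidate cap and score floor.
#' @param seed Run seed.
#' @return Named list of validated settings.
#' @export
runConfig <- function(simulation = simulationConfig(), k = 16,
                      scoring = scoringScheme(), min_depth = 8,
                      min_fraction = 0.75, phastcons_min = 0.7,
                      case_freq_max = 0.01, exclude_known = TRUE,
                      z_min = 1.64, confidence = 0.99, max_candidates = 8,
                      min_score = 30, seed = simulation@seed) {
  validObject(simulation)
  validObject(scoring)
  stopifnot(
    k >= 8, k <= 32, min_depth >= 1, min_fraction > 0, min_fraction <= 1,
    phastcons_min >= 0, phastcons_min <= 1, case_freq_max >= 0,
    case_freq_max <= 1, confidence > 0, confidence < 1
  )
  fb <- c(
    max(2 * simulation@read_length - 20, 50),
    ceiling(simulation@fragment_mean + 6 * simulation@fragment_sd)
  )
  list(
    simulation = simulation, k = as.integer(k), scoring = scoring,
    min_depth = min_depth, min_fraction = min_fraction,
    phastcons_min = phastcons_min, case_freq_max = case_freq_max,
    exclude_known = exclude_known, z_min = z_min, confidence = confidence,
    fragment_bounds = fb, max_candidates = as.integer(max_candidates),
    min_score = as.integer(min_score), seed = as.integer(seed)
  )
}

#' Read a run configuration from a flat YAML key-value file
#'
#' Unknown keys are rejected; keys that belong to the simulation config are
#' routed there.
#'
#' @param path YAML file of scalar keys.
#' @return A [runConfig()] list.
#' @export
readRunConfigFile <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_keys <- c(
    "target_length", "n_amplicons", "n_samples", "mean_depth",
    "read_length", "fragment_mean", "fragment_sd", "error_rate",
    "n_variants", "rare_fraction", "catalog_fraction", "conserved_fraction",
    "indel_fraction", "edge_margin", "allow_overlap", "seed"
  )
  run_keys <- c(
    "k", "min_depth", "min_fraction", "phastcons_min", "case_freq_max",
    "exclude_known", "z_min", "confidence", "max_candidates", "min_score"
  )
  unknown <- setdiff(names(raw), c(sim_keys, run_keys))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  sim <- do.call(simulationConfig, raw[intersect(names(raw), sim_keys)])
  do.call(runConfig, c(
    list(simulation = sim),
    raw[intersect(names(raw), run_keys)]
  ))
}

stageLog <- function(run_log, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  message(line)
  if (!is.null(run_log)) cat(line, "\n", file = run_log, append = TRUE)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort, maps and calls every sample, annotates and
#' prioritizes the merged cohort, computes the population-genetic summary
#' over the callable length, scans the target with the calibrated PWM set,
#' and evaluates the closing statistics.  Identical config and seed give
#' identical outputs; a stage failure aborts with the stage named and leaves
#' a `FAILED_<stage>` marker next to the partial outputs.
#'
#' @param config A [runConfig()] list.
#' @param outdir Run directory (created if needed).
#' @return Invisibly, a list with the cohort, annotated, prioritized,
#'   popgen, tfbs and stats tables, per-sample coverage, the simulation
#'   truth, and output paths.
#' @export
runPipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  run_log <- file.path(outdir, "run.log")
  cat("", file = run_log)
  for (key in setdiff(names(config), c("simulation", "scoring"))) {
    stageLog(run_log, "config", "%s = %s", key,
             paste(format(config[[key]]), collapse = " "))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(
        outdir,
        paste0("FAILED_", name)
      ))
      stop("stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  sim <- stage("simulate", {
    s <- simulateCohort(config$simulation, file.path(outdir, "sim"))
    stageLog(
      run_log, "simulate", "%d samples, %d truth variants",
      config$simulation@n_samples, nrow(s$truth)
    )
    s
  })
  reference <- sim$reference
  samples <- names(sim$haplotypes)

  dir.create(file.path(outdir, "placements"), showWarnings = FALSE)
  dir.create(file.path(outdir, "calls"), showWarnings = FALSE)
  sample_calls <- vector("list", length(samples))
  names(sample_calls) <- samples
  callable_any <- rep(FALSE, nchar(reference))
  coverage <- list()
  depth_pool <- numeric(0L)

  for (s in samples) {
    placements <- stage("map", mapFastqPair(
      file.path(sim$paths$reads, paste0(s, "_1.fastq")),
      file.path(sim$paths$reads, paste0(s, "_2.fastq")),
      reference,
      k = config$k, scoring = config$scoring,
      fragment_bounds = config$fragment_bounds,
      max_candidates = config$max_candidates,
      min_score = config$min_score
    ))
    writePlacements(placements, file.path(
      outdir, "placements",
      paste0(s, ".tsv")
    ))
    res <- stage("call", {
      pile <- accumulatePileup(placements, reference)
      callVariants(pile, reference,
        sample_id = s,
        min_depth = config$min_depth, min_fraction = config$min_fraction
      )
    })
    callable_any <- callable_any | !(seq_along(callable_any) %in% res$no_call)
    coverage[[s]] <- res$coverage
    sample_calls[[s]] <- res
    writeVcf(
      data.frame(
        pos = res$calls$pos, id = rep(".", nrow(res$calls)),
        ref = res$calls$ref, alt = res$calls$alt,
        info = sprintf("DP=%d;AF=%.4f", res$calls$depth, res$calls$fraction),
        stringsAsFactors = FALSE
      ),
      file.path(outdir, "calls", paste0(s, ".vcf"))
    )
  }
  stageLog(
    run_log, "map/call", "%d samples mapped and called; median of medians %sx",
    length(samples),
    format(median(vapply(coverage, `[[`, numeric(1L), "median_depth")))
  )

  cohort <- stage("merge", mergeCohort(sample_calls,
    n_samples = length(samples)
  ))
  writeTsv(cohort, file.path(outdir, "cohort.tsv"))
  stageLog(run_log, "merge", "%d cohort sites", nrow(cohort))

  annotated <- stage("annotate", {
    models <- readGeneModels(sim$paths$genes)
    catalog <- readCatalogVcf(sim$paths$catalog)
    track <- readConservationTrack(sim$paths$conservation)
    features <- lapply(sim$paths$features, readFeatureBed)
    names(features) <- names(sim$paths$features)
    controls <- readTsv(sim$paths$controls)
    annotateCohort(cohort, models, catalog, track, reference,
      feature_tracks = features, controls = controls
    )
  })
  writeTsv(annotated, file.path(outdir, "annotated.tsv"))
  stageLog(run_log, "annotate", "%d rows annotated", nrow(annotated))

  prioritized <- stage("prioritize", filterConservedRare(
    annotated,
    phastcons_min = config$phastcons_min,
    case_freq_max = config$case_freq_max,
    exclude_known = config$exclude_known
  ))
  writeTsv(prioritized, file.path(outdir, "prioritized.tsv"))
  stageLog(run_log, "prioritize", "%d rows kept", nrow(prioritized))

  popgen <- stage("popgen", {
    L_callable <- sum(callable_any)
    popgenSummary(cohort, n = length(samples), L = max(L_callable, 1L))
  })
  writeTsv(popgen, file.path(outdir, "popgen.tsv"))
  stageLog(
    run_log, "popgen", "S=%d theta_w=%.3g D=%.3f", popgen$S,
    popgen$theta_w_per_site, popgen$D
  )

  tfbs <- stage("tfbs", {
    pwms <- readPwms(sim$paths$pwms)
    bg <- as.character(Biostrings::readDNAStringSet(sim$paths$background))
    hits <- do.call(rbind, lapply(pwms, function(p) {
      cal <- calibratePwm(p, bg)
      scanPwm(reference, p, cal, z_min = config$z_min)
    }))
    rownames(hits) <- NULL
    hits
  })
  writeTsv(tfbs, file.path(outdir, "tfbs.tsv"))
  stageLog(run_log, "tfbs", "%d hits at z >= %.2f", nrow(tfbs), config$z_min)

  stats <- stage("stats", {
    novelty <- noveltySummary(annotated)
    data.frame(
      statistic = c(
        "poisson_bound", "coverage_fraction_ge_threshold",
        "median_depth_median_sample",
        paste0("novel_pct_", novelty$type)
      ),
      value = c(
        poissonUpperBound(0, length(samples), config$confidence),
        mean(vapply(coverage, `[[`, numeric(1L), "fraction_at_least")),
        median(vapply(coverage, `[[`, numeric(1L), "median_depth")),
        novelty$novel_pct
      )
    )
  })
  writeTsv(stats, file.path(outdir, "stats.tsv"))
  stageLog(run_log, "stats", "done")

  invisible(list(
    config = config, truth = sim$truth, planted_motifs = sim$planted_motifs,
    pwms = sim$pwms, reference = reference, cohort = cohort,
    annotated = annotated, prioritized = prioritized, popgen = popgen,
    tfbs = tfbs, stats = stats, coverage = coverage,
    callable_length = sum(callable_any), outdir = outdir
  ))
}
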