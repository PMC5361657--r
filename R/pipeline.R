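# End-to-end orchestration: configuration, the full analysis run, and
# artifact writing.

#' Configure a pipeline run
#'
#' A run takes exactly one input source: a long-format kinetic CSV
#' (`input_csv`) or a [simulation_config()] (`simulation`) to generate the
#' dataset on the fly.
#'
#' @param out_dir output directory (created if needed).
#' @param input_csv path to a kinetic CSV, or `NULL`.
#' @param simulation a [simulation_config()], or `NULL`.
#' @param thresholds a [growth_thresholds()] object.
#' @param permutations a [permutation_settings()] object.
#' @param linkage dendrogram linkage (`"average"`, `"single"`,
#'   `"complete"`).
#' @param include_control include the water-control well in the global
#'   comparisons (default `FALSE`).
#' @param verbose log progress to the console (default `TRUE`).
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir, input_csv = NULL, simulation = NULL,
                       thresholds = growth_thresholds(),
                       permutations = permutation_settings(),
                       linkage = "average", include_control = FALSE,
                       verbose = TRUE) {
  if (is.null(input_csv) == is.null(simulation)) {
    stop("exactly one input source required: `input_csv` or `simulation`")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation,
                                               "simulation_config"))
  stopifnot(inherits(thresholds, "growth_thresholds"),
            inherits(permutations, "permutation_settings"))
  structure(list(out_dir = out_dir, input_csv = input_csv,
                 simulation = simulation, thresholds = thresholds,
                 permutations = permutations, linkage = linkage,
                 include_control = isTRUE(include_control),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full phenotype-microarray comparison pipeline
#'
#' Loads or simulates a kinetic dataset, builds the per-substrate endpoint
#' summary (Welch tests, BH adjustment, outcome codes), computes the
#' census, runs the per-time-point global scan (Bray-Curtis + PERMANOVA /
#' ANOSIM / MRPP) and writes one dendrogram per time point. Artifacts are
#' written atomically into `out_dir`:
#' `summary.tsv`, `census.json`, `global_scan.tsv`, `global_scan.json`,
#' `dendrograms/day_<t>.nwk`, `run_log.txt`, plus `kinetic.csv` and
#' `truth.tsv` for simulated inputs. Given a seeded configuration the run
#' is deterministic.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `summary`, `census`, `scan`) and the artifact `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message("[pmcompare] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "dendrograms"),
             showWarnings = FALSE)
  paths <- list()

  layout <- stage("layout", ff_plate_layout())
  sim <- NULL
  dataset <- if (!is.null(config$input_csv)) {
    say("reading kinetic CSV from ", config$input_csv)
    stage("input", read_kinetic_csv(config$input_csv, layout))
  } else {
    say("simulating dataset (seed ", config$simulation$seed, ")")
    sim <- stage("simulate", generate_dataset(config$simulation))
    paths$kinetic_csv <- file.path(config$out_dir, "kinetic.csv")
    write_atomic(paths$kinetic_csv,
                 function(p) write_kinetic_csv(sim$dataset, p))
    paths$truth_tsv <- file.path(config$out_dir, "truth.tsv")
    write_atomic(paths$truth_tsv,
                 function(p) write_truth_tsv(sim$truth, p))
    sim$dataset
  }

  say("summarising substrates at day ", config$thresholds$endpoint_day)
  summary <- stage("summarize",
                   summarize_substrates(dataset, layout, config$thresholds))
  paths$summary_tsv <- file.path(config$out_dir, "summary.tsv")
  write_atomic(paths$summary_tsv,
               function(p) write_summary_tsv(summary, p))

  cen <- stage("census", census(summary, config$thresholds))
  paths$census_json <- file.path(config$out_dir, "census.json")
  write_atomic(paths$census_json, function(p) {
    jsonlite::write_json(
      c(list(schema = "pmcompare/census/1"), unclass(cen)),
      p, auto_unbox = TRUE, digits = NA)
  })

  say("global scan over ", length(dataset$time_grid), " time points (",
      config$permutations$n_perm, " permutations)")
  scan <- stage("global_scan",
                suppressWarnings(global_scan(dataset, layout,
                                             config$permutations,
                                             include_control =
                                               config$include_control)))
  paths$global_tsv <- file.path(config$out_dir, "global_scan.tsv")
  write_atomic(paths$global_tsv, function(p) write_global_tsv(scan, p))
  paths$global_json <- file.path(config$out_dir, "global_scan.json")
  write_atomic(paths$global_json, function(p) {
    jsonlite::write_json(list(schema = "pmcompare/global_scan/1",
                              clamped_cells = attr(scan, "clamped"),
                              comparisons = as.data.frame(scan)),
                         p, auto_unbox = TRUE, digits = NA)
  })

  say("writing dendrograms")
  paths$dendrograms <- vapply(dataset$time_grid, function(t) {
    em <- endpoint_matrix(dataset, layout, wavelength = 750, time = t,
                          include_control = config$include_control)
    d <- bray_curtis_matrix(em, warn_clamp = FALSE)
    f <- file.path(config$out_dir, "dendrograms",
                   sprintf("day_%s.nwk", format(t)))
    stage("dendrogram",
          write_atomic(f, function(p)
            upgma_dendrogram(d, linkage = config$linkage, file = p)))
    f
  }, character(1))

  paths$log <- file.path(config$out_dir, "run_log.txt")
  write_atomic(paths$log, function(p) writeLines(c(
    paste("pmcompare run", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste("input:", if (is.null(config$input_csv)) "simulated"
          else config$input_csv),
    paste("seed:", if (!is.null(sim)) sim$config$seed
          else format(config$permutations$seed)),
    paste("thresholds: lower", config$thresholds$lower, "upper",
          config$thresholds$upper, "endpoint day",
          config$thresholds$endpoint_day),
    paste("alpha:", config$thresholds$alpha),
    paste("n_perm:", config$permutations$n_perm),
    paste("permutation seed:", format(config$permutations$seed)),
    paste("linkage:", config$linkage),
    paste("clamped cells (Bray-Curtis):", attr(scan, "clamped")),
    paste("readings above 3.0:", attr(dataset, "n_above_upper"))
  ), p))

  say("done; artifacts in ", config$out_dir)
  invisible(list(dataset = dataset, summary = summary, census = cen,
                 scan = scan, truth = if (!is.null(sim)) sim$truth,
                 paths = paths))
}
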