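#' Pipeline configuration
#'
#' Declarative description of a full run: where the data come from (the
#' built-in simulator or files on disk), which analysis options to use, and
#' where outputs go. Exactly one input mode is active.
#'
#' @param mode `"simulate"` (generate data with [sim_config()] /
#'   scenario defaults) or `"files"` (ingest a tree and optional alignment).
#' @param scenario Simulation scenario name (simulate mode); see
#'   [generate_fixture_suite()].
#' @param sim Optional [sim_config()] overriding the scenario defaults.
#' @param tree_file Annotated NEXUS/newick path (files mode).
#' @param alignment_file Optional FASTA path (files mode); without it the
#'   saturation stage is skipped.
#' @param calibration_table Optional calibration TSV path; enables the
#'   prior-consistency stage.
#' @param out_dir Output directory.
#' @param seed Integer seed (simulate mode).
#' @param node_rate_mode Node-rate convention for [rate_age_points()].
#' @param intercept_mode,fixed_intercept Passed to [fit_exponential()].
#' @param include_tips Include tip nodes in the rate-time fit.
#' @param sat_model Distance correction for [saturation_table()].
#' @param n_bins Bins for [plateau_statistic()].
#' @param figure Figure format for the rate report (`"none"`, `"png"`,
#'   `"svg"`).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            scenario = "accelerating_clock", sim = NULL,
                            tree_file = NULL, alignment_file = NULL,
                            calibration_table = NULL,
                            out_dir = "pipeline_out", seed = 1L,
                            node_rate_mode = "annotation",
                            intercept_mode = "free", fixed_intercept = NULL,
                            include_tips = FALSE,
                            sat_model = "k2p", n_bins = 10L,
                            figure = "none") {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(tree_file))
    stop("files mode requires 'tree_file'")
  if (mode == "simulate" && (!is.null(tree_file) || !is.null(alignment_file)))
    stop("simulate mode must not also specify input files: exactly one ",
         "input mode is active")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(mode = mode, scenario = scenario, sim = sim,
                 tree_file = tree_file, alignment_file = alignment_file,
                 calibration_table = calibration_table, out_dir = out_dir,
                 seed = as.integer(seed), node_rate_mode = node_rate_mode,
                 intercept_mode = intercept_mode,
                 fixed_intercept = fixed_intercept,
                 include_tips = include_tips, sat_model = sat_model,
                 n_bins = as.integer(n_bins), figure = figure),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Reads a flat YAML file whose keys mirror the arguments of
#' [pipeline_config()]; `overrides` (e.g. from command-line flags) take
#' precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in workflow order — obtain data (simulate or ingest),
#' extract the node table, fit the exponential rate-time model, run the
#' saturation diagnostic, check calibrations against the dated tree — and
#' writes every product plus a JSON run manifest with the configuration
#' echo, per-stage status, and an MD5 checksum for each file written.
#' Identical configuration and seed produce byte-identical outputs. A stage
#' error aborts the run but still writes a manifest recording the failed
#' stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stages <- list()
  files <- character(0)
  config_echo <- unclass(config)
  config_echo$sim <- if (is.null(config$sim)) NULL else {
    s <- unclass(config$sim); s$base_freqs <- as.list(s$base_freqs); s
  }
  manifest <- list(tool = "cicadaclock",
                   version = as.character(utils::packageVersion("cicadaclock")),
                   seed = config$seed, config = config_echo)

  finish <- function(status) {
    manifest$stages <- stages
    manifest$status <- status
    checksums <- if (length(files) > 0L)
      as.list(unname(tools::md5sum(files))) else list()
    names(checksums) <- basename(files)
    manifest$files <- checksums
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    manifest
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- list(status = paste0("error: ", conditionMessage(res)))
      note("stage ", name, " FAILED: ", conditionMessage(res))
      manifest <- finish("failed")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    res
  }

  # -- stage 1: input ---------------------------------------------------------
  alignment <- NULL
  tree <- run_stage("input", function() {
    if (config$mode == "simulate") {
      sim <- if (!is.null(config$sim)) config$sim
             else .scenario_config(config$scenario, config$seed)
      note("input: simulating scenario '", config$scenario, "' (",
           sim$n_taxa, " taxa, seed ", sim$seed, ")")
      tr <- assign_branch_rates(simulate_yule_tree(sim), sim)
      alignment <<- simulate_alignment(tr, sim)
      tree_path <- file.path(config$out_dir, "simulated_tree.nex")
      write_annotated_nexus(tr, tree_path)
      fasta_path <- file.path(config$out_dir, "simulated_alignment.fasta")
      write_fasta(alignment, fasta_path)
      files <<- c(files, tree_path, fasta_path)
      tr
    } else {
      note("input: reading tree from ", config$tree_file)
      tr <- parse_annotated_nexus(readLines(config$tree_file, warn = FALSE))
      if (!is.null(config$alignment_file)) {
        note("input: reading alignment from ", config$alignment_file)
        alignment <<- read_alignment(config$alignment_file)
      }
      tr
    }
  })
  stages$input <- list(status = "ok",
                       n_tips = ape::Ntip(tree$phy),
                       root_age_ma = max(node_ages(tree)))

  # -- stage 2: node table ----------------------------------------------------
  tab <- run_stage("node_table", function() {
    tab <- node_table(tree, include_tips = TRUE)
    path <- file.path(config$out_dir, "node_table.tsv")
    write_node_table(tab, path)
    files <<- c(files, path)
    note("node_table: ", nrow(tab), " records")
    tab
  })
  stages$node_table <- list(status = "ok", n_records = nrow(tab))

  # -- stage 3: rate-time fit -------------------------------------------------
  fit <- run_stage("rate_fit", function() {
    pts <- rate_age_points(tree, node_rate_mode = config$node_rate_mode,
                           include_tips = config$include_tips)
    note("rate_fit: ", nrow(pts), " points (", attr(pts, "n_dropped"),
         " dropped for missing rates)")
    fit <- fit_exponential(pts, intercept_mode = config$intercept_mode,
                           fixed_intercept = config$fixed_intercept)
    written <- rate_report(pts, fit, config$out_dir, figure = config$figure)
    files <<- c(files, unname(written))
    fit
  })
  stages$rate_fit <- list(status = "ok", r0 = fit$r0, b = fit$b,
                          r_squared = fit$r_squared, n_points = fit$n_points)

  # -- stage 4: saturation ----------------------------------------------------
  if (is.null(alignment)) {
    stages$saturation <- list(status = "skipped: no alignment")
    note("saturation: skipped (no alignment)")
  } else {
    sat <- run_stage("saturation", function() {
      rec <- saturation_table(alignment, model = config$sat_model)
      path <- file.path(config$out_dir, "saturation_table.tsv")
      write_saturation_table(rec, path)
      files <<- c(files, path)
      note("saturation: ", nrow(rec), " pairs (", sum(rec$saturated),
           " saturated)")
      trend <- tryCatch(plateau_statistic(rec, n_bins = config$n_bins),
                        error = function(e) NULL)
      list(records = rec, trend = trend)
    })
    stages$saturation <- list(status = "ok", n_pairs = nrow(sat$records),
                              n_saturated = sum(sat$records$saturated),
                              ti_trend = if (is.null(sat$trend)) NA
                                         else sat$trend$ti_trend,
                              tv_trend = if (is.null(sat$trend)) NA
                                         else sat$trend$tv_trend)
  }

  # -- stage 5: calibration consistency --------------------------------------
  if (is.null(config$calibration_table)) {
    stages$calibration <- list(status = "skipped: no calibration table")
    note("calibration: skipped (no calibration table)")
  } else {
    cal_rep <- run_stage("calibration", function() {
      cals <- load_calibration_table(config$calibration_table)
      crep <- check_posterior_vs_prior(tree, cals)
      path <- file.path(config$out_dir, "calibration_report.tsv")
      utils::write.table(crep, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <<- c(files, path)
      note("calibration: ", nrow(crep), " calibrations checked (",
           sum(crep$status == "unresolvable"), " unresolvable, ",
           sum(crep$status == "flagged"), " flagged)")
      crep
    })
    stages$calibration <- list(status = "ok", n_checked = nrow(cal_rep),
                               n_flagged = sum(cal_rep$status == "flagged"),
                               n_unresolvable = sum(cal_rep$status == "unresolvable"))
  }

  invisible(finish("ok"))
}
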