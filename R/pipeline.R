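# End-to-end orchestration: simulate -> qc -> screen -> blasso -> cv /
# freq from a single flat configuration, with seeds recorded in a run
# manifest.  A thin command-line wrapper over this function ships in
# inst/scripts/tourney.R.

#' Default run configuration
#'
#' Flat key-value configuration understood by [run_pipeline()].  Any
#' subset may be overridden via a named list or a YAML file; unknown
#' keys are rejected.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "screen", "blasso"),
    out_dir = "tourney_run",
    seed = 1L,
    # simulate
    n = 384L, p = 11812L, chromosomes = 10L,
    maf_lo = 0.05, maf_hi = 0.5, ld_rho = 0.7,
    scenario = 3L, h2 = 0.25, mu = 100, magnitude = 1,
    # external inputs (used when "simulate" is absent)
    dosage_path = NULL, map_path = NULL, pheno_path = NULL,
    # qc
    call_rate_min = 0.98, het_sd_max = 3.0, maf_min = 0.03,
    # screen
    pg = 25L, mode = "random", target = 100L,
    # blasso
    iterations = 4000L, burn_in = 2000L, thin = 20L,
    # cv / freq
    k = 8L, marker_counts = c(100L, 250L, 500L),
    R = 100L, window = 5L, freq_min = 18L
  )
}

#' Read a run configuration
#'
#' @param path YAML file of flat key-value pairs; keys not in
#'   [default_config()] are an error.
#' @param overrides named list applied on top of the file.
#' @return merged configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(config))
  if (length(unknown))
    stop_("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(config, user)
}

#' Run the screening pipeline
#'
#' Executes the requested stages in the fixed order simulate, qc,
#' screen, blasso, cv, freq.  Every artifact is written under
#' `config$out_dir` and listed, with the master seed and stage
#' timings, in `manifest.yaml`.  Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config list as from [read_run_config()], or a path to a YAML
#'   config file.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  stages <- unlist(strsplit(as.character(config$stages), ","))
  stages <- trimws(stages)
  known <- c("simulate", "qc", "screen", "blasso", "cv", "freq")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_("unknown stage(s): ", paste(bad, collapse = ", "))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  artifacts <- character(0)
  timings <- list()
  note <- function(...) message("[tourney] ", ...)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  seed <- as.integer(config$seed)
  settings <- mcmc_settings(config$iterations, config$burn_in,
                            config$thin)

  panel <- NULL; phen <- NULL; effects <- NULL; y <- NULL

  if ("simulate" %in% stages) {
    note("simulate: n=", config$n, " p=", config$p,
         " scenario=", config$scenario, " h2=", config$h2)
    tick("simulate", {
      panel <- simulate_panel(config$n, config$p, config$chromosomes,
                               c(config$maf_lo, config$maf_hi),
                               config$ld_rho, seed = seed)
      effects <- plant_effects(panel, config$scenario,
                                magnitude = config$magnitude, seed = seed)
      phen <- simulate_phenotypes(panel, effects, h2 = config$h2,
                                   mu = config$mu, seed = seed)
      y <- phen$y
      write_panel(panel, file.path(out, "dosages.tsv"),
                  file.path(out, "map.tsv"))
      write_truth(effects, phen, file.path(out, "effects_true.tsv"),
                  file.path(out, "phenotypes.tsv"))
    })
    artifacts <- c(artifacts, "dosages.tsv", "map.tsv",
                   "effects_true.tsv", "phenotypes.tsv")
  } else {
    if (is.null(config$dosage_path) || is.null(config$map_path))
      stop_("without the simulate stage, dosage_path and map_path ",
            "must be given")
    panel <- read_panel(config$dosage_path, config$map_path)
    if (!is.null(config$pheno_path))
      y <- align_phenotypes(panel, read_phenotypes(config$pheno_path))
  }

  if ("qc" %in% stages) {
    note("qc: call_rate>=", config$call_rate_min,
         " |het|<=", config$het_sd_max, "SD maf>=", config$maf_min)
    tick("qc", {
      s <- filter_samples(panel, config$call_rate_min, config$het_sd_max)
      m <- filter_markers(s$panel, config$maf_min)
      report <- new_qc_report(rbind(s$report$removed, m$report$removed),
                              c(s$report$thresholds,
                                m$report$thresholds))
      if (!is.null(y)) y <- y[rownames(m$panel$dosages)]
      panel <- m$panel
      # (panel and y updated in the enclosing frame)
      write_qc_report(report, file.path(out, "qc_report.tsv"))
    })
    artifacts <- c(artifacts, "qc_report.tsv")
  }

  tour <- NULL
  if ("screen" %in% stages) {
    if (is.null(y)) stop_("screening needs phenotypes")
    note("screen: pg=", config$pg, " mode=", config$mode,
         " target=", config$target)
    tour <- tick("screen",
                 tournament(panel, y, target = config$target,
                            pg = config$pg, mode = config$mode,
                            seed = seed))
    write_tournament(tour, out)
    artifacts <- c(artifacts, "survivors.txt", "ranking.txt",
                   "stage_log.tsv")
  }

  fit <- NULL
  if ("blasso" %in% stages) {
    if (is.null(y)) stop_("blasso needs phenotypes")
    ids <- if (!is.null(tour)) tour$survivors else panel$map$marker_id
    note("blasso: ", length(ids), " markers, ",
         settings$iterations, " iterations")
    fit <- tick("blasso",
                blasso(panel$dosages[, ids, drop = FALSE], y,
                       settings = settings, seed = seed))
    write_beta_summary(fit, file.path(out, "beta_summary.tsv"))
    artifacts <- c(artifacts, "beta_summary.tsv")
  }

  if ("cv" %in% stages) {
    if (is.null(y)) stop_("cv needs phenotypes")
    rank_full <- if (!is.null(tour)) ranking(tour) else
      attr(select_top_by_estimate(
        fit %||% stop_("cv needs a screen or blasso stage"), 1L),
        "ranking")
    counts <- config$marker_counts[config$marker_counts <=
                                     n_markers(panel)]
    note("cv: k=", config$k, " counts=", paste(counts, collapse = ","))
    cv <- tick("cv",
               kfold_cv(panel, y, marker_counts = counts,
                        ranking = rank_full, k = config$k,
                        settings = settings, seed = seed,
                        gbv_true = phen$gbv_true))
    utils::write.table(cv$folds, file.path(out, "cv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "cv.tsv")
  }

  if ("freq" %in% stages) {
    note("freq: R=", config$R)
    selector <- function(p, y_r, s)
      tournament(p, y_r, target = config$target, pg = config$pg,
                 mode = config$mode, seed = s)$survivors
    freq <- tick("freq", {
      if (!is.null(effects))
        selection_frequency(panel, selector, R = config$R,
                            effects = effects, h2 = config$h2,
                            mu = config$mu, seed = seed)
      else
        selection_frequency(panel, selector, R = config$R, y = y,
                            seed = seed)
    })
    utils::write.table(
      data.frame(marker_id = names(freq$counts),
                 frequency = unname(freq$counts)),
      file.path(out, "selection_frequency.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "selection_frequency.tsv")
  }

  manifest <- list(
    package = "tourney",
    version = as.character(utils::packageVersion("tourney")),
    seed = seed,
    stages = stages,
    config = config[setdiff(names(config), c("stages", "out_dir"))],
    artifacts = artifacts,
    timings_sec = timings)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}
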