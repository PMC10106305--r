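# End-to-end pipeline: preprocess -> discover -> SEM -> indices -> stability
# (optional) -> pathway / rolled-cycle reports, with all outputs and a JSON
# manifest written to a run directory.  Fully reproducible from the manifest:
# the PAG, SEM table and stability report are byte-identical across runs with
# the same config and seed.

#' Run the full discovery-and-estimation pipeline
#'
#' The config is a YAML file or an R list with fields:
#' \describe{
#'   \item{input}{Path to a CSV of numeric columns, \emph{or}}
#'   \item{simulation}{`list(published_model = TRUE, n = ..., seed = ...)` or
#'     `list(spec = "model.yaml")` to simulate the input instead.}
#'   \item{variables}{Optional list of variable definitions (`name`, `items`,
#'     `agg`, `transform`, `standardize`) applied with [derive_variables()].}
#'   \item{knowledge}{`tiers`: list of character vectors; `forbidden`: list of
#'     `[from, to]` pairs; `uncaused`: variables nothing may cause.}
#'   \item{params}{`alpha` (default 0.01), `penalty_discount` (default 1).}
#'   \item{stability}{Optional `mode`, `reps`, `frac`.}
#'   \item{outcomes}{Node names for pathway reports.}
#'   \item{pairs}{Optional rolled-cycle pairing: list of `concept`,
#'     `baseline`, `followup`.}
#'   \item{seed}{Master seed for simulation and resampling.}
#' }
#'
#' @param config A list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main objects (`data`, `pag`, `fit`,
#'   `stability`, `paths`, `cycles`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) {
      rlang::abort(paste0("Config file not found: ", config),
                   class = "causalpaths_missing_file")
    }
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  # --- input ---
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) {
      rlang::abort(paste0("Input file not found: ", config$input),
                   class = "causalpaths_missing_file")
    }
    dat <- readr::read_csv(config$input, show_col_types = FALSE)
    timepoints <- NULL
  } else if (!is.null(config$simulation)) {
    sim <- config$simulation
    spec <- if (isTRUE(sim$published_model)) {
      build_published_model(n = sim$n %||% 1000, seed = sim$seed %||% seed)
    } else if (!is.null(sim$spec)) {
      read_sim_spec(sim$spec)
    } else {
      rlang::abort("`simulation` must set `published_model: true` or `spec:`.",
                   class = "causalpaths_bad_config")
    }
    dat <- simulate(spec)
    timepoints <- attr(dat, "timepoints")
    readr::write_csv(dat, file.path(out_dir, "data.csv"))
  } else {
    rlang::abort("Config needs `input` or `simulation`.",
                 class = "causalpaths_bad_config")
  }

  # --- preprocessing ---
  excluded <- 0L
  if (!is.null(config$variables)) {
    defs <- lapply(config$variables, function(v) {
      variable_def(v$name, unlist(v$items), agg = v$agg %||% "sum",
                   transform = v$transform %||% "none",
                   standardize = isTRUE(v$standardize))
    })
    dat <- derive_variables(dat, defs)
  }
  cc <- complete_case_filter(dat)
  dat <- cc$data
  excluded <- cc$n_excluded
  if (nrow(dat) == 0L) {
    rlang::abort("No complete cases remain after filtering.",
                 class = "causalpaths_bad_data")
  }

  # --- knowledge ---
  kcfg <- config$knowledge %||% list()
  k <- knowledge(tiers = lapply(kcfg$tiers %||% list(), unlist),
                 forbidden = if (length(kcfg$forbidden)) {
                   do.call(rbind, lapply(kcfg$forbidden, function(x) {
                     data.frame(from = x[[1]], to = x[[2]])
                   }))
                 } else NULL)
  for (v in kcfg$uncaused %||% character()) {
    k <- forbid_all_causes(k, v, names(dat))
  }
  if (is.null(config$knowledge) && !is.null(timepoints)) {
    k <- knowledge(tiers = list(names(timepoints)[timepoints == "baseline"],
                                names(timepoints)[timepoints == "six_month"]))
  }

  pcfg <- config$params %||% list()
  params <- analysis_params(alpha = pcfg$alpha %||% 0.01,
                            penalty_discount = pcfg$penalty_discount %||% 1)

  # --- discovery ---
  pag <- gfci(dat, params, k)
  write_graph(attr(pag, "cpdag"), file.path(out_dir, "cpdag.txt"))
  write_graph(pag, file.path(out_dir, "pag.txt"))

  # --- SEM ---
  spec_sem <- pag_to_sem(pag)
  fit <- fit_sem(spec_sem, dat)
  readr::write_csv(tidy(fit), file.path(out_dir, "sem.csv"))
  jsonlite::write_json(as.list(glance(fit)), file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- stability (optional) ---
  stab <- NULL
  if (!is.null(config$stability)) {
    scfg <- config$stability
    sp <- stability_params(mode = scfg$mode %||% "jackknife",
                           reps = scfg$reps %||% 100,
                           frac = scfg$frac %||% 0.9,
                           seed = scfg$seed %||% seed)
    stab <- resample_stability(dat, params, k, sp, reference = pag)
    readr::write_csv(tidy(stab), file.path(out_dir, "stability.csv"))
  }

  # --- reports ---
  paths <- NULL
  if (!is.null(config$outcomes)) {
    paths <- dplyr::bind_rows(lapply(unlist(config$outcomes), function(o) {
      dplyr::mutate(causal_paths_to(pag, o, include_possible = TRUE), outcome = o)
    }))
    jsonlite::write_json(
      lapply(split(paths$label, paths$outcome), as.list),
      file.path(out_dir, "pathways.json"), auto_unbox = TRUE)
  }
  cycles <- NULL
  if (!is.null(config$pairs)) {
    pr <- dplyr::bind_rows(lapply(config$pairs, tibble::as_tibble))
    cycles <- rolled_graph(pag, pr, es = fit)
    readr::write_csv(cycles, file.path(out_dir, "rolled_cycles.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("causalpaths")),
    seed = seed,
    n = nrow(dat), p = ncol(dat), n_excluded = excluded,
    params = list(alpha = params$alpha, penalty_discount = params$penalty_discount),
    knowledge = list(tiers = k$tiers, n_forbidden = nrow(k$forbidden)),
    outputs = list.files(out_dir),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = dat, knowledge = k, pag = pag, fit = fit,
                 stability = stab, paths = paths, cycles = cycles,
                 manifest = manifest))
}
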