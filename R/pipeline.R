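#' Bundled scenario configurations
#'
#' Three scenarios mirror the laboratory reactors the analysis was
#' designed around, calibrated from their printed endpoint rates and
#' activation energies: `lactate_2L` (k_max 0.144 mmol/L.h, Ea 19.0/65.7
#' kJ/mol, 2 L), `lactate_8L` (0.128 mmol/L.h, 30.6/63.4 kJ/mol, 8 L) and
#' `acetate_2L` (0.127 mmol/L.h, 50.4/209.9 kJ/mol, 2 L, acetate-fed).
#'
#' @param name Scenario name.
#' @param seed Integer seed recorded in the config.
#' @return A nested run-config list with sections `feed`, `kinetics`,
#'   `schedule`, `noise`, `asv` and `analysis`.
#' @examples
#' cfg <- scenario_config("lactate_2L")
#' @export
scenario_config <- function(name = c("lactate_2L", "lactate_8L", "acetate_2L"),
                            seed = 1) {
  name <- match.arg(name)
  base <- list(
    scenario = name,
    seed = as.integer(seed),
    volume = 2,
    feed = list(sulphate_g_l = 1.0, carbon_source = "lactate",
                carbon_mmol_l = NULL, yeast_extract_acetate_rate = 0.01),
    kinetics = as.list(unclass(kinetic_params())),
    schedule = list(hrt = 48, stage_temps_c = c(30, 25, 20, 15, 10),
                    stage_duration_rt = 6, disruption_interval = 3,
                    harvest_interval = 6, sample_interval = 24),
    noise = list(cv = 0.05),
    asv = list(read_depth = 35000, overdispersion = 200,
               temperatures = c(30, 10)),
    analysis = list(arrhenius_mode = "fixed", boundary_temp_c = 15,
                    n_window = 3, dt = 0.1)
  )
  switch(name,
    lactate_2L = base,
    lactate_8L = {
      base$volume <- 8
      base$kinetics$k_max <- 0.128
      base$kinetics$Ea_above <- 30600
      base$kinetics$Ea_below <- 63400
      base
    },
    acetate_2L = {
      base$feed$carbon_source <- "acetate"
      base$kinetics$k_max <- 0.127
      base$kinetics$Ea_above <- 50400
      base$kinetics$Ea_below <- 209900
      base$kinetics$ferm_fraction <- 0
      base
    }
  )
}

#' Read / write a run configuration
#'
#' Run configurations are stored as a single structured YAML file with
#' sections `feed`, `kinetics`, `schedule`, `noise`, `asv`, `analysis`
#' plus `scenario`, `seed` and `volume` keys. Unknown keys are rejected.
#'
#' @param path File path.
#' @param config A config list as from [scenario_config()].
#' @return `read_run_config` returns the config list; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("scenario", "seed", "volume", "feed", "kinetics", "schedule",
             "noise", "asv", "analysis")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(paste0("Unknown config sections: ", paste(extra, collapse = ", ")),
      class = "lfcr_config_error")
  }
  defaults <- scenario_config(cfg$scenario %||% "lactate_2L", seed = cfg$seed %||% 1)
  for (sec in c("feed", "kinetics", "schedule", "noise", "asv", "analysis")) {
    if (!is.null(cfg[[sec]])) defaults[[sec]] <- modifyList(defaults[[sec]], cfg[[sec]])
  }
  for (key in c("seed", "volume")) {
    if (!is.null(cfg[[key]])) defaults[[key]] <- cfg[[key]]
  }
  defaults
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_objects <- function(config) {
  feed <- do.call(feed_spec, config$feed)
  params <- do.call(kinetic_params, config$kinetics)
  schedule <- do.call(reactor_schedule, config$schedule)
  list(feed = feed, params = params, schedule = schedule)
}

#' Run a full analysis scenario
#'
#' Orchestrates simulate -> stage summaries -> flux partition -> Arrhenius
#' fit -> sulphur ledgers -> ASV diversity for one configuration, writing
#' all tabular artifacts and a machine-readable manifest (config hash,
#' seed, versions) into `out_dir`. Re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config Run config list (see [scenario_config()],
#'   [read_run_config()]).
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @param seed Overrides `config$seed` if given.
#' @return (Invisibly) a list with elements `sim`, `summaries`,
#'   `partition`, `arrhenius`, `ledgers`, `asv_table`, `diversity`,
#'   `shifts`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_config("lactate_2L"), out_dir = NULL)
#' glance(res$arrhenius)
#' }
#' @export
run_scenario <- function(config = scenario_config("lactate_2L"),
                         out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        class = "lfcr_stage_error", parent = e)
    })
  }

  obj <- run_stage("config", config_objects(config))

  sim <- run_stage("simulate", simulate_reactor(
    obj$feed, obj$params, obj$schedule,
    noise_cv = config$noise$cv, seed = config$seed,
    volume = config$volume, dt = config$analysis$dt %||% 0.1
  ))

  summaries <- run_stage("summarise", stage_summaries(
    sim$samples, obj$feed, obj$schedule, n_window = config$analysis$n_window %||% 3
  ))

  partition <- run_stage("partition", partition_stages(summaries, obj$feed))

  arr <- run_stage("arrhenius", {
    pts <- arrhenius_points(summaries)
    arrhenius_fit(pts, mode = config$analysis$arrhenius_mode %||% "fixed",
                  boundary_temp_c = config$analysis$boundary_temp_c)
  })

  ledgers <- run_stage("balance", stage_ledgers(
    summaries, sim$harvests,
    dplyr::filter(sim$samples, .data$port == "effluent"),
    obj$schedule, volume = config$volume
  ))

  asv_cfg <- config$asv
  design <- run_stage("diversity", asv_design(
    default_asv_taxa(),
    read_depth = asv_cfg$read_depth %||% 35000,
    overdispersion = asv_cfg$overdispersion %||% 200
  ))
  asv_table <- run_stage("diversity", generate_asv_table(
    design, temperatures = asv_cfg$temperatures %||% c(30, 10),
    seed = config$seed + 1000L
  ))
  diversity <- run_stage("diversity", diversity_table(asv_table))
  temps <- asv_cfg$temperatures %||% c(30, 10)
  shifts <- run_stage("diversity", shift_table(
    asv_table, warm_c = max(temps), cold_c = min(temps), rank = "class"
  ))

  manifest <- list(
    scenario = config$scenario,
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("lfcrtemp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_samples = nrow(sim$samples),
    n_harvests = nrow(sim$harvests)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    readr::write_csv(sim$samples, p("samples.csv"))
    readr::write_csv(sim$harvests, p("harvests.csv"))
    readr::write_csv(sim$truth, p("truth.csv"))
    readr::write_csv(summaries, p("stage_summaries.csv"))
    readr::write_csv(partition, p("flux_partition.csv"))
    readr::write_csv(tidy(arr), p("arrhenius_segments.csv"))
    readr::write_csv(glance(arr), p("arrhenius_model.csv"))
    readr::write_csv(arrhenius_plot_table(arr), p("arrhenius_points.csv"))
    readr::write_csv(ledgers, p("sulphur_ledgers.csv"))
    readr::write_tsv(asv_table, p("asv_table.tsv"))
    readr::write_csv(diversity, p("diversity.csv"))
    readr::write_csv(shifts, p("abundance_shifts.csv"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  }

  invisible(list(
    sim = sim, summaries = summaries, partition = partition, arrhenius = arr,
    ledgers = ledgers, asv_table = asv_table, diversity = diversity,
    shifts = shifts, manifest = manifest
  ))
}

#' Validate analysis input tables
#'
#' Schema and sanity checks on sample records, harvest records and ASV
#' tables: required columns, non-negative concentrations, temperatures in
#' a plausible range (-5 to 60 degC), and (given a schedule) coverage of
#' every temperature stage by at least one sample. Issues are reported,
#' not raised, unless `strict = TRUE`.
#'
#' @param samples Sample-record tibble (or path to its CSV).
#' @param harvests Optional harvest tibble (or CSV path).
#' @param asv Optional ASV table (or TSV path).
#' @param schedule Optional [reactor_schedule()] for stage-coverage
#'   checks.
#' @param strict Raise an error if any issue is found.
#' @return A tibble of issues (`table`, `row`, `column`, `message`);
#'   zero rows when everything passes.
#' @export
validate_inputs <- function(samples, harvests = NULL, asv = NULL,
                            schedule = NULL, strict = FALSE) {
  read_maybe <- function(x, reader) if (is.character(x)) reader(x) else x
  samples <- read_maybe(samples, function(f) readr::read_csv(f, show_col_types = FALSE))
  harvests <- read_maybe(harvests, function(f) readr::read_csv(f, show_col_types = FALSE))
  asv <- read_maybe(asv, function(f) readr::read_tsv(f, show_col_types = FALSE))

  issues <- list()
  add <- function(table, row, column, message) {
    issues[[length(issues) + 1]] <<- tibble(
      table = table, row = row, column = column, message = message
    )
  }

  sample_cols <- c("time_h", "port", "temp_C", "sulphate_mmol_L", "sulphide_mmol_L",
                   "lactate_mmol_L", "acetate_mmol_L", "propionate_mmol_L")
  for (col in setdiff(sample_cols, names(samples))) {
    add("samples", NA_integer_, col, "required column missing")
  }
  conc_cols <- intersect(grep("_mmol_L$", sample_cols, value = TRUE), names(samples))
  for (col in conc_cols) {
    bad <- which(samples[[col]] < 0)
    for (r in bad) add("samples", r, col, "negative concentration")
  }
  if ("temp_C" %in% names(samples)) {
    bad <- which(samples$temp_C < -5 | samples$temp_C > 60)
    for (r in bad) add("samples", r, "temp_C", "temperature outside -5..60 degC")
  }
  if (!is.null(schedule) && "time_h" %in% names(samples)) {
    for (i in seq_len(nrow(schedule$stages))) {
      st <- schedule$stages[i, ]
      n_in <- sum(samples$time_h > st$start_h & samples$time_h <= st$end_h)
      if (n_in == 0) {
        add("samples", NA_integer_, "time_h",
            sprintf("no samples cover stage %d (%g degC)", st$stage, st$temp_c))
      }
    }
  }

  if (!is.null(harvests)) {
    harvest_cols <- c("time_h", "dry_mass_g", "frac_C", "frac_H", "frac_N", "frac_S")
    for (col in setdiff(harvest_cols, names(harvests))) {
      add("harvests", NA_integer_, col, "required column missing")
    }
    if (all(c("frac_C", "frac_H", "frac_N", "frac_S") %in% names(harvests))) {
      tot <- harvests$frac_C + harvests$frac_H + harvests$frac_N + harvests$frac_S
      for (r in which(tot > 1 + 1e-6)) {
        add("harvests", r, "frac_*", "CHNS fractions sum above 1")
      }
    }
    if ("dry_mass_g" %in% names(harvests)) {
      for (r in which(harvests$dry_mass_g < 0)) {
        add("harvests", r, "dry_mass_g", "negative dry mass")
      }
    }
  }

  if (!is.null(asv)) {
    for (col in setdiff(c("asv_id", "taxonomy"), names(asv))) {
      add("asv", NA_integer_, col, "required column missing")
    }
    count_cols <- setdiff(names(asv), c("asv_id", "taxonomy"))
    for (col in count_cols) {
      for (r in which(asv[[col]] < 0)) add("asv", r, col, "negative count")
    }
  }

  report <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble(table = character(), row = integer(), column = character(),
           message = character())
  }
  if (strict && nrow(report) > 0) {
    abort(sprintf("Input validation failed with %d issue(s).", nrow(report)),
      class = "lfcr_validation_error")
  }
  report
}
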