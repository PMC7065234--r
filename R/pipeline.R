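#' Run a complete analysis from a configuration
#'
#' Configuration-driven orchestration of the three analyses:
#' * `"titration"` — simulate (or load) a detergent titration of spectra, run
#'   peak picking, adduct assignment and bound-fraction quantification per
#'   concentration, fit the competitive displacement model per lipid class,
#'   classify classes and adduct positions as annular or non-annular.
#' * `"kinetics"` — simulate (or load) per-site binding/contact traces,
#'   binarize with the dual-cutoff scheme, extract gap-merged dwells, estimate
#'   censored-MLE k_off with bootstrap confidence intervals, and compare sites.
#' * `"accessibility"` — per-conformational-state residue contact frequencies.
#'
#' The run is deterministic given the config and seed. Every parameter used —
#' including defaults that were not explicitly set — is recorded in the
#' report's log, and the provenance block (config hash, seed, version) is
#' sufficient to re-run the report.
#'
#' @param config A configuration list, a path to a YAML config, or a fixture
#'   name. Recognised fields: `analysis` (`"titration"`, `"kinetics"`,
#'   `"accessibility"`; defaults to the fixture's), `fixture` (fixture name or
#'   YAML path) *or* `inputs` (named file paths: `contact_table` for kinetics /
#'   accessibility, `series` CSV for a titration fit of pre-quantified bound
#'   fractions), `params` (module parameter overrides), `seed`, `output_dir`.
#' @param output_dir Where to write `report.json`, one TSV per table, and
#'   `run.log`; overrides the config's entry. `NULL` writes nothing.
#' @return A `lipidex_report`: list with `analysis`, `tables` (named list of
#'   tibbles), `provenance`, `log`.
#' @export
run_analysis <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config) && grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      list(fixture = config)
    }
  }
  if (!is.list(config)) {
    abort_param("`config` must be a list, a YAML path, or a fixture name.")
  }

  fixture_cfg <- NULL
  if (!is.null(config$fixture)) {
    fixture_cfg <- load_fixture(config$fixture)
  }

  problems <- character()
  if (is.null(fixture_cfg) && is.null(config$inputs)) {
    problems <- c(problems, "one of `fixture` or `inputs` must be given")
  }
  if (!is.null(fixture_cfg) && !is.null(config$inputs)) {
    problems <- c(problems, "give `fixture` or `inputs`, not both")
  }
  analysis <- config$analysis %||% fixture_cfg$analysis
  if (is.null(analysis) ||
      !analysis %in% c("titration", "kinetics", "accessibility")) {
    problems <- c(problems,
                  "`analysis` must be one of titration, kinetics, accessibility")
  }
  seed <- config$seed %||% fixture_cfg$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    problems <- c(problems, "`seed` must be a single finite number")
  }
  params <- config$params %||% list()
  if (!is.list(params)) problems <- c(problems, "`params` must be a list")
  if (length(problems) > 0) {
    abort(paste0("Invalid configuration:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "lipidex_error_config")
  }

  result <- switch(
    analysis,
    titration = run_titration(fixture_cfg, config$inputs, params, seed),
    kinetics = run_kinetics(fixture_cfg, config$inputs, params, seed),
    accessibility = run_accessibility(fixture_cfg, config$inputs, params, seed)
  )

  provenance_cfg <- config
  provenance_cfg$output_dir <- NULL
  report <- structure(
    list(
      analysis = analysis,
      tables = result$tables,
      provenance = list(
        config = provenance_cfg,
        config_hash = rlang::hash(provenance_cfg),
        seed = seed,
        package_version = as.character(utils::packageVersion("lipidex"))
      ),
      log = result$log
    ),
    class = "lipidex_report"
  )

  output_dir <- output_dir %||% config$output_dir
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# Resolve a parameter with default-tracking for the run log.
resolve_params <- function(params, defaults) {
  log <- character()
  out <- defaults
  for (nm in names(defaults)) {
    if (!is.null(params[[nm]])) {
      out[[nm]] <- params[[nm]]
      log <- c(log, sprintf("param %s = %s (set)", nm, format(params[[nm]])))
    } else {
      log <- c(log, sprintf("param %s = %s (default)", nm, format(defaults[[nm]])))
    }
  }
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown parameter(s): %s", paste(unknown, collapse = ", ")),
          class = "lipidex_error_config")
  }
  list(params = out, log = log)
}

run_titration <- function(fixture_cfg, inputs, params, seed) {
  params <- utils::modifyList(fixture_cfg$analysis_params %||% list(), params)
  rp <- resolve_params(params, list(
    min_snr = 3, min_spacing_mz = 5, tolerance_da = 2.5,
    detection_threshold = 0.03, r_threshold = 0.5, noise_sd = NA_real_
  ))
  p <- rp$params

  if (!is.null(inputs)) {
    # pre-quantified bound fractions: fit and classify only
    series <- readr::read_csv(inputs$series, show_col_types = FALSE,
                              progress = FALSE)
    cmc <- inputs$cmc %||% 0
    lipid_conc <- unlist(inputs$lipid_conc)
    fit <- fit_competition(series, lipid_conc = lipid_conc, cmc = cmc,
                           r_threshold = p$r_threshold,
                           detection_threshold = p$detection_threshold)
    return(list(tables = list(series = as_tibble(series), fits = tidy(fit),
                              classification = classify_exchange(fit, p$r_threshold)),
                log = rp$log))
  }

  fx <- fixture_spectrum(fixture_cfg)
  if (is.finite(p$noise_sd)) fx$noise_sd <- p$noise_sd
  concs <- unlist(fixture_cfg$titration$detergent_concs)
  sim <- simulate_titration(fx, concs, seed = seed)
  candidates <- fixture_candidates(fx)
  max_adducts <- sum(fx$lipids$n_sites)

  per_conc <- lapply(seq_along(concs), function(i) {
    peaks <- pick_peaks(sim$spectra[[i]], min_snr = p$min_snr,
                        min_spacing_mz = p$min_spacing_mz)
    asg <- assign_adducts(peaks, fx$protein, candidates,
                          max_adducts = max_adducts,
                          tolerance_da = p$tolerance_da)
    list(
      fractions = quantify_bound_fractions(asg) |>
        mutate(detergent_conc = concs[i]),
      avg_charge = tibble(detergent_conc = concs[i],
                          average_charge = average_charge(asg)),
      n_unassigned = sum(!asg$assigned)
    )
  })

  count_series <- lapply(per_conc, `[[`, "fractions") |>
    list_rbind() |>
    select("detergent_conc", "lipid_class", "n_bound", "fraction")
  series <- count_series |>
    filter(.data$lipid_class != "any") |>
    group_by(.data$detergent_conc, .data$lipid_class) |>
    summarise(bound_fraction = sum(.data$fraction[.data$n_bound >= 1]),
              .groups = "drop")

  lipid_conc <- fx$lipids |>
    distinct(.data$lipid_class, .data$conc)
  lipid_conc <- setNames(lipid_conc$conc, lipid_conc$lipid_class)
  fit <- fit_competition(series, lipid_conc = lipid_conc,
                         cmc = fx$detergent$cmc,
                         r_threshold = p$r_threshold,
                         detection_threshold = p$detection_threshold)
  positions <- retention_by_position(
    filter(count_series, .data$lipid_class != "any"),
    r_threshold = p$r_threshold,
    detection_threshold = p$detection_threshold
  )

  list(
    tables = list(
      series = series,
      count_series = count_series,
      fits = tidy(fit),
      classification = classify_exchange(fit, p$r_threshold),
      positions = positions,
      average_charge = lapply(per_conc, `[[`, "avg_charge") |> list_rbind(),
      truth = sim$truth
    ),
    log = c(rp$log,
            sprintf("unassigned peaks per concentration: %s",
                    paste(vapply(per_conc, `[[`, 0, "n_unassigned"),
                          collapse = ", ")))
  )
}

run_kinetics <- function(fixture_cfg, inputs, params, seed) {
  rp <- resolve_params(params, list(
    d_on = 0.55, d_off = 1.0, gap_tolerance_ns = 5, n_boot = 500
  ))
  p <- rp$params

  if (!is.null(inputs)) {
    trace <- read_contact_table(inputs$contact_table)
  } else {
    # protomer replicates are simulated as separate traces (site_id::repN) so
    # dwell extraction never fuses events across replicates, then pooled per
    # site after extraction
    kin <- fixture_cfg$kinetics
    n_prot <- kin$n_protomers %||% 1
    traces <- list()
    idx <- 0
    for (site in fixture_cfg$sites) {
      for (prot in seq_len(n_prot)) {
        idx <- idx + 1
        traces[[idx]] <- simulate_contact_trace(
          k_on = site$k_on, k_off = site$k_off,
          duration_ns = kin$duration_ns, dt_ns = kin$dt_ns,
          rattle_rate = kin$rattle_rate %||% 0,
          rattle_mean = kin$rattle_mean %||% 2,
          seed = seed + idx,
          site_id = paste0(site$site_id, "::rep", prot),
          output = kin$output %||% "state"
        )
      }
    }
    dt <- attr(traces[[1]], "dt_ns")
    trace <- new_contact_trace(list_rbind(traces), dt_ns = dt)
  }

  binary <- binarize_contacts(trace, d_on = p$d_on, d_off = p$d_off)
  dwells <- extract_dwells(binary, gap_tolerance_ns = p$gap_tolerance_ns)
  if (is.null(inputs)) {
    dwells$site_id <- sub("::rep[0-9]+$", "", dwells$site_id)
  }

  estimates <- estimate_koff(dwells, n_boot = p$n_boot, seed = seed)
  comparison <- compare_sites(estimates)
  curves <- survival_curve(dwells)
  crosscheck <- koff_from_survival(curves)
  occ <- site_occupancy(binary)
  if (is.null(inputs)) {
    occ <- occ |>
      mutate(site_id = sub("::rep[0-9]+$", "", .data$site_id)) |>
      group_by(.data$site_id) |>
      summarise(occupancy = mean(.data$occupancy), .groups = "drop")
  }

  list(
    tables = list(
      dwell_summary = dwells |>
        group_by(.data$site_id) |>
        summarise(n_events = dplyr::n(), n_censored = sum(.data$censored),
                  mean_dwell_ns = mean(.data$duration_ns),
                  max_dwell_ns = max(.data$duration_ns), .groups = "drop"),
      koff = estimates,
      fold_ratios = comparison$pairs,
      survival = curves,
      koff_crosscheck = crosscheck,
      occupancy = occ
    ),
    log = rp$log
  )
}

run_accessibility <- function(fixture_cfg, inputs, params, seed) {
  rp <- resolve_params(params, list(d_contact = 0.7))
  p <- rp$params

  if (!is.null(inputs)) {
    contacts <- readr::read_csv(inputs$contact_table, show_col_types = FALSE,
                                progress = FALSE)
  } else {
    acc <- fixture_cfg$accessibility
    if (is.null(acc)) {
      abort_input("Fixture has no `accessibility` section.")
    }
    k_off_base <- acc$k_off_base %||% 50
    contacts <- lapply(seq_along(acc$cells), function(i) {
      cell <- acc$cells[[i]]
      k_on <- if (cell$occupancy <= 0) 0 else
        k_off_base * cell$occupancy / (1 - cell$occupancy)
      tr <- simulate_contact_trace(
        k_on = k_on, k_off = k_off_base,
        duration_ns = acc$duration_ns, dt_ns = acc$dt_ns,
        seed = seed + 100 + i, site_id = cell$residue, output = "distance"
      )
      tr |>
        mutate(state = cell$state, residue = cell$residue) |>
        select("state", "residue", "frame", "distance_nm")
    }) |>
      list_rbind()
  }

  profile <- contact_frequency(contacts, d_contact = p$d_contact)
  matrix_table <- tidyr::pivot_wider(
    profile |> select("state", "residue", "contact_frequency"),
    names_from = "residue", values_from = "contact_frequency"
  )
  list(
    tables = list(accessibility = profile, accessibility_matrix = matrix_table),
    log = rp$log
  )
}

#' Write a report to disk
#'
#' Writes `report.json` (tables + provenance; byte-identical across reruns of
#' the same config and seed), one TSV per table, and `run.log` (timestamped
#' parameter log).
#'
#' @param report A `lipidex_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    tab <- report$tables[[nm]]
    tab <- tab[, !vapply(tab, is.list, TRUE), drop = FALSE]
    readr::write_tsv(as_tibble(tab), file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  json <- jsonlite::toJSON(
    list(analysis = report$analysis,
         tables = lapply(report$tables, function(tab) {
           as.data.frame(tab[, !vapply(tab, is.list, TRUE), drop = FALSE])
         }),
         provenance = report$provenance),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null"
  )
  writeLines(json, file.path(dir, "report.json"))
  writeLines(c(sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("config hash %s", report$provenance$config_hash),
               report$log),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.lipidex_report <- function(x, ...) {
  cat(sprintf("lipidex %s report (seed %s, config %s)\n",
              x$analysis, x$provenance$seed, x$provenance$config_hash))
  for (nm in names(x$tables)) {
    cat(sprintf("\n== %s ==\n", nm))
    print(x$tables[[nm]], n = 10)
  }
  invisible(x)
}
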