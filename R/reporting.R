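# Configuration-driven pipeline entry points, run manifests and tabular
# reporting. CSV is the single results interchange format; plots are optional
# and never load-bearing.

default_config <- function() {
  list(
    seed = 1L,
    iterations = 100L,
    years = 100L,
    pedigree = NULL,
    population = list(n_founders = 7L, generations = 6L, cohort_size = 120L,
                      initial_n = NULL),
    params = NULL,           # list(p2013 = path, p2017 = path) or NULL
    scenario = list(use = "2017"),
    surface = list(caps = round(seq(100, 1000, length.out = 10)))
  )
}

load_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  out <- utils::modifyList(base, cfg)
  out$seed <- as.integer(out$seed)
  out$iterations <- as.integer(out$iterations)
  out$years <- as.integer(out$years)
  out
}

config_parameter_sets <- function(cfg) {
  if (is.null(cfg$params)) return(default_parameter_sets())
  for (nm in c("p2013", "p2017")) {
    if (is.null(cfg$params[[nm]])) {
      stop("config field params$", nm, " is required when params is given")
    }
    if (!file.exists(cfg$params[[nm]])) {
      stop("config field params$", nm, ": file not found: ", cfg$params[[nm]])
    }
  }
  list("2013" = read_params(cfg$params$p2013),
       "2017" = read_params(cfg$params$p2017))
}

config_population <- function(cfg, params) {
  if (!is.null(cfg$pedigree)) {
    if (!file.exists(cfg$pedigree)) {
      stop("config field pedigree: file not found: ", cfg$pedigree)
    }
    ped <- read_pedigree(cfg$pedigree)
    cap <- list(ped = ped, living = ped$id[ped$location == "captive"])
    class(cap) <- "pva_captive_pop"
  } else {
    cap <- make_founder_pedigree(
      n_founders = cfg$population$n_founders,
      generations = cfg$population$generations,
      cohort_size = cfg$population$cohort_size,
      seed = cfg$seed
    )
  }
  n0 <- cfg$population$initial_n
  if (is.null(n0)) n0 <- params$initial_n
  make_initial_population(cap, n = n0, seed = cfg$seed)
}

write_manifest <- function(out_dir, cfg, command, sets) {
  manifest <- list(
    package = "wolfpva",
    version = as.character(utils::packageVersion("wolfpva")),
    command = command,
    seed = cfg$seed,
    iterations = cfg$iterations,
    years = cfg$years,
    event_order = sets[[1]]$event_order,
    placeholders = lapply(sets, placeholder_fields)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run a configured pipeline command
#'
#' Subcommands: `"fixtures"` regenerates the synthetic input tree (pedigree
#' TSV, parameter YAMLs, threshold CSV); `"simulate"` runs one Monte-Carlo
#' scenario; `"sensitivity"` runs the full factorial with contrast models,
#' shares and dispersion summaries; `"surface"` runs the cap x release grid
#' with retention against the current-captive baseline. Every run writes CSV
#' artifacts plus a `manifest.json` recording the seed and all placeholder
#' parameters used; identical config and seed give identical outputs.
#' Sensitivity runs are resumable: scenarios already present in
#' `scenario_results.csv` are not re-run.
#'
#' @param config path to a YAML config file, a config list, or `NULL` for
#'   defaults
#' @param command one of `"fixtures"`, `"simulate"`, `"sensitivity"`,
#'   `"surface"`
#' @param out_dir output directory (created if needed)
#' @param overrides named list patched over the config (e.g.
#'   `list(iterations = 10)`)
#' @return invisibly, a character vector of artifact paths
#' @export
run_config <- function(config = NULL,
                       command = c("sensitivity", "simulate", "surface", "fixtures"),
                       out_dir = "wolfpva_out", overrides = list()) {
  command <- match.arg(command)
  cfg <- load_config(config)
  if (length(overrides) > 0) cfg <- utils::modifyList(cfg, overrides)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sets <- config_parameter_sets(cfg)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }

  if (command == "fixtures") {
    fixdir <- file.path(out_dir, "fixtures")
    dir.create(fixdir, showWarnings = FALSE, recursive = TRUE)
    pop <- config_population(cfg, sets[["2017"]])
    paths <- c(paths, write_pedigree(pop$ped, file.path(fixdir, "pedigree.tsv")))
    paths <- c(paths, write_params(sets[["2013"]], file.path(fixdir, "params_2013.yaml")))
    paths <- c(paths, write_params(sets[["2017"]], file.path(fixdir, "params_2017.yaml")))
    thr <- make_threshold_table(cfg$seed)
    p <- file.path(fixdir, "risk_thresholds.csv")
    utils::write.csv(thr, p, row.names = FALSE)
    paths <- c(paths, p)
  } else if (command == "simulate") {
    use <- cfg$scenario$use
    if (!use %in% names(sets)) stop("config field scenario$use must name a parameter set")
    params <- sets[[use]]
    pop <- config_population(cfg, params)
    sc <- run_scenario(params, pop, n_iter = cfg$iterations, years = cfg$years,
                       seed = cfg$seed, keep_iterations = TRUE)
    iters <- do.call(rbind, lapply(seq_along(sc$iterations), function(i) {
      it <- sc$iterations[[i]]
      data.frame(iteration = i, extinct = it$extinct,
                 quasi_extinct = it$quasi_extinct, final_N = it$final_N,
                 final_GD = it$final_GD,
                 effective_releases = it$effective_releases, seed = it$seed)
    }))
    paths <- c(paths, wcsv(iters, "scenario_iterations.csv"))
    paths <- c(paths, wcsv(data.frame(
      label = sc$label, n_iter = sc$n_iter, years = sc$years,
      p_ext = sc$p_ext, p_quasi = sc$p_quasi, mean_GD = sc$mean_GD,
      p_ext_se = sc$p_ext_se, p_quasi_se = sc$p_quasi_se,
      mean_effective_releases = sc$mean_effective_releases),
      "scenario_summary.csv"))
  } else if (command == "sensitivity") {
    pop <- config_population(cfg, sets[["2013"]])
    design <- build_factorial_design(default_factor_specs(sets),
                                     base = sets[["2013"]])
    res_path <- file.path(out_dir, "scenario_results.csv")
    prior <- if (file.exists(res_path)) {
      utils::read.csv(res_path, stringsAsFactors = FALSE)
    } else NULL
    todo <- if (is.null(prior)) seq_len(nrow(design$design)) else
      which(!design$design$id %in% prior$id)
    if (length(todo) > 0) {
      fac_new <- run_factorial(design, pop, n_iter = cfg$iterations,
                               years = cfg$years, seed = cfg$seed,
                               subset = todo)
      results <- rbind(prior, fac_new$results)
    } else {
      results <- prior
    }
    results <- results[match(design$design$id, results$id), ]
    fac <- design
    fac$results <- results
    fac$n_iter <- cfg$iterations
    class(fac) <- c("pva_factorial", "pva_design")
    paths <- c(paths, wcsv(design$design, "design.csv"))
    paths <- c(paths, wcsv(results, "scenario_results.csv"))
    share_tab <- do.call(rbind, lapply(
      c("extinction", "quasi_extinction", "genetic_diversity"), function(resp) {
        m <- fit_contrast_model(fac, resp)
        if (m$degenerate) return(NULL)
        s <- contrast_shares(m)$factor_shares
        s$response <- resp
        s
      }))
    paths <- c(paths, wcsv(share_tab, "share_table.csv"))
    cat_tab <- stats::aggregate(share_pct ~ response + category,
                                data = share_tab, FUN = sum)
    paths <- c(paths, wcsv(cat_tab, "category_shares.csv"))
    paths <- c(paths, wcsv(qcd_summary(fac), "qcd.csv"))
  } else if (command == "surface") {
    params <- sets[["2017"]]
    pop <- config_population(cfg, params)
    surf <- sweep_cap_release(params, pop, cap_values = cfg$surface$caps,
                              release_levels = list(
                                high = sets[["2013"]]$release_schedule,
                                low = sets[["2017"]]$release_schedule),
                              n_iter = cfg$iterations, years = cfg$years,
                              seed = cfg$seed)
    paths <- c(paths, wcsv(surf$grid, "surface_grid.csv"))
    base_gd <- baseline_gd(pop, "current_captive")
    ret <- gd_retention_curve(surf, base_gd)
    paths <- c(paths, wcsv(ret$cells, "retention.csv"))
    paths <- c(paths, wcsv(ret$minimal_cap, "minimal_cap.csv"))
  }
  paths <- c(paths, write_manifest(out_dir, cfg, command, sets))
  invisible(paths)
}

#' Assemble summary report tables from a results directory
#'
#' Reads the CSV artifacts written by [run_config()] and emits the stacked
#' share table per response metric, the category-share summary (biological /
#' policy / mixed percentages), the three-row dispersion table, and — when a
#' surface run is present — the cap x release metric grids.
#'
#' @param results_dir directory holding `run_config()` outputs
#' @return invisibly, a named list of the report data.frames (also written as
#'   `report_*.csv` in `results_dir`)
#' @export
write_report <- function(results_dir) {
  if (!dir.exists(results_dir)) stop("results directory not found: ", results_dir)
  have <- list.files(results_dir)
  if (length(have) == 0) stop("results directory is empty: ", results_dir)
  out <- list()
  rcsv <- function(name) {
    utils::read.csv(file.path(results_dir, name), stringsAsFactors = FALSE)
  }
  if ("share_table.csv" %in% have) {
    st <- rcsv("share_table.csv")
    out$stacked_shares <- st[order(st$response, -st$share_pct), ]
    cs <- stats::aggregate(share_pct ~ response + category, data = st, FUN = sum)
    out$category_shares <- cs[order(cs$response, cs$category), ]
  }
  if ("qcd.csv" %in% have) out$qcd <- rcsv("qcd.csv")
  if ("surface_grid.csv" %in% have) out$surface <- rcsv("surface_grid.csv")
  if (length(out) == 0) {
    stop("no recognized result tables in ", results_dir)
  }
  for (nm in names(out)) {
    utils::write.csv(out[[nm]], file.path(results_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(out)
}

#' Stacked-bar plot of standardized coefficients by response metric
#'
#' @param share_table data.frame as written to `share_table.csv` (columns
#'   factor, category, standardized, share_pct, response)
#' @return a ggplot object
#' @export
plot_contrast_shares <- function(share_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(share_table,
                  ggplot2::aes(x = response, y = standardized,
                               fill = factor)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "standardized coefficient (z or t)") +
    ggplot2::theme_minimal()
}

#' Response-metric curves over population cap by release level
#'
#' @param surface_grid data.frame as written to `surface_grid.csv`
#' @param metric one of `"p_ext"`, `"p_quasi"`, `"mean_GD"`
#' @return a ggplot object
#' @export
plot_surface <- function(surface_grid, metric = "p_ext") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(surface_grid,
                  ggplot2::aes(x = cap, y = !!as.name(metric),
                               colour = release_level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "population cap", y = metric) +
    ggplot2::theme_minimal()
}
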