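# Response surfaces of the three output metrics over the management levers
# (population cap, releases from captivity), diversity-retention evaluation
# against fixed or shifting baselines, and the risk-threshold survey summary.

#' Sweep population cap x release schedule
#'
#' Runs one Monte-Carlo scenario per (cap, release level) cell. Per-cell
#' seeds are derived from the master seed and the cell's position in the
#' grid, so results are independent of evaluation order. The default grid is
#' 10 cap values (100-1000) crossed with the packaged high (2013) and low
#' (2017) release schedules.
#'
#' @param base_params a `pva_params` patched per cell
#' @param population a `pva_population`
#' @param cap_values numeric vector of population caps (>= 1 value)
#' @param release_levels named list of release schedules
#' @param n_iter iterations per cell
#' @param years simulation horizon
#' @param seed master seed
#' @return object of class `pva_surface`: `grid` data.frame (cap,
#'   release_level, p_ext, p_quasi, mean_GD, seed) plus the call settings
#' @export
sweep_cap_release <- function(base_params, population,
                              cap_values = round(seq(100, 1000, length.out = 10)),
                              release_levels = list(
                                high = default_parameter_sets()[["2013"]]$release_schedule,
                                low = default_parameter_sets()[["2017"]]$release_schedule),
                              n_iter = 100L, years = 100L, seed = 1L) {
  if (length(cap_values) < 1 || length(release_levels) < 1) {
    stop("need at least one cap value and one release level")
  }
  if (is.null(names(release_levels))) {
    names(release_levels) <- paste0("release", seq_along(release_levels))
  }
  ncell <- length(cap_values) * length(release_levels)
  seeds <- matrix(derive_seeds(seed, ncell, stream = 2L),
                  nrow = length(cap_values))
  rows <- vector("list", ncell)
  k <- 0L
  for (j in seq_along(release_levels)) {
    for (i in seq_along(cap_values)) {
      p <- unclass(base_params)
      p$cap <- cap_values[i]
      p$release_schedule <- release_levels[[j]]
      p$label <- sprintf("cap%d_%s", cap_values[i], names(release_levels)[j])
      class(p) <- "pva_params"
      sc <- run_scenario(p, population, n_iter = n_iter, years = years,
                         seed = seeds[i, j])
      k <- k + 1L
      rows[[k]] <- data.frame(
        cap = cap_values[i],
        release_level = names(release_levels)[j],
        p_ext = sc$p_ext,
        p_quasi = sc$p_quasi,
        mean_GD = sc$mean_GD,
        n_iter = n_iter,
        seed = seeds[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(grid = do.call(rbind, rows), cap_values = cap_values,
              release_levels = release_levels, years = years, seed = seed)
  class(out) <- "pva_surface"
  out
}

#' @export
print.pva_surface <- function(x, ...) {
  cat(sprintf("<pva_surface> %d caps x %d release levels\n",
              length(x$cap_values), length(x$release_levels)))
  print(x$grid, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Reference gene diversity for retention criteria
#'
#' @param population a `pva_population`
#' @param type `"current_captive"` (analytic GD of the living captive set),
#'   `"future_captive"` (allele-based GD of the captive population projected
#'   `year` years ahead under `params`), or `"founders"` (GD of the founder
#'   set)
#' @param params a `pva_params` (required for `"future_captive"`)
#' @param year projection horizon for `"future_captive"`
#' @param seed seed for the captive projection
#' @return baseline gene diversity in (0, 1]
#' @export
baseline_gd <- function(population, type = c("current_captive",
                                             "future_captive", "founders"),
                        params = NULL, year = 100L, seed = 1L) {
  type <- match.arg(type)
  switch(type,
    current_captive = gene_diversity(population$ped, population$captive_ids),
    founders = gene_diversity(population$ped, founders(population$ped)),
    future_captive = {
      if (is.null(params)) stop("future_captive baseline needs params")
      proj <- project_captive(population, params, years = year, seed = seed)
      proj$GD[nrow(proj)]
    })
}

#' Genetic-diversity retention over a cap x release grid
#'
#' Retention is each cell's mean final gene diversity divided by the baseline
#' gene diversity. For every release level the smallest cap whose retention
#' meets `target` is reported (`NA` when none does). Measuring retention
#' against a depleted future captive baseline (a shifting baseline) yields
#' retention values at least as high as against the current captive
#' population, and hence smaller qualifying caps.
#'
#' @param surface a `pva_surface`
#' @param baseline baseline gene diversity (> 0), e.g. from [baseline_gd()]
#' @param target retention target (default 0.90)
#' @return list: `cells` (grid data.frame with `retained` column) and
#'   `minimal_cap` (data.frame: release_level, minimal_cap)
#' @export
gd_retention_curve <- function(surface, baseline, target = 0.90) {
  if (!is.numeric(baseline) || baseline <= 0) {
    stop("baseline gene diversity must be > 0")
  }
  cells <- surface$grid
  cells$retained <- cells$mean_GD / baseline
  mc <- lapply(split(cells, cells$release_level), function(d) {
    d <- d[order(d$cap), ]
    hit <- d$cap[!is.na(d$retained) & d$retained >= target]
    data.frame(release_level = d$release_level[1],
               minimal_cap = if (length(hit) > 0) min(hit) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(cells = cells, minimal_cap = do.call(rbind, unname(mc)), target = target,
       baseline = baseline)
}

#' Summarize a recovery-plan risk-threshold survey
#'
#' @param threshold_table data.frame with columns `species`, `threshold_pct`,
#'   `horizon_years`; rows with non-numeric thresholds are rejected with a
#'   notice
#' @return list: `count`, `range` (min/max threshold), `modal_threshold`,
#'   `modal_share_pct`, and `distribution` (data.frame: threshold_pct, n,
#'   share_pct)
#' @export
threshold_survey_summary <- function(threshold_table) {
  need <- c("species", "threshold_pct", "horizon_years")
  if (!all(need %in% names(threshold_table))) {
    stop("threshold table needs columns: ", paste(need, collapse = ", "))
  }
  thr <- suppressWarnings(as.numeric(threshold_table$threshold_pct))
  bad <- is.na(thr)
  if (any(bad)) {
    message(sum(bad), " row(s) with non-numeric thresholds rejected")
  }
  thr <- thr[!bad]
  if (length(thr) == 0) {
    return(list(count = 0L, range = c(NA_real_, NA_real_),
                modal_threshold = NA_real_, modal_share_pct = NA_real_,
                distribution = data.frame(threshold_pct = numeric(0),
                                          n = integer(0),
                                          share_pct = numeric(0))))
  }
  tab <- table(thr)
  dist <- data.frame(
    threshold_pct = as.numeric(names(tab)),
    n = as.integer(tab),
    share_pct = round_half_up(100 * as.integer(tab) / length(thr), 0)
  )
  modal <- dist$threshold_pct[which.max(dist$n)]
  list(
    count = length(thr),
    range = range(thr),
    modal_threshold = modal,
    modal_share_pct = dist$share_pct[dist$threshold_pct == modal],
    distribution = dist
  )
}
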