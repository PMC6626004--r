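# Projection of the genetically managed captive population: the source of
# release animals and the baseline for diversity-retention criteria.

#' Project the captive population forward
#'
#' Runs the managed captive annual cycle (age-class mortality, then breeding
#' pairs chosen under `pairing_policy` producing enough litters to hold the
#' census within `captive_capacity`) for `years` years, and records yearly
#' genetic summaries of the living captive set estimated from the tracked
#' founder alleles. Under `"mean_kinship_min"` breeding pairs are picked
#' greedily by lowest pairwise kinship (a standard stand-in for optimal
#' genetic management); `"random"` pairing loses diversity faster.
#'
#' @param population a `pva_population` or `pva_captive_pop`
#' @param params a `pva_params` (`captive_capacity[2]` must be >= 2)
#' @param years projection horizon (>= 1)
#' @param seed integer seed
#' @return data.frame with columns `year`, `N`, `GD`, `Ho`, `mean_kinship`,
#'   `FGE`; year 0 is the starting state
#' @export
project_captive <- function(population, params, years = 100L, seed = 1L) {
  validate_params(params)
  if (years < 1) stop("years must be >= 1")
  if (params$captive_capacity[2] < 2) stop("captive capacity must be >= 2")
  if (inherits(population, "pva_captive_pop")) {
    population <- list(ped = population$ped, wild_ids = character(0),
                       captive_ids = population$living)
    class(population) <- "pva_population"
  }
  set.seed(seed)
  st <- init_sim_state(population, params)
  out <- vector("list", years + 1L)
  snap <- function(yr) {
    cw <- living_slots(st, 2L)
    gd <- allele_gd(st, cw)
    data.frame(
      year = yr,
      N = length(cw),
      GD = gd,
      Ho = allele_ho(st, cw),
      mean_kinship = 1 - gd,
      FGE = if (!is.na(gd) && gd < 1) 1 / (2 * (1 - gd)) else NA_real_
    )
  }
  out[[1L]] <- snap(0L)
  for (yr in seq_len(years)) {
    st$year <- yr
    captive_cycle(st, params)
    al <- which(st$alive)
    st$age[al] <- st$age[al] + 1L
    out[[yr + 1L]] <- snap(yr)
  }
  do.call(rbind, out)
}
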