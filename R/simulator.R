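# Annual-cycle individual-based simulation of the wild population, with a
# concurrently projected captive source population. Event order follows the
# Vortex-style sequence (breed, die, harvest, supplement, age) and is
# configurable via params$event_order.

sample_year_effects <- function(p) {
  list(
    ev_z = stats::rnorm(1),
    outbreak = stats::runif(1) < p$disease_freq
  )
}

#' Form breeding pairs for one simulated year
#'
#' Existing pairs persist with probability `pair_persistence` (and break when
#' a member dies). Unpaired adult females are then matched with unpaired
#' adult males so the expected proportion of adult females paired equals
#' `p_pair` (or its density-dependent value at the current census relative to
#' the cap). Each individual belongs to at most one pair; pairings with an
#' individual's own parent, offspring or full sibling are excluded. Newly
#' formed pairs (packs) are assigned supplemental feeding with probability
#' `fed_fraction`, persistent for the life of the pair.
#'
#' @param state a `pva_state`
#' @param params a `pva_params`
#' @return the state, invisibly (modified in place)
#' @export
form_pairs <- function(state, params) {
  st <- state; p <- params
  n_wild <- length(living_slots(st, 1L))
  if (n_wild == 0) return(invisible(st))
  cpp_form_pairs(st, p$pair_persistence, pairing_rate(p, n_wild),
                 p$fed_fraction, p$first_breeding_age, p$kin_exclusion)
  invisible(st)
}

#' Reproduction for one simulated year
#'
#' For each breeding pair the effective inbreeding load is `F* = 0` if the
#' pack is fed, else the expected inbreeding coefficient of prospective
#' offspring (the pair's kinship). Whelping succeeds with probability
#' `(1 - whelp_fail_base) * exp(-B_fail F*) * age_fecundity`, reduced by the
#' disease reproduction multiplier in outbreak years; litter size is drawn
#' from `litter_dist` and binomially thinned by `exp(-B_size F*)`, where
#' `B_fail = le_split * B` and `B_size = (1 - le_split) * B`. Pups inherit one
#' uniformly random allele per parent per locus and receive `F` equal to
#' their parents' kinship.
#'
#' @param state a `pva_state`
#' @param params a `pva_params`
#' @param year_effects list with elements `ev_z` and `outbreak`, as sampled
#'   once per year (see details in [run_iteration()])
#' @return the state, invisibly (modified in place)
#' @export
reproduce <- function(state, params, year_effects = list(ev_z = 0, outbreak = FALSE)) {
  st <- state; p <- params
  repro_mult <- if (isTRUE(year_effects$outbreak)) p$disease_sev_repro else 1
  cpp_reproduce(st, p$whelp_fail_base,
                p$lethal_equivalents * p$le_split,
                p$lethal_equivalents * (1 - p$le_split),
                p$age_fecundity, repro_mult, p$litter_dist, p$sex_ratio,
                p$first_breeding_age, p$max_age, 1L, st$year)
  invisible(st)
}

#' Age-class mortality and disease for one simulated year
#'
#' Each wild individual dies with its age-class rate (pup = age 0, yearling =
#' age 1, adult = 2+; optionally sex-specific) shifted by the year's shared
#' environmental deviate times `env_sd`; rates falling outside \[0, 1\] after
#' adjustment are clamped and logged. In outbreak years survival is further
#' multiplied by `disease_sev_survival`. Individuals at or beyond `max_age`
#' die.
#'
#' @inheritParams reproduce
#' @return the state, invisibly (modified in place)
#' @export
apply_mortality_and_disease <- function(state, params,
                                        year_effects = list(ev_z = 0, outbreak = FALSE)) {
  st <- state; p <- params
  rf <- unname(p$mortality) + year_effects$ev_z * unname(p$env_sd)
  rm_ <- if (is.null(p$mortality_male)) rf else
    unname(p$mortality_male) + year_effects$ev_z * unname(p$env_sd)
  rates <- cbind(rf, rm_)
  if (any(rates < 0 | rates > 1)) {
    log_note(st, sprintf("year %d: adjusted mortality rates clamped to [0,1]",
                         st$year))
    rates <- pmin(pmax(rates, 0), 1)
  }
  sev <- if (isTRUE(year_effects$outbreak)) p$disease_sev_survival else 1
  cpp_mortality(st, rates, sev, p$max_age, 1L)
  invisible(st)
}

#' Population-cap removals for one simulated year
#'
#' If the wild census exceeds `cap`, `removal_rate * (N - cap)` individuals
#' (stochastically rounded) are removed uniformly at random.
#'
#' @param state a `pva_state`
#' @param params a `pva_params`
#' @return the state, invisibly (modified in place)
#' @export
enforce_cap <- function(state, params) {
  st <- state; p <- params
  w <- living_slots(st, 1L)
  n <- length(w)
  if (n <= p$cap) return(invisible(st))
  k <- min(rstoch_round(p$removal_rate * (n - p$cap)), n)
  if (k > 0) kill_slots(st, cpp_sample_k(w, k))
  invisible(st)
}

#' Rank captive individuals as release candidates
#'
#' Candidates are the living captive animals with lowest mean kinship to the
#' wild living set (estimated from the tracked founder alleles); ties are
#' broken by lower own inbreeding coefficient, then by id order.
#'
#' @param state a `pva_state`
#' @param k number of candidates requested (>= 0)
#' @return character vector of up to `k` individual ids (pedigree/studbook
#'   ids); fewer than `k`, with a log notice, when availability is short
#' @export
select_release_candidates <- function(state, k) {
  st <- state
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(character(0))
  slots <- release_candidate_slots(st, k)
  slot_pid(st, slots)
}

slot_pid <- function(st, slots) {
  out <- st$pid[slots]
  anon <- out == ""
  out[anon] <- paste0("S", st$id[slots[anon]])
  out
}

release_candidate_slots <- function(st, k) {
  cand <- living_slots(st, 2L)
  if (length(cand) == 0) return(integer(0))
  if (length(cand) < k) {
    log_note(st, sprintf("year %d: release request %d truncated to %d available",
                         st$year, k, length(cand)))
    k <- length(cand)
  }
  wild <- living_slots(st, 1L)
  mk <- if (length(wild) > 0) {
    allele_mk_to_set(st, cand, wild)
  } else rep(0, length(cand))
  ord <- order(mk, st$Fi[cand], st$id[cand])
  cand[ord[seq_len(k)]]
}

#' Release captive individuals into the wild population
#'
#' Moves `release_schedule[year]` captive animals (selected by
#' [select_release_candidates()]) into the wild population, retaining their
#' pedigree links. Requests exceeding captive availability are truncated and
#' logged. An animal counts toward `effective_releases` when it later reaches
#' `first_breeding_age` alive in the wild.
#'
#' @param state a `pva_state`
#' @param params a `pva_params`
#' @param year current simulation year
#' @return the state, invisibly (modified in place)
#' @export
release_individuals <- function(state, params, year) {
  st <- state; p <- params
  sched <- p$release_schedule
  if (length(sched) == 0) return(invisible(st))
  k <- sched[as.character(year)]
  if (is.na(k) || k <= 0) return(invisible(st))
  slots <- release_candidate_slots(st, as.integer(k))
  if (length(slots) == 0) return(invisible(st))
  mates <- st$pair[slots]
  mates <- mates[mates > 0L]
  if (length(mates) > 0) { st$pair[mates] <- 0L; st$fed[mates] <- FALSE }
  st$pair[slots] <- 0L
  st$fed[slots] <- FALSE
  st$loc[slots] <- 1L
  st$released[slots] <- TRUE
  invisible(st)
}

captive_breeding_pairs <- function(st, fem, mal, npairs, policy) {
  if (policy == "random") {
    f <- sample_vec(fem, npairs)
    m <- sample_vec(mal, npairs)
    return(cbind(f, m))
  }
  # pre-select a pool of the lowest mean-kinship animals per sex, then pick
  # pairs greedily by lowest pairwise kinship within the pool
  cw <- living_slots(st, 2L)
  pool_size <- min(2L * npairs + 4L, max(length(fem), length(mal)))
  if (length(fem) > pool_size) {
    fem <- fem[order(allele_mk_to_set(st, fem, cw))[seq_len(pool_size)]]
  }
  if (length(mal) > pool_size) {
    mal <- mal[order(allele_mk_to_set(st, mal, cw))[seq_len(pool_size)]]
  }
  K <- allele_cross_kinship(st, fem, mal)
  forb <- outer(st$sire_id[fem], st$id[mal], "==") |
    outer(st$id[fem], st$dam_id[mal], "==") |
    (outer(st$sire_id[fem], st$sire_id[mal], "==") &
       outer(st$dam_id[fem], st$dam_id[mal], "==") &
       st$sire_id[fem] > 0L & st$dam_id[fem] > 0L)
  K[forb] <- Inf
  out <- matrix(0L, 0, 2)
  for (i in seq_len(npairs)) {
    j <- which.min(K)
    if (!is.finite(K[j])) break
    r <- (j - 1L) %% nrow(K) + 1L
    cc <- (j - 1L) %/% nrow(K) + 1L
    out <- rbind(out, c(fem[r], mal[cc]))
    K[r, ] <- Inf
    K[, cc] <- Inf
  }
  out
}

# One year of the managed captive population: mortality, then managed
# breeding (pairs chosen under pairing_policy) producing enough litters to
# hold the census within capacity.
captive_cycle <- function(st, p) {
  cw <- living_slots(st, 2L)
  if (length(cw) == 0) return(invisible(st))
  cls <- pmin(st$age[cw], 2L) + 1L
  rate <- unname(p$captive_mortality)[cls]
  dead <- stats::runif(length(cw)) < rate | st$age[cw] >= p$max_age
  if (any(dead)) { kill_slots(st, cw[dead]); cw <- cw[!dead] }
  cap_max <- p$captive_capacity[2]
  if (length(cw) > cap_max) {
    # managed down to capacity (transfers out of the breeding population)
    drop <- cpp_sample_k(cw, length(cw) - cap_max)
    kill_slots(st, drop)
    cw <- setdiff(cw, drop)
  }
  target <- cap_max - length(cw)
  if (target <= 0) return(invisible(st))
  adult <- st$age[cw] >= p$first_breeding_age
  fem <- cw[adult & st$sex[cw] == 1L]
  mal <- cw[adult & st$sex[cw] == 2L]
  mean_litter <- sum((seq_along(p$litter_dist) - 1) * p$litter_dist)
  npairs <- min(ceiling(target / max(mean_litter, 1e-9)), length(fem), length(mal))
  if (npairs <= 0) return(invisible(st))
  pairs <- captive_breeding_pairs(st, fem, mal, npairs, p$pairing_policy)
  if (nrow(pairs) == 0) return(invisible(st))
  sizes <- sample.int(length(p$litter_dist), nrow(pairs), replace = TRUE,
                      prob = p$litter_dist) - 1L
  pos <- sizes > 0L
  if (!any(pos)) return(invisible(st))
  rep_idx <- rep.int(which(pos), sizes[pos])
  ds <- pairs[rep_idx, 1]; ss <- pairs[rep_idx, 2]
  fi <- allele_pair_kinship(st, ss, ds)
  n <- length(ds)
  slots <- spawn_offspring(st, ss, ds, fi, 2L, p$sex_ratio)
  over <- (length(cw) + n) - cap_max
  if (over > 0) kill_slots(st, sample_vec(slots, over))
  invisible(st)
}

#' Run one Monte-Carlo iteration of the annual cycle
#'
#' Executes the annual event sequence (default: pair formation, reproduction,
#' mortality and disease, cap enforcement, releases, captive-population
#' cycle, age increment and census) for `years` years or until extinction
#' (no wild individuals, or a single sex remaining; the final census is then
#' reported as 0). The captive population is projected only while the release
#' schedule still has pending years, after which it no longer influences the
#' wild population. Quasi-extinction is the census dropping below
#' `quasi_threshold` in any year after year 0 (or in the final year only,
#' when `quasi_any_year` is FALSE). Fully reproducible given `seed`.
#'
#' @param params a `pva_params`
#' @param population a `pva_population`
#' @param years simulation horizon (>= 1)
#' @param seed integer seed
#' @param keep_yearly keep the yearly census series in the result
#' @return a `pva_iteration` list: `extinct`, `quasi_extinct`, `final_N`,
#'   `final_GD` (allele-based gene diversity of wild survivors; `NA` if
#'   extinct), `yearly_N`, `effective_releases`, `seed`, `log`
#' @export
run_iteration <- function(params, population, years = 100L, seed = 1L,
                          keep_yearly = TRUE) {
  validate_params(params)
  if (years < 1) stop("years must be >= 1")
  set.seed(seed)
  st <- init_sim_state(population, params)
  sched_years <- if (length(params$release_schedule) > 0) {
    as.integer(names(params$release_schedule))
  } else integer(0)
  last_release <- if (length(sched_years) > 0) max(sched_years) else 0L
  yearly <- integer(years)
  any_below <- FALSE
  extinct <- FALSE
  last_year <- years
  for (yr in seq_len(years)) {
    st$year <- yr
    ye <- sample_year_effects(params)
    for (ev in params$event_order) {
      switch(ev,
             pairing = form_pairs(st, params),
             reproduction = reproduce(st, params, ye),
             mortality = apply_mortality_and_disease(st, params, ye),
             cap = enforce_cap(st, params),
             releases = release_individuals(st, params, yr),
             captive = if (yr <= last_release) captive_cycle(st, params))
    }
    cs <- cpp_age_census(st$alive, st$loc, st$age, st$sex, st$released,
                         st$rel_counted, params$first_breeding_age)
    n <- cs[1]
    yearly[yr] <- n
    st$eff_releases <- st$eff_releases + cs[2]
    if (n < params$quasi_threshold) any_below <- TRUE
    if (n == 0L || cs[3] == 0L || cs[4] == 0L) {
      extinct <- TRUE
      last_year <- yr
      break
    }
  }
  yearly <- yearly[seq_len(last_year)]
  w <- living_slots(st, 1L)
  quasi <- if (params$quasi_any_year) any_below else
    (length(w) < params$quasi_threshold)
  res <- list(
    extinct = extinct,
    quasi_extinct = quasi || extinct,
    final_N = if (extinct) 0L else length(w),
    final_GD = if (extinct) NA_real_ else allele_gd(st, w),
    yearly_N = if (keep_yearly) yearly else NULL,
    effective_releases = st$eff_releases,
    seed = seed,
    log = st$log
  )
  class(res) <- "pva_iteration"
  res
}

# Deterministic derivation of child RNG seeds (kept below 2^31).
derive_seeds <- function(seed, n, stream = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + (as.numeric(stream) * 69621 + seq_len(n)) * 16807) %%
               2147483629) + 1L
}

#' Run a Monte-Carlo scenario
#'
#' Aggregates `n_iter` independent iterations whose seeds are derived
#' deterministically from the scenario seed. `p_ext` and `p_quasi` are exact
#' fractions of iterations; `mean_GD` averages final gene diversity over
#' non-extinct iterations (all-extinct scenarios report `NA`).
#'
#' @param params a `pva_params`
#' @param population a `pva_population`
#' @param n_iter number of iterations (>= 1)
#' @param years simulation horizon
#' @param seed scenario seed
#' @param keep_iterations retain the per-iteration records in the result
#' @return a `pva_scenario` list with `p_ext`, `p_quasi`, `mean_GD`, their
#'   Monte-Carlo standard errors, `mean_effective_releases`, `n_iter`,
#'   `years`, `seed`, and (optionally) `iterations`
#' @export
run_scenario <- function(params, population, n_iter = 100L, years = 100L,
                         seed = 1L, keep_iterations = FALSE) {
  validate_params(params)
  if (n_iter < 1) stop("n_iter must be >= 1")
  seeds <- derive_seeds(seed, n_iter)
  ext <- logical(n_iter); quasi <- logical(n_iter)
  gd <- rep(NA_real_, n_iter); eff <- numeric(n_iter)
  iters <- if (keep_iterations) vector("list", n_iter) else NULL
  for (i in seq_len(n_iter)) {
    it <- run_iteration(params, population, years, seeds[i],
                        keep_yearly = keep_iterations)
    ext[i] <- it$extinct
    quasi[i] <- it$quasi_extinct
    gd[i] <- it$final_GD
    eff[i] <- it$effective_releases
    if (keep_iterations) iters[[i]] <- it
  }
  p_ext <- mean(ext)
  p_quasi <- mean(quasi)
  gd_ok <- gd[!ext]
  res <- list(
    label = params$label,
    params = params,
    n_iter = n_iter,
    years = years,
    seed = seed,
    p_ext = p_ext,
    p_quasi = p_quasi,
    mean_GD = if (length(gd_ok) > 0) mean(gd_ok) else NA_real_,
    p_ext_se = sqrt(p_ext * (1 - p_ext) / n_iter),
    p_quasi_se = sqrt(p_quasi * (1 - p_quasi) / n_iter),
    mean_GD_se = if (length(gd_ok) > 1) stats::sd(gd_ok) / sqrt(length(gd_ok)) else NA_real_,
    mean_effective_releases = mean(eff),
    iterations = iters
  )
  class(res) <- "pva_scenario"
  res
}

#' @export
print.pva_scenario <- function(x, ...) {
  cat(sprintf(
    "<pva_scenario> %s: n_iter=%d years=%d | P(ext)=%.3f P(quasi)=%.3f mean GD=%s\n",
    x$label, x$n_iter, x$years, x$p_ext, x$p_quasi,
    if (is.na(x$mean_GD)) "NA" else sprintf("%.4f", x$mean_GD)))
  invisible(x)
}

#' @export
print.pva_iteration <- function(x, ...) {
  cat(sprintf(
    "<pva_iteration> %s after %d years: final N=%d GD=%s, quasi=%s, effective releases=%d\n",
    if (x$extinct) "EXTINCT" else "extant",
    length(x$yearly_N), x$final_N,
    if (is.na(x$final_GD)) "NA" else sprintf("%.4f", x$final_GD),
    x$quasi_extinct, x$effective_releases))
  invisible(x)
}
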