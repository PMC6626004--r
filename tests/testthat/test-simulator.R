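new_state <- function(pop, params, seed = 1) {
  set.seed(seed)
  init_sim_state(pop, params)
}

n_wild <- function(st) length(wolfpva:::living_slots(st, 1L))
n_pairs <- function(st) {
  w <- wolfpva:::living_slots(st, 1L)
  sum(st$pair[w] > 0L) / 2
}

test_that("pair formation honours the target pairing proportion", {
  pop <- founder_population(10, 10)
  p0 <- test_params(p_pair = 0)
  st <- new_state(pop, p0)
  form_pairs(st, p0)
  expect_equal(n_pairs(st), 0)

  p1 <- test_params(p_pair = 1)
  st <- new_state(pop, p1)
  form_pairs(st, p1)
  expect_equal(n_pairs(st), 10)
  # each individual in at most one pair, and pairing is mutual
  w <- wolfpva:::living_slots(st, 1L)
  expect_true(all(st$pair[st$pair[w]] == w))
})

test_that("kin exclusion blocks parent-offspring and full-sibling pairs", {
  ped <- pedigree(data.frame(
    id = c("A", "B", "C", "D"),
    sire = c(NA, NA, "A", "A"),
    dam = c(NA, NA, "B", "B"),
    sex = c("M", "F", "F", "M"),
    birth_year = c(0, 0, 1, 1),
    location = "wild"))
  attr(ped, "ref_year") <- 4L
  # only a daughter and her father alive: no permissible pair
  pop <- list(ped = ped, wild_ids = c("A", "C"), captive_ids = character(0))
  class(pop) <- "pva_population"
  p <- test_params(p_pair = 1)
  st <- new_state(pop, p)
  form_pairs(st, p)
  expect_equal(n_pairs(st), 0)
  # full siblings only: still no pair
  pop$wild_ids <- c("C", "D")
  st <- new_state(pop, p)
  form_pairs(st, p)
  expect_equal(n_pairs(st), 0)
  # disabling the exclusion allows the sibling pair
  p2 <- test_params(p_pair = 1, kin_exclusion = FALSE)
  st <- new_state(pop, p2)
  form_pairs(st, p2)
  expect_equal(n_pairs(st), 1)
})

test_that("whelping probability is exact for unrelated pairs", {
  pop <- founder_population(60, 60)
  p <- test_params(p_pair = 1, whelp_fail_base = 0.3,
                   litter_dist = c(0, 1))  # one pup per successful litter
  base <- new_state(pop, p)
  form_pairs(base, p)
  litters <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    st <- clone_state(base)
    before <- n_wild(st)
    reproduce(st, p)
    litters <- litters + (n_wild(st) - before)
  }
  n <- 60 * reps
  expect_lt(abs(litters - 0.7 * n), 3 * sqrt(n * 0.7 * 0.3))
})

test_that("inbreeding thins litters by exp(-B_size F*) and pups record parental kinship", {
  pop <- founder_population(60, 60)
  p <- test_params(p_pair = 1, lethal_equivalents = 2, le_split = 0,
                   litter_dist = c(0, 0, 0, 0, 0, 1))  # litters of 5
  base <- new_state(pop, p)
  form_pairs(base, p)
  w <- wolfpva:::living_slots(base, 1L)
  # force pair kinship estimate to exactly 0.25 at every locus:
  # sire carries (1,2), dam carries (1,3)
  males <- w[base$sex[w] == 2L]
  fems <- w[base$sex[w] == 1L]
  base$A1[, males] <- as.raw(1); base$A2[, males] <- as.raw(2)
  base$A1[, fems] <- as.raw(1); base$A2[, fems] <- as.raw(3)
  pups_total <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    st <- clone_state(base)
    before <- n_wild(st)
    reproduce(st, p)
    pups <- setdiff(wolfpva:::living_slots(st, 1L),
                    wolfpva:::living_slots(base, 1L))
    expect_true(all(st$Fi[pups] == 0.25))
    pups_total <- pups_total + (n_wild(st) - before)
  }
  n_litters <- 60 * reps
  expected <- 5 * exp(-2 * 0.25 * 1)  # le_split 0 puts all load on litter size
  keep <- exp(-0.5)
  se <- sqrt(n_litters * 5 * keep * (1 - keep)) / n_litters
  expect_lt(abs(pups_total / n_litters - expected), 3 * se)
})

test_that("mortality is binomial with the age-class rate and spares no one at rate 1", {
  pop <- founder_population(50, 50, age_f = 0L, age_m = 0L)
  p <- test_params(mortality = c(pup = 0.3, yearling = 0.3, adult = 0.3))
  base <- new_state(pop, p)
  deaths <- 0L
  reps <- 100L
  for (r in seq_len(reps)) {
    st <- clone_state(base)
    apply_mortality_and_disease(st, p)
    deaths <- deaths + (100 - n_wild(st))
  }
  n <- 100 * reps
  expect_lt(abs(deaths - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))

  # rate zero: no deaths; adult rate one: all adults die
  p0 <- test_params()
  st <- new_state(founder_population(20, 20), p0)
  apply_mortality_and_disease(st, p0)
  expect_equal(n_wild(st), 40)
  p1 <- test_params(mortality = c(pup = 0, yearling = 0, adult = 1))
  mixed <- founder_population(10, 10, age_f = 5L, age_m = 0L)
  st <- new_state(mixed, p1)
  apply_mortality_and_disease(st, p1)
  w <- wolfpva:::living_slots(st, 1L)
  expect_equal(length(w), 10)            # pups survive
  expect_true(all(st$age[w] == 0L))
})

test_that("per-year death counts are exactly binomial without disease or environmental variance", {
  pop <- founder_population(25, 25, age_f = 0L, age_m = 0L)
  p <- test_params(mortality = c(pup = 0.3, yearling = 0.3, adult = 0.3))
  base <- new_state(pop, p)
  reps <- 400L
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    st <- clone_state(base)
    apply_mortality_and_disease(st, p)
    counts[r] <- 50 - n_wild(st)
  }
  # chi-square goodness of fit against Binomial(50, 0.3), pooled tails
  probs <- dbinom(0:50, 50, 0.3)
  breaks <- c(-1, 9, 11, 13, 15, 17, 19, 50)
  obs <- table(cut(counts, breaks))
  exp_p <- diff(pbinom(breaks, 50, 0.3))
  chi <- sum((as.numeric(obs) - reps * exp_p)^2 / (reps * exp_p))
  expect_lt(chi, qchisq(0.999, df = length(exp_p) - 1))
})

test_that("cap enforcement removes the excess and respects stochastic rounding", {
  pop <- founder_population(60, 60)
  p <- test_params(cap = 200)
  st <- new_state(pop, p)
  enforce_cap(st, p)
  expect_equal(n_wild(st), 120)           # below cap: untouched

  p_hard <- test_params(cap = 20, removal_rate = 1)
  st <- new_state(pop, p_hard)
  enforce_cap(st, p_hard)
  expect_equal(n_wild(st), 20)

  p_half <- test_params(cap = 19, removal_rate = 0.5)
  base <- new_state(pop, p_half)
  removed <- 0
  reps <- 200L
  for (r in seq_len(reps)) {
    st <- clone_state(base)
    enforce_cap(st, p_half)
    removed <- removed + (120 - n_wild(st))
  }
  # expectation 0.5 * 101 = 50.5 per replicate, sd 0.5 from the rounding
  expect_lt(abs(removed / reps - 50.5), 3 * 0.5 / sqrt(reps))
})

test_that("releases move captive animals into the wild and truncate when short", {
  pop <- founder_population(10, 10, n_captive_f = 4, n_captive_m = 4)
  p <- test_params(release_schedule = c("1" = 5))
  st <- new_state(pop, p)
  release_individuals(st, p, year = 1)
  expect_equal(n_wild(st), 25)
  expect_equal(length(wolfpva:::living_slots(st, 2L)), 3)

  p_over <- test_params(release_schedule = c("1" = 50))
  st <- new_state(pop, p_over)
  release_individuals(st, p_over, year = 1)
  expect_equal(n_wild(st), 28)
  expect_match(paste(st$log, collapse = " "), "truncated")
  # no scheduled release this year: no change
  st2 <- new_state(pop, p)
  release_individuals(st2, p, year = 7)
  expect_equal(n_wild(st2), 20)
})

test_that("effective releases count survival to first breeding age", {
  pop <- founder_population(5, 5, age_f = 3L, age_m = 3L,
                            n_captive_f = 50, n_captive_m = 50,
                            captive_age = 0L)
  p <- test_params(
    mortality = c(pup = 0.2, yearling = 0.2, adult = 0.2),
    litter_dist = c(1),          # no reproduction
    p_pair = 0,
    first_breeding_age = 3L,
    release_schedule = c("1" = 100)
  )
  effs <- vapply(1:8, function(s) {
    run_iteration(p, pop, years = 4, seed = s)$effective_releases
  }, numeric(1))
  # released as pups; counted at age 3 after two wild mortality years
  n <- 100 * 8
  expect_lt(abs(sum(effs) - 0.64 * n), 3 * sqrt(n * 0.64 * 0.36))
})

test_that("an iteration goes extinct under total mortality and flags quasi-extinction", {
  pop <- founder_population(10, 10)
  p <- test_params(mortality = c(pup = 1, yearling = 1, adult = 1),
                   quasi_threshold = 150)
  it <- run_iteration(p, pop, years = 10, seed = 1)
  expect_true(it$extinct)
  expect_true(it$quasi_extinct)
  expect_equal(it$final_N, 0L)
  expect_true(is.na(it$final_GD))
  expect_equal(length(it$yearly_N), 1L)
})

test_that("with a zero quasi-threshold, quasi-extinction coincides with extinction", {
  pop <- founder_population(6, 6)
  p <- test_params(mortality = c(pup = 0.5, yearling = 0.5, adult = 0.5),
                   litter_dist = c(0.4, 0.3, 0.3), quasi_threshold = 0)
  for (s in 1:15) {
    it <- run_iteration(p, pop, years = 25, seed = s)
    expect_identical(it$quasi_extinct, it$extinct)
  }
})

test_that("a deterministic-limit configuration follows the closed-form census recurrence", {
  pop <- founder_population(5, 5, age_f = 2L, age_m = 2L)
  p <- test_params(p_pair = 1, kin_exclusion = FALSE, sex_ratio = 1,
                   litter_dist = c(0, 0, 1))
  # five immortal pairs each add two female pups per year: N_t = 10 + 10 t
  it <- run_iteration(p, pop, years = 8, seed = 99)
  expect_identical(it$yearly_N, as.integer(10 + 10 * (1:8)))
  expect_false(it$extinct)
})

test_that("feeding fully masks the inbreeding load: (B > 0, all fed) equals (B = 0)", {
  pop <- study_population()
  masked <- pva_params(p_pair = 0.7, lethal_equivalents = 6, fed_fraction = 1,
                       mortality = c(pup = 0.3, yearling = 0.2, adult = 0.2),
                       disease_freq = 0.05, cap = 300, initial_n = 220L)
  unloaded <- pva_params(p_pair = 0.7, lethal_equivalents = 0, fed_fraction = 0,
                         mortality = c(pup = 0.3, yearling = 0.2, adult = 0.2),
                         disease_freq = 0.05, cap = 300, initial_n = 220L)
  for (s in c(5, 17)) {
    it_m <- run_iteration(masked, pop, years = 40, seed = s)
    it_u <- run_iteration(unloaded, pop, years = 40, seed = s)
    expect_identical(it_m$yearly_N, it_u$yearly_N)
    expect_identical(it_m$final_GD, it_u$final_GD)
  }
})

test_that("scenarios are deterministic given the seed and aggregate exactly", {
  pop <- founder_population(8, 8)
  p <- test_params(mortality = c(pup = 0.4, yearling = 0.4, adult = 0.4),
                   litter_dist = c(0.3, 0.3, 0.4), quasi_threshold = 5)
  r1 <- run_scenario(p, pop, n_iter = 15, years = 20, seed = 7)
  r2 <- run_scenario(p, pop, n_iter = 15, years = 20, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$p_ext <= r1$p_quasi)
  expect_equal(r1$p_ext * r1$n_iter, round(r1$p_ext * r1$n_iter))

  # degenerate all-survive configuration
  calm <- test_params()
  r0 <- run_scenario(calm, pop, n_iter = 10, years = 10, seed = 1)
  expect_equal(r0$p_ext, 0)
})

test_that("extinction probability matches a multitype branching-process oracle", {
  # Non-overlapping female generations: females breed once at age 2 and die;
  # males are immortal and never limiting, so female lines are independent
  # Galton-Watson processes. The oracle iterates the exact extinction
  # recursion over female age states backwards from the horizon.
  litter <- c(0.02, 0.05, 0.08, 0.12, 0.18, 0.20, 0.15, 0.12, 0.08)
  w <- 0.8; s0 <- 0.8; s1 <- 0.8; Y <- 30L; k0 <- 4L
  p <- test_params(
    p_pair = 1, kin_exclusion = FALSE,
    whelp_fail_base = 1 - w,
    litter_dist = litter,
    mortality = c(pup = 1 - s0, yearling = 1 - s1, adult = 1),
    mortality_male = c(pup = 0, yearling = 0, adult = 0),
    max_age = 1000L, age_fecundity = rep(1, 1001),
    cap = 1e6, quasi_threshold = 0
  )
  # oracle: e_t(state) = P(no living female descendant at end of year Y)
  gk <- function(z) {  # pgf of daughters born to one breeder
    (1 - w) + w * sum(litter * (0.5 + 0.5 * z)^(seq_along(litter) - 1))
  }
  eA <- 0; eB <- 0  # values at t = Y
  for (t in (Y - 1):0) {
    h <- (1 - s0) + s0 * eA          # a newborn daughter's extinction factor
    eB_new <- gk(h)
    eA_new <- (1 - s1) + s1 * eB
    eA <- eA_new; eB <- eB_new
  }
  p_ext_oracle <- eB^k0

  pop <- founder_population(k0, 60, age_f = 2L, age_m = 2L)
  sc <- run_scenario(p, pop, n_iter = 5000, years = Y, seed = 31)
  se <- sqrt(p_ext_oracle * (1 - p_ext_oracle) / 5000)
  expect_lt(abs(sc$p_ext - p_ext_oracle), 3 * se)
})
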