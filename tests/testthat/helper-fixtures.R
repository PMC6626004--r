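# Shared fixtures, built in code at test time.

# Small nuclear-family pedigree: founders A (M) x B (F), full siblings C (F)
# and D (M), unrelated founder E (F).
family_pedigree <- function() {
  pedigree(data.frame(
    id = c("A", "B", "C", "D", "E"),
    sire = c(NA, NA, "A", "A", NA),
    dam = c(NA, NA, "B", "B", NA),
    sex = c("M", "F", "F", "M", "F"),
    birth_year = c(0, 0, 1, 1, 0),
    location = "captive",
    stringsAsFactors = FALSE
  ))
}

# Four-generation pedigree with an inbreeding loop (mating of half sibs'
# descendants), exercising the recursive kinship beyond closed forms.
loop_pedigree <- function() {
  pedigree(data.frame(
    id   = c("F1", "F2", "F3", "S1", "S2", "T1", "T2", "U1"),
    sire = c(NA,   NA,   NA,   "F1", "F1", "S2", "S2", "T2"),
    dam  = c(NA,   NA,   NA,   "F2", "F3", "S1", "S1", "T1"),
    sex  = c("M",  "F",  "F",  "F",  "M",  "F",  "M",  "F"),
    birth_year = c(0, 0, 0, 1, 1, 2, 2, 3),
    location = "captive",
    stringsAsFactors = FALSE
  ))
}

# Population of unrelated wild founders with chosen sex/age composition, plus
# an optional captive set, for controlled simulator-operation tests.
founder_population <- function(n_f, n_m, age_f = 3L, age_m = 3L,
                               n_captive_f = 0L, n_captive_m = 0L,
                               captive_age = 3L) {
  n <- n_f + n_m + n_captive_f + n_captive_m
  sex <- c(rep("F", n_f), rep("M", n_m),
           rep("F", n_captive_f), rep("M", n_captive_m))
  loc <- c(rep("wild", n_f + n_m), rep("captive", n_captive_f + n_captive_m))
  age <- c(rep(age_f, n_f), rep(age_m, n_m),
           rep(captive_age, n_captive_f + n_captive_m))
  ref <- max(age) + 1L
  ped <- pedigree(data.frame(
    id = sprintf("I%03d", seq_len(n)),
    sire = NA_character_, dam = NA_character_,
    sex = sex, birth_year = ref - age, location = loc,
    stringsAsFactors = FALSE
  ))
  attr(ped, "ref_year") <- ref
  out <- list(ped = ped,
              wild_ids = ped$id[ped$location == "wild"],
              captive_ids = ped$id[ped$location == "captive"])
  class(out) <- "pva_population"
  out
}

# Parameter set for fast, controlled simulations: deterministic-friendly
# defaults (no disease, no environmental variance, no inbreeding load).
test_params <- function(...) {
  pva_params(
    p_pair = 1,
    pair_persistence = 1,
    litter_dist = c(0, 0, 1),          # always 2 pups
    whelp_fail_base = 0,
    lethal_equivalents = 0,
    fed_fraction = 0,
    mortality = c(pup = 0, yearling = 0, adult = 0),
    env_sd = c(pup = 0, yearling = 0, adult = 0),
    disease_freq = 0,
    cap = 1e6,
    release_schedule = numeric(0),
    quasi_threshold = 0,
    initial_n = 10L,
    ...
  )
}

# Default study population, built once per test run.
study_population <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) {
      cp <- make_founder_pedigree(seed = 1)
      pop <<- make_initial_population(cp, n = 220, seed = 1)
    }
    pop
  }
})

# Copy of a simulation state with every field duplicated (the kernels mutate
# vectors in place), so a configuration can be re-run many times.
clone_state <- function(st) {
  st2 <- new.env(parent = emptyenv())
  for (nm in ls(st)) {
    v <- get(nm, envir = st)
    if (length(v) > 0) v[1] <- v[1]  # force a distinct copy
    st2[[nm]] <- v
  }
  class(st2) <- "pva_state"
  st2
}
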