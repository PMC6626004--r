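# Simulation state: a mutable environment holding parallel per-slot vectors
# plus founder-allele matrices. Slots of dead individuals are recycled; stable
# integer ids are never reused, so parentage checks use ids, not slots.

new_sim_state <- function(n_slots, L) {
  st <- new.env(parent = emptyenv())
  st$n_slots <- n_slots
  st$L <- as.integer(L)
  st$alive <- logical(n_slots)
  st$loc <- integer(n_slots)        # 0 free, 1 wild, 2 captive
  st$sex <- integer(n_slots)        # 1 female, 2 male
  st$age <- integer(n_slots)
  st$Fi <- numeric(n_slots)         # inbreeding coefficient
  st$id <- integer(n_slots)
  st$sire_id <- integer(n_slots)
  st$dam_id <- integer(n_slots)
  st$pair <- integer(n_slots)       # partner slot, 0 = unpaired
  st$fed <- logical(n_slots)
  st$byear <- integer(n_slots)
  st$released <- logical(n_slots)
  st$rel_counted <- logical(n_slots)
  st$pid <- character(n_slots)      # pedigree / studbook id
  # loci x slots (raw bytes): one individual's genotype is one contiguous
  # 2 x L byte block; supports up to 255 distinct founder-allele labels
  st$A1 <- matrix(as.raw(0), L, n_slots)
  st$A2 <- matrix(as.raw(0), L, n_slots)
  st$free_stack <- rev(seq_len(n_slots))
  st$free_top <- n_slots
  st$next_id <- 1L
  st$n_lab <- 0L
  st$year <- 0L
  st$eff_releases <- 0L
  st$log <- character(0)
  class(st) <- "pva_state"
  st
}

log_note <- function(st, msg) {
  st$log <- c(st$log, msg)
  invisible(NULL)
}

grow_state <- function(st, need) {
  extra <- max(st$n_slots %/% 2L, need)
  pad_i <- integer(extra); pad_n <- numeric(extra); pad_l <- logical(extra)
  for (nm in c("loc", "sex", "age", "id", "sire_id", "dam_id", "pair", "byear")) {
    st[[nm]] <- c(st[[nm]], pad_i)
  }
  st$Fi <- c(st$Fi, pad_n)
  for (nm in c("alive", "fed", "released", "rel_counted")) {
    st[[nm]] <- c(st[[nm]], pad_l)
  }
  st$pid <- c(st$pid, character(extra))
  st$A1 <- cbind(st$A1, matrix(as.raw(0), st$L, extra))
  st$A2 <- cbind(st$A2, matrix(as.raw(0), st$L, extra))
  st$free_stack <- c(st$free_stack, integer(extra))
  st$free_stack[st$free_top + seq_len(extra)] <- st$n_slots + seq_len(extra)
  st$free_top <- st$free_top + extra
  st$n_slots <- st$n_slots + extra
  invisible(NULL)
}

alloc_slots <- function(st, n) {
  if (st$free_top < n) grow_state(st, n - st$free_top)
  slots <- st$free_stack[(st$free_top - n + 1L):st$free_top]
  st$free_top <- st$free_top - n
  slots
}

add_individuals <- function(st, n, sex, age, Fi, sire_id, dam_id, loc,
                            A1 = NULL, A2 = NULL, pid = NULL) {
  slots <- alloc_slots(st, n)
  ids <- st$next_id - 1L + seq_len(n)
  st$next_id <- st$next_id + n
  st$alive[slots] <- TRUE
  st$loc[slots] <- loc
  st$sex[slots] <- sex
  st$age[slots] <- age
  st$Fi[slots] <- Fi
  st$id[slots] <- ids
  st$sire_id[slots] <- sire_id
  st$dam_id[slots] <- dam_id
  st$pair[slots] <- 0L
  st$fed[slots] <- FALSE
  st$byear[slots] <- st$year
  st$released[slots] <- FALSE
  st$rel_counted[slots] <- FALSE
  st$pid[slots] <- if (is.null(pid)) "" else pid
  if (!is.null(A1)) st$A1[, slots] <- A1
  if (!is.null(A2)) st$A2[, slots] <- A2
  slots
}

kill_slots <- function(st, slots) {
  cpp_kill(st, as.integer(slots))
  invisible(NULL)
}

# create newborn individuals from parent slots; returns the new slots
spawn_offspring <- function(st, sires, dams, Fi, loc, sex_ratio) {
  n <- length(sires)
  if (st$free_top < n) grow_state(st, n - st$free_top)
  cpp_newborns(st, as.integer(sires), as.integer(dams), as.numeric(Fi),
               as.integer(loc), sex_ratio, st$year)
}

living_slots <- function(st, loc = NULL) {
  if (is.null(loc)) which(st$alive) else cpp_living(st$alive, st$loc, loc)
}

# sample() without the length-1 surprise
sample_vec <- function(x, size = length(x)) {
  if (length(x) <= 1L) {
    if (size >= length(x)) return(x) else return(x[seq_len(size)])
  }
  sample(x, size)
}

# stochastic rounding: floor plus Bernoulli on the fractional remainder
rstoch_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

# --- founder-allele genetics ------------------------------------------------

# Kinship estimate between paired individuals a[i], b[i] from allele sharing
# across the tracked loci; unbiased for the pedigree kinship coefficient.
allele_pair_kinship <- function(st, a, b) {
  cpp_pair_kinship(st$A1, st$A2, as.integer(a), as.integer(b))
}

# Full pairwise kinship-estimate matrix between two (small) sets of slots.
allele_cross_kinship <- function(st, rows, cols) {
  cpp_cross_kinship(st$A1, st$A2, as.integer(rows), as.integer(cols))
}

# Mean kinship of each candidate slot to a reference set of slots.
allele_mk_to_set <- function(st, cand, set) {
  cpp_mean_kinship_to_set(st$A1, st$A2, as.integer(cand), as.integer(set),
                          st$n_lab)
}

# Gene-diversity estimate (1 - mean kinship, ordered pairs incl. self) of a
# set of slots, averaged over the tracked loci.
allele_gd <- function(st, idx) {
  if (length(idx) == 0) return(NA_real_)
  cpp_gd(st$A1, st$A2, as.integer(idx), st$n_lab)
}

# Observed heterozygosity of a set of slots.
allele_ho <- function(st, idx) {
  if (length(idx) == 0) return(NA_real_)
  cpp_ho(st$A1, st$A2, as.integer(idx))
}

#' Initialize a simulation state from a population
#'
#' Drops founder alleles through the pedigree (one realization per tracked
#' locus, using the current RNG stream), assigns exact pedigree inbreeding
#' coefficients to the starting individuals, and loads the wild and captive
#' living sets.
#'
#' @param population a `pva_population` (see [make_initial_population()])
#' @param params a `pva_params`
#' @return a `pva_state` environment
#' @export
init_sim_state <- function(population, params) {
  ped <- population$ped
  wild <- population$wild_ids
  captive <- population$captive_ids
  living <- c(wild, captive)
  li <- ped_index(ped, living)
  L <- params$n_loci
  st <- new_sim_state(max(256L, 2L * length(living) + 128L), L)
  si0 <- match(ped$sire, ped$id); si0[is.na(si0)] <- 0L
  di0 <- match(ped$dam, ped$id); di0[is.na(di0)] <- 0L
  n_founder_sides <- sum(si0 == 0L) + sum(di0 == 0L)
  if (n_founder_sides > 255L) {
    stop("more than 255 founder-allele labels; reduce founder/phantom count")
  }
  al <- cpp_drop_alleles(si0, di0, L)
  st$n_lab <- al$n_lab
  year0 <- attr(ped, "ref_year")
  if (is.null(year0)) year0 <- max(ped$birth_year)
  age <- pmin(year0 - ped$birth_year[li], params$max_age)
  sire_idx <- match(ped$sire[li], ped$id)
  dam_idx <- match(ped$dam[li], ped$id)
  # stable ids for starting individuals = pedigree row index
  n0 <- length(li)
  slots <- alloc_slots(st, n0)
  st$next_id <- as.integer(nrow(ped) + 1L)
  st$alive[slots] <- TRUE
  st$loc[slots] <- rep(c(1L, 2L), c(length(wild), length(captive)))
  st$sex[slots] <- ifelse(ped$sex[li] == "F", 1L, 2L)
  st$age[slots] <- age
  st$Fi[slots] <- inbreeding_coefficient(ped, living)
  st$id[slots] <- li
  st$sire_id[slots] <- ifelse(is.na(sire_idx), 0L, sire_idx)
  st$dam_id[slots] <- ifelse(is.na(dam_idx), 0L, dam_idx)
  st$byear[slots] <- -(age)
  st$pid[slots] <- living
  st$A1[, slots] <- al$A1[, li, drop = FALSE]
  st$A2[, slots] <- al$A2[, li, drop = FALSE]
  st
}
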