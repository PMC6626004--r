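#' Monte-Carlo gene drop through a pedigree
#'
#' Each founder (and each unknown phantom parent side) carries two uniquely
#' labelled alleles; alleles are transmitted Mendelianly (one uniformly random
#' allele from each parent) down the pedigree in `n_reps` independent
#' replicates. One neutral locus is tracked per replicate; replicates play the
#' role of unlinked loci. Diversity statistics are estimated over replicates
#' for the living set.
#'
#' Gene diversity is estimated per replicate as \eqn{1 - \sum_k p_k^2} over
#' founder-allele frequencies in the living allele pool, whose expectation
#' equals one minus the mean kinship of the living set (ordered pairs
#' including self-pairs).
#'
#' @param ped a `wolf_pedigree`
#' @param living_ids nonempty character vector of ids forming the living set
#' @param n_reps number of gene-drop replicates (>= 1)
#' @param seed integer seed; results are deterministic given the seed
#' @return a `genetic_summary` list: `gd`, `ho`, `allelic_diversity`,
#'   `mean_kinship`, `fge`, with Monte-Carlo standard errors `gd_se`, `ho_se`,
#'   `allelic_diversity_se`, and `n_reps`
#' @export
gene_drop <- function(ped, living_ids, n_reps = 1000L, seed = 1L) {
  if (length(living_ids) == 0) stop("living set must be nonempty")
  if (n_reps < 1) stop("n_reps must be >= 1")
  live <- ped_index(ped, living_ids)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  R <- as.integer(n_reps)
  # allele label matrices: paternal (A1) and maternal (A2), one column set per
  # individual would be n x R; labels are integers, unique per founder side
  A1 <- matrix(0L, n, R)
  A2 <- matrix(0L, n, R)
  next_label <- 1L
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s)) {
      A1[i, ] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(R) < 0.5
      A1[i, ] <- ifelse(pick, A1[s, ], A2[s, ])
    }
    if (is.na(d)) {
      A2[i, ] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(R) < 0.5
      A2[i, ] <- ifelse(pick, A1[d, ], A2[d, ])
    }
  }
  n_lab <- next_label - 1L

  pool <- rbind(A1[live, , drop = FALSE], A2[live, , drop = FALSE])
  n_alleles <- nrow(pool)
  # per-replicate founder-allele counts: tabulate over a combined (label, rep)
  # linear index, then reshape to n_lab x R
  lin <- as.integer(pool) ## column-major: replicate-blocks
  lin <- lin + rep.int((seq_len(R) - 1L) * n_lab, rep.int(n_alleles, R))
  counts <- matrix(tabulate(lin, nbins = n_lab * R), nrow = n_lab, ncol = R)
  sumsq <- colSums((counts / n_alleles)^2)
  gd_rep <- 1 - sumsq
  het_rep <- colMeans(A1[live, , drop = FALSE] != A2[live, , drop = FALSE])
  ad_rep <- colSums(counts > 0L)

  mse <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  gd <- mean(gd_rep)
  summary <- list(
    gd = gd,
    gd_se = mse(gd_rep),
    ho = mean(het_rep),
    ho_se = mse(het_rep),
    allelic_diversity = mean(ad_rep),
    allelic_diversity_se = mse(ad_rep),
    mean_kinship = 1 - gd,
    fge = if (gd < 1) 1 / (2 * (1 - gd)) else Inf,
    n_reps = R,
    n_living = length(live)
  )
  class(summary) <- "genetic_summary"
  summary
}

#' @export
print.genetic_summary <- function(x, ...) {
  cat(sprintf(
    "<genetic_summary> n=%d  GD=%.4f  Ho=%.4f  mean kinship=%.4f  FGE=%.3f  alleles/locus=%.2f\n",
    x$n_living, x$gd, x$ho, x$mean_kinship, x$fge, x$allelic_diversity))
  invisible(x)
}

#' Gene diversity (expected heterozygosity) of a living set
#'
#' `GD = 1 - mean kinship` over all ordered pairs of living individuals
#' including self-pairs (Vortex-consistent convention), computed analytically
#' from the pedigree kinship matrix.
#'
#' @param ped a `wolf_pedigree`
#' @param living_ids nonempty vector of ids
#' @return gene diversity in \[0, 1\]
#' @export
gene_diversity <- function(ped, living_ids) {
  if (length(living_ids) == 0) stop("living set must be nonempty")
  K <- kinship_matrix(ped, living_ids)
  1 - mean(K)
}

#' Founder genome equivalents of a living set
#'
#' Number of unrelated, non-inbred founders that would carry the same gene
#' diversity: `FGE = 1 / (2 * mean kinship)`.
#'
#' @param ped a `wolf_pedigree`
#' @param living_ids nonempty vector of ids
#' @return founder genome equivalents (> 0)
#' @export
founder_genome_equivalents <- function(ped, living_ids) {
  if (length(living_ids) == 0) stop("living set must be nonempty")
  mk <- 1 - gene_diversity(ped, living_ids)
  if (mk <= 0) return(Inf)
  1 / (2 * mk)
}

#' Effective population size inferred from a gene-diversity decline
#'
#' Solves `gd_end = gd_start * (1 - 1/(2 Ne))^years` for `Ne`. Returns `NA`
#' (undefined) when no diversity was lost.
#'
#' @param gd_start,gd_end gene diversities with `0 < gd_end <= gd_start <= 1`
#' @param years elapsed years (>= 1)
#' @return effective population size, or `NA` when `gd_end == gd_start`
#' @export
ne_from_gd_decline <- function(gd_start, gd_end, years) {
  if (gd_end > gd_start) stop("gd_end must not exceed gd_start")
  if (gd_end <= 0 || gd_start > 1) stop("gene diversities must be in (0, 1]")
  if (years < 1) stop("years must be >= 1")
  if (gd_end == gd_start) return(NA_real_)
  lambda <- (gd_end / gd_start)^(1 / years)
  1 / (2 * (1 - lambda))
}

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used when reporting
#' percentages (IEEE `round()` rounds half to even).
#'
#' @param x numeric
#' @param digits decimal digits
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a pairing rate from field estimates
#'
#' The proportion of adult females pairing used in a parameter set is the mean
#' of the available field estimates, rounded half-up to one decimal in percent.
#'
#' @param estimates_pct numeric vector of estimates, in percent
#' @return derived value in percent, one decimal
#' @export
derive_pairing_rate <- function(estimates_pct) {
  round_half_up(mean(estimates_pct), 1)
}
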