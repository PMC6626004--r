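# Factorial sensitivity analysis contrasting two PVA parameterizations:
# design construction, scenario execution, contrast regressions with
# standardized-coefficient partitioning, and dispersion summaries.

#' Define a sensitivity-analysis factor
#'
#' A factor carries parameter patches for its 2013 and 2017 levels. A factor
#' may expand to more than one binary design column (each with its own patch
#' pair); multi-column factors are crossed fully in the design but merged
#' into a single analysis factor when fitting contrast models.
#'
#' @param name analysis-factor name
#' @param category `"biological"`, `"policy"` or `"mixed"`
#' @param patch_2013,patch_2017 named lists of `pva_params` fields (single
#'   design column); ignored when `columns` is given
#' @param columns optional named list of design columns, each a list with
#'   elements `patch_2013` and `patch_2017`
#' @return object of class `factor_spec`
#' @export
factor_spec <- function(name, category, patch_2013 = NULL, patch_2017 = NULL,
                        columns = NULL) {
  if (!category %in% c("biological", "policy", "mixed")) {
    stop("category must be biological, policy or mixed")
  }
  if (is.null(columns)) {
    if (is.null(patch_2013) || is.null(patch_2017)) {
      stop("factor needs both a 2013 and a 2017 patch")
    }
    columns <- stats::setNames(
      list(list(patch_2013 = patch_2013, patch_2017 = patch_2017)), name)
  }
  for (col in columns) {
    if (!setequal(names(col$patch_2013), names(col$patch_2017))) {
      stop("a column's 2013 and 2017 patches must touch the same fields")
    }
  }
  out <- list(name = name, category = category, columns = columns)
  class(out) <- "factor_spec"
  out
}

pull_patch <- function(params, fields) {
  stats::setNames(lapply(fields, function(f) params[[f]]), fields)
}

#' The default six-factor specification
#'
#' Builds the six analysis factors of the 2013-vs-2017 contrast from the
#' packaged parameter sets: proportion of females pairing and disease effects
#' (biological); releases from captivity and population cap (policy);
#' inbreeding jointly with supplemental feeding, and adult mortality (mixed).
#' The inbreeding/feeding factor expands to two design columns (inbreeding
#' load; fed fraction), so the full cross has `2^7 = 128` scenarios while six
#' analysis factors are fitted.
#'
#' @param parameter_sets list with elements `"2013"` and `"2017"`; defaults to
#'   [default_parameter_sets()]
#' @return list of `factor_spec`
#' @export
default_factor_specs <- function(parameter_sets = default_parameter_sets()) {
  a <- parameter_sets[["2013"]]
  b <- parameter_sets[["2017"]]
  pf <- function(fields) list(patch_2013 = pull_patch(a, fields),
                              patch_2017 = pull_patch(b, fields))
  list(
    factor_spec("pairing", "biological",
                pull_patch(a, "p_pair"), pull_patch(b, "p_pair")),
    factor_spec("disease", "biological",
                pull_patch(a, c("disease_freq", "disease_sev_survival",
                                "disease_sev_repro")),
                pull_patch(b, c("disease_freq", "disease_sev_survival",
                                "disease_sev_repro"))),
    factor_spec("inbreeding_feeding", "mixed", columns = list(
      inbreeding = pf("lethal_equivalents"),
      feeding = pf("fed_fraction"))),
    factor_spec("mortality", "mixed",
                pull_patch(a, "mortality"), pull_patch(b, "mortality")),
    factor_spec("releases", "policy",
                pull_patch(a, "release_schedule"),
                pull_patch(b, "release_schedule")),
    factor_spec("cap", "policy",
                pull_patch(a, "cap"), pull_patch(b, "cap"))
  )
}

#' Build the full factorial scenario design
#'
#' Crosses every design column of every factor at its 2013 and 2017 levels
#' and instantiates one validated `pva_params` per combination. With the
#' default factor specification (seven design columns) this yields 128
#' scenarios with stable ids and deterministic order.
#'
#' @param factors list of `factor_spec` (default: [default_factor_specs()])
#' @param base `pva_params` used for all non-contrasted fields (default: the
#'   packaged 2013 set)
#' @return object of class `pva_design`: `design` (data.frame of scenario id
#'   and column levels), `params` (list of `pva_params`), `factors`
#' @export
build_factorial_design <- function(factors = default_factor_specs(),
                                   base = default_parameter_sets()[["2013"]]) {
  if (length(factors) < 1) stop("at least one factor is required")
  cols <- list()
  col_factor <- character(0)
  for (f in factors) {
    for (cn in names(f$columns)) {
      if (cn %in% names(cols)) stop("duplicate design column name: ", cn)
      cols[[cn]] <- f$columns[[cn]]
      col_factor[cn] <- f$name
    }
  }
  touched <- unlist(lapply(cols, function(cl) names(cl$patch_2013)))
  if (anyDuplicated(touched)) {
    stop("conflicting patches touch the same parameter: ",
         paste(unique(touched[duplicated(touched)]), collapse = ", "))
  }
  grid <- do.call(expand.grid,
                  c(stats::setNames(rep(list(c("2013", "2017")), length(cols)),
                                    names(cols)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  n <- nrow(grid)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    p <- unclass(base)
    for (cn in names(cols)) {
      patch <- if (grid[i, cn] == "2013") cols[[cn]]$patch_2013 else
        cols[[cn]]$patch_2017
      for (fld in names(patch)) p[[fld]] <- patch[[fld]]
    }
    p$label <- sprintf("S%03d", i)
    class(p) <- "pva_params"
    validate_params(p)
    params[[i]] <- p
  }
  design <- cbind(data.frame(id = sprintf("S%03d", seq_len(n)),
                             stringsAsFactors = FALSE), grid)
  out <- list(design = design, params = params, factors = factors,
              col_factor = col_factor)
  class(out) <- "pva_design"
  out
}

#' @export
print.pva_design <- function(x, ...) {
  cat(sprintf("<pva_design> %d scenarios over %d design columns (%d analysis factors)\n",
              nrow(x$design), length(x$col_factor), length(x$factors)))
  invisible(x)
}

#' Run every scenario of a factorial design
#'
#' @param design a `pva_design`
#' @param population a `pva_population`
#' @param n_iter iterations per scenario
#' @param years simulation horizon
#' @param seed master seed; per-scenario seeds are derived deterministically
#'   from scenario position, so any subset reproduces the full run's values
#' @param progress print one line per completed scenario
#' @param subset optional integer vector of scenario indices to run (used for
#'   resuming partial runs); default all
#' @return object of class `pva_factorial`: the design plus a `results`
#'   data.frame (one row per scenario: `n_ext`, `n_quasi`, `p_ext`,
#'   `p_quasi`, `mean_GD`, `n_iter`, `seed`)
#' @export
run_factorial <- function(design, population, n_iter = 100L, years = 100L,
                          seed = 1L, progress = FALSE, subset = NULL) {
  n <- nrow(design$design)
  seeds <- derive_seeds(seed, n, stream = 1L)
  if (is.null(subset)) subset <- seq_len(n)
  rows <- vector("list", length(subset))
  for (k in seq_along(subset)) {
    i <- subset[k]
    sc <- run_scenario(design$params[[i]], population, n_iter = n_iter,
                       years = years, seed = seeds[i])
    rows[[k]] <- data.frame(
      id = design$design$id[i],
      n_ext = as.integer(round(sc$p_ext * n_iter)),
      n_quasi = as.integer(round(sc$p_quasi * n_iter)),
      p_ext = sc$p_ext,
      p_quasi = sc$p_quasi,
      mean_GD = sc$mean_GD,
      n_iter = n_iter,
      seed = seeds[i],
      stringsAsFactors = FALSE
    )
    if (progress) {
      cat(sprintf("%s: p_ext=%.3f p_quasi=%.3f GD=%s\n", design$design$id[i],
                  sc$p_ext, sc$p_quasi,
                  if (is.na(sc$mean_GD)) "NA" else sprintf("%.4f", sc$mean_GD)))
    }
  }
  out <- design
  out$results <- do.call(rbind, rows)
  out$n_iter <- n_iter
  out$years <- years
  out$seed <- seed
  class(out) <- c("pva_factorial", "pva_design")
  out
}

# Analysis-factor predictor matrix: per factor, the mean of its design
# columns coded 0 (2013 level) / 1 (2017 level).
factor_predictors <- function(design) {
  facs <- design$factors
  out <- data.frame(row.names = seq_len(nrow(design$design)))
  for (f in facs) {
    cols <- names(f$columns)
    v <- rowMeans(sapply(cols, function(cn) {
      as.numeric(design$design[[cn]] == "2017")
    }))
    out[[f$name]] <- v
  }
  out
}

factor_categories <- function(factors) {
  stats::setNames(vapply(factors, function(f) f$category, character(1)),
                  vapply(factors, function(f) f$name, character(1)))
}

# Firth-style bias-reduced binomial logistic regression (events/trials),
# used as fallback under (quasi-)separation.
firth_logistic <- function(X, events, trials, max_iter = 200, tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- trials * p * (1 - p)
    XtWX <- crossprod(X * w, X)
    XtWX_inv <- solve(XtWX)
    h <- rowSums((X %*% XtWX_inv) * X) * w
    U <- drop(crossprod(X, events - trials * p + h * (0.5 - p)))
    delta <- drop(XtWX_inv %*% U)
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- trials * p * (1 - p)
  se <- sqrt(diag(solve(crossprod(X * w, X))))
  list(coefficients = beta, se = se, iterations = iter)
}

#' Fit a contrast regression over factorial scenario results
#'
#' Binary-derived responses (extinction, quasi-extinction) are fitted by
#' binomial logistic regression on aggregated events/trials per scenario
#' (the scenario is the sample unit); genetic diversity is fitted by ordinary
#' least squares on scenario means. Predictors are the analysis factors coded
#' 0 (2013 level) to 1 (2017 level), with multi-column factors averaged into
#' a single predictor. Standardized coefficients are the coefficient divided
#' by its standard error (z for logistic, t for linear). Degenerate responses
#' (constant across scenarios) are flagged and their standardized
#' coefficients reported as `NA`; (quasi-)separated logistic fits fall back
#' to Firth bias reduction, with a notice recorded.
#'
#' @param factorial a `pva_factorial` from [run_factorial()]
#' @param response `"extinction"`, `"quasi_extinction"` or
#'   `"genetic_diversity"`
#' @return object of class `contrast_model`: `response`, `family`,
#'   `coefficients`, `se`, `standardized`, `categories`, `degenerate`,
#'   `firth`, `notes`
#' @export
fit_contrast_model <- function(factorial,
                               response = c("extinction", "quasi_extinction",
                                            "genetic_diversity")) {
  response <- match.arg(response)
  if (is.null(factorial$results)) stop("factorial has no results; run_factorial first")
  preds <- factor_predictors(factorial)
  cats <- factor_categories(factorial$factors)
  notes <- character(0)
  fam <- if (response == "genetic_diversity") "linear" else "binomial_logistic"
  if (fam == "binomial_logistic") {
    ev <- if (response == "extinction") factorial$results$n_ext else
      factorial$results$n_quasi
    tr <- factorial$results$n_iter
    degenerate <- length(unique(ev)) == 1L && (all(ev == 0) || all(ev == tr))
    if (degenerate) {
      notes <- c(notes, sprintf("degenerate %s response: constant across scenarios",
                                response))
      std <- stats::setNames(rep(NA_real_, ncol(preds)), names(preds))
      out <- list(response = response, family = fam,
                  coefficients = std, se = std, standardized = std,
                  categories = cats, degenerate = TRUE, firth = FALSE,
                  notes = notes)
      class(out) <- "contrast_model"
      return(out)
    }
    dat <- cbind(preds, .ev = ev, .tr = tr)
    fml <- stats::as.formula(paste("cbind(.ev, .tr - .ev) ~",
                                   paste(names(preds), collapse = " + ")))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    coefs <- stats::coef(fit)[names(preds)]
    if (sep || any(abs(coefs) > 15)) {
      notes <- c(notes, "quasi-separation detected: Firth bias-reduction engaged")
      X <- cbind(1, as.matrix(preds))
      fr <- firth_logistic(X, ev, tr)
      coefs <- stats::setNames(fr$coefficients[-1], names(preds))
      ses <- stats::setNames(fr$se[-1], names(preds))
      firth <- TRUE
    } else {
      sm <- summary(fit)$coefficients
      ses <- stats::setNames(sm[names(preds), "Std. Error"], names(preds))
      firth <- FALSE
    }
    std <- coefs / ses
  } else {
    y <- factorial$results$mean_GD
    ok <- !is.na(y)
    if (sum(!ok) > 0) {
      notes <- c(notes, sprintf("%d all-extinct scenarios dropped from GD fit",
                                sum(!ok)))
    }
    degenerate <- stats::var(y[ok]) == 0 || sum(ok) <= ncol(preds) + 1
    if (degenerate) {
      notes <- c(notes, "degenerate genetic_diversity response")
      std <- stats::setNames(rep(NA_real_, ncol(preds)), names(preds))
      out <- list(response = response, family = fam,
                  coefficients = std, se = std, standardized = std,
                  categories = cats, degenerate = TRUE, firth = FALSE,
                  notes = notes)
      class(out) <- "contrast_model"
      return(out)
    }
    dat <- cbind(preds[ok, , drop = FALSE], .y = y[ok])
    fml <- stats::as.formula(paste(".y ~", paste(names(preds), collapse = " + ")))
    fit <- stats::lm(fml, data = dat)
    sm <- summary(fit)$coefficients
    coefs <- stats::setNames(sm[names(preds), "Estimate"], names(preds))
    ses <- stats::setNames(sm[names(preds), "Std. Error"], names(preds))
    std <- coefs / ses
    firth <- FALSE
    degenerate <- FALSE
  }
  out <- list(response = response, family = fam, coefficients = coefs,
              se = ses, standardized = std, categories = cats,
              degenerate = degenerate, firth = firth, notes = notes)
  class(out) <- "contrast_model"
  out
}

#' @export
print.contrast_model <- function(x, ...) {
  cat(sprintf("<contrast_model> %s (%s)%s\n", x$response, x$family,
              if (x$firth) " [Firth]" else ""))
  df <- data.frame(factor = names(x$standardized),
                   category = unname(x$categories[names(x$standardized)]),
                   coef = unname(x$coefficients),
                   se = unname(x$se),
                   standardized = unname(x$standardized))
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-factor and per-category shares of summed standardized coefficients
#'
#' `share_i = |std_i| / sum_j |std_j| * 100`; category shares sum the factor
#' shares within biological, policy and mixed. Factors with undefined
#' standardized coefficients are excluded (with a notice); at least one must
#' be defined.
#'
#' @param model a `contrast_model`
#' @return list with `factor_shares` (data.frame: factor, category,
#'   standardized, share_pct) and `category_shares` (data.frame: category,
#'   share_pct)
#' @export
contrast_shares <- function(model) {
  std <- model$standardized
  ok <- !is.na(std)
  if (!any(ok)) stop("no defined standardized coefficients")
  if (any(!ok)) {
    message("excluding factors with undefined standardized coefficients: ",
            paste(names(std)[!ok], collapse = ", "))
  }
  s <- abs(std[ok])
  share <- 100 * s / sum(s)
  fs <- data.frame(
    factor = names(share),
    category = unname(model$categories[names(share)]),
    standardized = unname(std[ok]),
    share_pct = unname(share),
    stringsAsFactors = FALSE
  )
  cs <- stats::aggregate(share_pct ~ category, data = fs, FUN = sum)
  list(factor_shares = fs, category_shares = cs)
}

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with linear-interpolation (type-7) quartiles: a
#' scale-free spread measure in \[0, 1\] for nonnegative data. Returns `NA`
#' with a notice when `Q1 = Q3 = 0`.
#'
#' @param values nonnegative numeric vector, length >= 4
#' @return dispersion coefficient in \[0, 1\], or `NA`
#' @export
qcd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values")
  if (any(values < 0)) stop("values must be nonnegative")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] == 0 && q[2] == 0) {
    message("qcd undefined: both quartiles are zero")
    return(NA_real_)
  }
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Dispersion of the three output metrics across factorial scenarios
#'
#' @param factorial a `pva_factorial` with results
#' @return data.frame with columns `metric` and `qcd` for extinction
#'   probability, quasi-extinction probability and genetic diversity
#' @export
qcd_summary <- function(factorial) {
  r <- factorial$results
  data.frame(
    metric = c("extinction", "quasi_extinction", "genetic_diversity"),
    qcd = c(qcd(r$p_ext), qcd(r$p_quasi), qcd(r$mean_GD[!is.na(r$mean_GD)]))
  )
}
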