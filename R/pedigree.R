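#' Construct a validated pedigree
#'
#' A pedigree is a directed acyclic parentage structure over individuals.
#' Founders have both parents unknown. Individuals with exactly one known
#' parent are accepted and treated, for all genetic computations, as if the
#' unknown side were an unrelated phantom founder (standard studbook
#' convention).
#'
#' @param df data.frame with columns `id`, `sire`, `dam`, `sex`, `birth_year`,
#'   `location`. `sire`/`dam` may be `NA`, `""` or `"0"` for unknown parents.
#'   `sex` is `"F"` or `"M"`; `location` is `"captive"` or `"wild"`.
#' @return object of class `wolf_pedigree`: the normalized data.frame with a
#'   kinship cache attached.
#' @export
pedigree <- function(df) {
  required <- c("id", "sire", "dam", "sex", "birth_year", "location")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("pedigree table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ped <- data.frame(
    id = as.character(df$id),
    sire = normalize_parent(df$sire),
    dam = normalize_parent(df$dam),
    sex = as.character(df$sex),
    birth_year = as.integer(df$birth_year),
    location = as.character(df$location),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  # order so parents precede offspring (birth_year strictly increases down
  # lineages, enforced by validation)
  ped <- ped[order(ped$birth_year, ped$id), , drop = FALSE]
  rownames(ped) <- NULL
  attr(ped, "cache") <- new.env(parent = emptyenv())
  class(ped) <- c("wolf_pedigree", "data.frame")
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0" | toupper(x) == "UNKNOWN"] <- NA_character_
  x
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(ped$location %in% c("captive", "wild"))) {
    stop("location must be 'captive' or 'wild'")
  }
  if (anyNA(ped$birth_year)) stop("birth_year must be integer, no NA")
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  bad_sire <- !is.na(ped$sire) & is.na(si)
  bad_dam <- !is.na(ped$dam) & is.na(di)
  if (any(bad_sire | bad_dam)) {
    stop("referenced parent ids absent from pedigree: ",
         paste(unique(c(ped$sire[bad_sire], ped$dam[bad_dam])), collapse = ", "))
  }
  if (any(ped$sire == ped$id, na.rm = TRUE) || any(ped$dam == ped$id, na.rm = TRUE)) {
    stop("self-parentage is not allowed")
  }
  if (any(ped$sex[si[!is.na(si)]] != "M")) stop("sire must be male")
  if (any(ped$sex[di[!is.na(di)]] != "F")) stop("dam must be female")
  # acyclicity via strict birth-year ordering along parent edges
  if (any(ped$birth_year[si[!is.na(si)]] >= ped$birth_year[!is.na(si)]) ||
      any(ped$birth_year[di[!is.na(di)]] >= ped$birth_year[!is.na(di)])) {
    stop("parent birth_year must be strictly less than offspring birth_year ",
         "(cyclic or time-inconsistent pedigree)")
  }
  invisible(TRUE)
}

#' Founders of a pedigree
#'
#' @param ped a `wolf_pedigree`
#' @return character vector of ids with both parents unknown
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$sire) & is.na(ped$dam)]
}

#' @export
print.wolf_pedigree <- function(x, ...) {
  cat(sprintf("<wolf_pedigree> %d individuals (%d founders), years %d-%d\n",
              nrow(x), length(founders(x)), min(x$birth_year), max(x$birth_year)))
  cat(sprintf("  captive: %d  wild: %d\n",
              sum(x$location == "captive"), sum(x$location == "wild")))
  invisible(x)
}

#' Read a pedigree from a tab-delimited file
#'
#' Expects a header with columns id, sire, dam, sex, birth_year, location;
#' unknown parents encoded as `0` or empty.
#'
#' @param path file path
#' @return `wolf_pedigree`
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  pedigree(df)
}

#' Write a pedigree to a tab-delimited file
#'
#' @param ped a `wolf_pedigree`
#' @param path file path
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ped_index <- function(ped, ids, what = "id") {
  i <- match(ids, ped$id)
  if (anyNA(i)) {
    stop("unknown ", what, ": ", paste(ids[is.na(i)], collapse = ", "))
  }
  i
}

#' Additive kinship matrix of a pedigree
#'
#' Standard recursive (tabular) kinship: for individual `x` with parents `s`,
#' `d`, `f(x, y) = (f(s, y) + f(d, y)) / 2` for `y` preceding `x`, and
#' `f(x, x) = (1 + f(s, d)) / 2`. Unknown parents contribute zero kinship.
#' The full matrix is computed once per pedigree and cached.
#'
#' @param ped a `wolf_pedigree`
#' @param ids optional subset of ids (rows/columns of the returned matrix)
#' @return numeric matrix with dimnames = ids
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  cache <- attr(ped, "cache")
  K <- if (!is.null(cache)) cache$K else NULL
  if (is.null(K)) {
    n <- nrow(ped)
    si <- match(ped$sire, ped$id)
    di <- match(ped$dam, ped$id)
    K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        v <- numeric(i - 1L)
        if (!is.na(s)) v <- v + K[s, prev]
        if (!is.na(d)) v <- v + K[d, prev]
        v <- v / 2
        K[i, prev] <- v
        K[prev, i] <- v
      }
      fsd <- if (!is.na(s) && !is.na(d)) K[s, d] else 0
      K[i, i] <- 0.5 * (1 + fsd)
    }
    if (!is.null(cache)) cache$K <- K
  }
  if (is.null(ids)) return(K)
  K[ped_index(ped, ids), ped_index(ped, ids), drop = FALSE]
}

#' Kinship coefficient between two individuals
#'
#' Probability that random alleles drawn from each are identical by descent.
#' Distinct founders are unrelated by definition; `kinship(x, x) =
#' (1 + F_x) / 2`.
#'
#' @param ped a `wolf_pedigree`
#' @param id_a,id_b individual ids
#' @return kinship coefficient in \[0, 1\]
#' @export
kinship <- function(ped, id_a, id_b) {
  K <- kinship_matrix(ped)
  K[ped_index(ped, id_a), ped_index(ped, id_b)]
}

#' Inbreeding coefficient of an individual
#'
#' `F = kinship(sire, dam)`; founders and individuals with any unknown parent
#' have `F = 0`.
#'
#' @param ped a `wolf_pedigree`
#' @param id individual id (vectorized)
#' @return numeric vector of inbreeding coefficients
#' @export
inbreeding_coefficient <- function(ped, id) {
  i <- ped_index(ped, id)
  K <- kinship_matrix(ped)
  si <- match(ped$sire[i], ped$id)
  di <- match(ped$dam[i], ped$id)
  out <- numeric(length(i))
  known <- !is.na(si) & !is.na(di)
  if (any(known)) out[known] <- K[cbind(si[known], di[known])]
  out
}
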