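#' One-year age bin
#'
#' Ages are modeled at one-year intervals: bin(a) = floor(a), fifteen bins
#' covering [4, 19).
#'
#' @param age numeric vector of ages in [4, 19).
#' @return integer vector of bin lower edges (4..18).
#' @export
age_bin <- function(age) {
  if (any(age < 4 | age >= 19)) stop("ages must lie in [4, 19)")
  as.integer(floor(age))
}

#' Stratified train/validation/test split
#'
#' Within each stratum, subjects are shuffled by the seed and cut at the
#' cumulative ratios with largest-remainder rounding, so per-stratum counts
#' are within one subject of the requested fractions. Default ratios follow
#' the 7:1.5:1.5 scheme.
#'
#' @param metadata data.frame with a \code{subject_id} column, \code{age}
#'   and/or the stratification columns.
#' @param ratios named numeric vector (train, val, test) summing to 1.
#' @param strata character vector of stratification variables; "age_bin" is
#'   derived from \code{age} if absent.
#' @param seed integer seed.
#' @return data.frame (subject_id, split) with the ratios/strata/seed stored
#'   as attributes; split is a factor with levels train/val/test.
#' @export
stratified_split <- function(metadata,
                             ratios = c(train = 0.7, val = 0.15, test = 0.15),
                             strata = c("sex", "age_bin"), seed = 1) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3)
  md <- metadata
  if ("age_bin" %in% strata && !"age_bin" %in% names(md))
    md$age_bin <- age_bin(md$age)
  missing_cols <- setdiff(strata, names(md))
  if (length(missing_cols))
    stop("stratum columns absent from metadata: ",
         paste(missing_cols, collapse = ", "))
  key <- if (length(strata)) interaction(md[strata], drop = FALSE) else
    factor(rep("all", nrow(md)))
  out <- with_seed(seed, {
    res <- character(nrow(md))
    for (lev in levels(key)) {
      idx <- which(key == lev)
      if (!length(idx)) {
        warning("empty stratum: ", lev)
        next
      }
      counts <- largest_remainder(length(idx), ratios)
      res[sample(idx)] <- rep(names(ratios), counts)
    }
    res
  })
  sp <- data.frame(subject_id = md$subject_id,
                   split = factor(out, levels = names(ratios)),
                   stringsAsFactors = FALSE)
  attr(sp, "ratios") <- ratios
  attr(sp, "strata") <- strata
  attr(sp, "seed") <- seed
  sp
}

largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Age-specific subsets for the sex-classification task
#'
#' Subjects with floor(age) equal to each requested bin, mirroring the five
#' key developmental time points (6, 9, 12, 15 and 18 years).
#'
#' @param metadata data.frame with \code{age}.
#' @param ages integer bins to extract.
#' @return named list of metadata subsets.
#' @export
select_age_subsets <- function(metadata, ages = c(6, 9, 12, 15, 18)) {
  b <- age_bin(metadata$age)
  out <- lapply(ages, function(a) metadata[b == a, , drop = FALSE])
  names(out) <- as.character(ages)
  out
}
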