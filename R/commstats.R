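#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T); `N` positions are excluded from
#' both numerator and denominator.
#'
#' @param seq A single sequence (character scalar).
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("ACGTN")  # 0.5
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  s <- canonicalize_seq(seq)
  counts <- table(factor(strsplit(s, "", TRUE)[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0L) stop("sequence contains no unambiguous bases")
  unname((counts[["G"]] + counts[["C"]]) / acgt)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation via `stats::cor.test(method = "spearman")`: rho is
#' the Pearson correlation of mid-ranks (ties receive average ranks) and
#' the default p-value comes from the t-approximation with n - 2 degrees
#' of freedom. For small samples without ties an exact permutation
#' p-value is available via `exact = TRUE`.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @param exact Use the exact permutation null distribution (only without
#'   ties; sensible for n < 10).
#' @return List with `rho` and `p_value`. A constant vector yields
#'   `rho = NA` with a warning (the correlation is undefined).
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Read profile of a sample
#'
#' Per-species read counts of one sample aliquot over the full reference
#' species domain (species with no reads count zero), the unit of the
#' reproducibility and covariate correlations.
#'
#' @param assignments An `assignment_table` (see [assign_reads]) or a
#'   named numeric vector of counts.
#' @param label Sample label.
#' @return Object of class `read_profile`: list with `label` and `counts`
#'   (named integer vector).
#' @export
read_profile <- function(assignments, label = "sample") {
  counts <- if (inherits(assignments, "assignment_table"))
    assignments$per_species else assignments
  if (is.null(names(counts))) stop("counts must be named by species")
  if (any(counts < 0)) stop("negative read counts")
  structure(list(label = label, counts = counts), class = "read_profile")
}

#' Reproducibility correlation between two aliquot profiles
#'
#' Spearman correlation of the paired per-species read counts of two
#' technical replicates of the same sample; high rho means the run is
#' reproducible in which species dominate.
#'
#' @param a,b [read_profile] objects over the same species domain.
#' @param exact Passed to [spearman_test].
#' @return List with `rho` and `p_value`.
#' @export
profile_correlation <- function(a, b, exact = FALSE) {
  stopifnot(inherits(a, "read_profile"), inherits(b, "read_profile"))
  if (!identical(sort(names(a$counts)), sort(names(b$counts))))
    stop("profiles cover different species domains")
  sp <- names(a$counts)
  spearman_test(as.numeric(a$counts[sp]), as.numeric(b$counts[sp]),
                exact = exact)
}

#' Correlation of read counts with a per-species covariate
#'
#' Spearman correlation between a sample's per-species read counts and a
#' covariate defined for every species (e.g. input DNA concentration or
#' the GC content of the marker region).
#'
#' @param profile A [read_profile].
#' @param covariate Named numeric vector over the same species domain.
#' @param exact Passed to [spearman_test].
#' @return List with `rho` and `p_value`.
#' @export
covariate_correlation <- function(profile, covariate, exact = FALSE) {
  stopifnot(inherits(profile, "read_profile"))
  missing <- setdiff(names(profile$counts), names(covariate))
  if (length(missing))
    stop("covariate undefined for species: ", paste(missing, collapse = ", "))
  sp <- names(profile$counts)
  spearman_test(as.numeric(profile$counts[sp]), as.numeric(covariate[sp]),
                exact = exact)
}

#' Detection accounting against a known composition
#'
#' Compares the species detected in an assignment (read count at least
#' `min_reads`) with the set of species actually pooled in the sample:
#' detected-and-true, missed, and unexpected (detected though absent,
#' the contamination signal).
#'
#' @param assignments An `assignment_table` or named count vector.
#' @param truth Character vector of species truly present.
#' @param min_reads Minimum read count for a species to count as detected
#'   (default 1).
#' @return Object of class `detection_report`: list with `truth`,
#'   `detected`, `missed`, `unexpected`, `detection_rate` and
#'   `min_reads`.
#' @export
detection_report <- function(assignments, truth, min_reads = 1) {
  counts <- if (inherits(assignments, "assignment_table"))
    assignments$per_species else assignments
  truth <- unique(as.character(truth))
  detected <- names(counts)[counts >= min_reads]
  structure(list(truth = truth,
                 detected = detected,
                 missed = setdiff(truth, detected),
                 unexpected = setdiff(detected, truth),
                 detection_rate = length(intersect(truth, detected)) /
                   length(truth),
                 min_reads = min_reads),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "detection_report: %d/%d true species detected (%.1f%%) at >= %d read(s)\n",
    length(intersect(x$truth, x$detected)), length(x$truth),
    100 * x$detection_rate, x$min_reads))
  if (length(x$missed))
    cat("  missed:", paste(x$missed, collapse = ", "), "\n")
  if (length(x$unexpected))
    cat("  unexpected:", paste(x$unexpected, collapse = ", "), "\n")
  invisible(x)
}
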