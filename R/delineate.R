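#' Species-resolution metrics of a cluster set
#'
#' With one reference sequence per species, a species counts as resolved
#' when its sequence forms a singleton cluster; clusters holding two or
#' more species are the unresolved residue. The resolved fraction is the
#' criterion optimized when choosing the similarity threshold.
#'
#' @param clusters A `cluster_set` over one-sequence-per-species records.
#' @param taxonomy Named character vector mapping sequence id to species,
#'   or a taxonomy `data.frame` (see [read_taxonomy]) whose `ref_id`
#'   column is used as the id.
#' @return An object of class `resolution_report`: list with `n_species`,
#'   `n_clusters`, `n_singletons`, `resolved_fraction`, and `unresolved`
#'   (list of `(cluster, species)` for each multi-member cluster).
#' @export
resolution_metrics <- function(clusters, taxonomy) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (is.data.frame(taxonomy))
    taxonomy <- setNames(taxonomy$species, taxonomy$ref_id)
  ids <- unlist(lapply(clusters$clusters, function(cl) cl$members$id))
  if (anyNA(match(ids, names(taxonomy))))
    stop("unlabeled sequence id(s): ",
         paste(setdiff(ids, names(taxonomy)), collapse = ", "))
  sizes <- vapply(clusters$clusters, function(cl) nrow(cl$members), integer(1))
  n_species <- length(ids)
  multi <- which(sizes > 1L)
  unresolved <- lapply(multi, function(k) {
    list(cluster = clusters$clusters[[k]]$index,
         species = unname(taxonomy[clusters$clusters[[k]]$members$id]))
  })
  n_resolved <- sum(sizes == 1L)
  structure(list(n_species = n_species,
                 n_clusters = length(sizes),
                 n_singletons = sum(sizes == 1L),
                 resolved_fraction = n_resolved / n_species,
                 unresolved = unresolved),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf(
    "resolution_report: %d/%d species resolved (%.1f%%), %d clusters\n",
    x$n_singletons, x$n_species, 100 * x$resolved_fraction, x$n_clusters))
  for (u in x$unresolved)
    cat(sprintf("  cluster %d: %s\n", u$cluster,
                paste(u$species, collapse = " + ")))
  invisible(x)
}

#' Threshold x homopolymer-cap delineation sweep
#'
#' For every homopolymer cap level the reference library is run-capped
#' ([cap_runs]) and then clustered de novo ([greedy_cluster]) at every
#' similarity threshold; the resulting cluster counts form the sweep
#' grid. For a fixed cap the cluster count is non-decreasing in the
#' threshold. `Inf` (or `NA`) as a cap level means the unmodified
#' library.
#'
#' @param library A [ref_library].
#' @param thresholds Numeric vector of thresholds in `(0, 1]`; default
#'   `c(0.97, 0.98, 0.99, 1.00)`.
#' @param caps Numeric vector of cap levels; default
#'   `c(Inf, 5, 4, 3, 2)` (uncapped plus the 5-, 4-, 3- and 2-mer
#'   libraries).
#' @param params An [identity_params] object.
#' @param mode Clustering mode passed to [greedy_cluster].
#' @return An object of class `delineation_sweep`: list with `grid`
#'   (`data.frame` of `threshold`, `cap`, `n_clusters`, `n_singletons`,
#'   `resolved_fraction`), `thresholds`, `caps`, and `cluster_sets`
#'   (nested list keyed by cap label then threshold label).
#' @export
threshold_sweep <- function(library, thresholds = c(0.97, 0.98, 0.99, 1.00),
                            caps = c(Inf, 5, 4, 3, 2),
                            params = identity_params(),
                            mode = "first_fit") {
  stopifnot(inherits(library, "ref_library"))
  stopifnot(all(thresholds > 0 & thresholds <= 1))
  tax <- setNames(library$taxonomy$species, library$taxonomy$ref_id)
  rows <- list()
  sets <- list()
  for (cap in caps) {
    capped <- if (is.na(cap) || !is.finite(cap)) library$records
              else cap_runs(library$records, cap)
    cap_lab <- if (is.na(cap) || !is.finite(cap)) "uncapped"
               else as.character(as.integer(cap))
    sets[[cap_lab]] <- list()
    for (t in thresholds) {
      cs <- greedy_cluster(capped, t, params = params, mode = mode)
      rep <- resolution_metrics(cs, tax)
      t_lab <- format(t, nsmall = 2)
      sets[[cap_lab]][[t_lab]] <- cs
      rows[[length(rows) + 1L]] <-
        data.frame(threshold = t, cap = cap_lab,
                   n_clusters = rep$n_clusters,
                   n_singletons = rep$n_singletons,
                   resolved_fraction = rep$resolved_fraction)
    }
  }
  structure(list(grid = do.call(rbind, rows), thresholds = thresholds,
                 caps = caps, cluster_sets = sets),
            class = "delineation_sweep")
}

#' @export
print.delineation_sweep <- function(x, ...) {
  cat("delineation_sweep: cluster counts by threshold and cap\n")
  wide <- reshape_sweep(x$grid, "n_clusters")
  print(wide)
  invisible(x)
}

reshape_sweep <- function(grid, value) {
  caps <- unique(grid$cap)
  ths <- sort(unique(grid$threshold))
  out <- sapply(caps, function(cp)
    sapply(ths, function(t)
      grid[[value]][grid$cap == cp & grid$threshold == t][1]))
  out <- matrix(out, nrow = length(ths),
                dimnames = list(threshold = format(ths), cap = caps))
  out
}

#' @method plot delineation_sweep
#' @export
plot.delineation_sweep <- function(x, ...) {
  wide <- reshape_sweep(x$grid, "n_clusters")
  ths <- as.numeric(rownames(wide))
  graphics::matplot(ths, wide, type = "b", pch = 19, lty = 1,
                    xlab = "similarity threshold", ylab = "number of clusters",
                    ...)
  graphics::legend("topleft", legend = colnames(wide), col = seq_len(ncol(wide)),
                   lty = 1, pch = 19, bty = "n", title = "cap")
  invisible(x)
}

#' Pick the similarity threshold maximizing species resolution
#'
#' Returns the threshold with the highest resolved fraction; ties are
#' broken toward the lowest threshold (the more merge-tolerant choice).
#'
#' @param reports Either a named numeric vector of resolved fractions
#'   keyed by threshold, a named list of [resolution_metrics] reports
#'   keyed by threshold, or a `delineation_sweep` (in which case `cap`
#'   selects the grid slice, default `"3"`).
#' @param cap Cap label used when `reports` is a sweep.
#' @return The selected threshold as a numeric scalar.
#' @examples
#' pick_threshold(c(`0.97` = 0.79, `0.98` = 0.83, `0.99` = 0.88,
#'                  `1` = 0.88))  # 0.99
#' @export
pick_threshold <- function(reports, cap = "3") {
  if (inherits(reports, "delineation_sweep")) {
    g <- reports$grid[reports$grid$cap == cap, ]
    if (!nrow(g)) stop("no sweep entries for cap ", cap)
    reports <- setNames(g$resolved_fraction, g$threshold)
  }
  if (is.list(reports) && length(reports) &&
      inherits(reports[[1]], "resolution_report"))
    reports <- vapply(reports, function(r) r$resolved_fraction, numeric(1))
  if (!length(reports)) stop("no resolution reports supplied")
  th <- as.numeric(names(reports))
  if (anyNA(th)) stop("reports must be keyed by numeric thresholds")
  ord <- order(th)
  th <- th[ord]; v <- unname(reports[ord])
  th[which.max(v)]  # which.max takes the first (lowest threshold) on ties
}
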