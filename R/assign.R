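#' Assign reads to reference species
#'
#' Compares every (filtered, run-capped) read against the equally
#' run-capped reference library and attributes it to the best-identity
#' species at or above the threshold; the rest form the unassigned pool.
#' When the reference has been run-capped (i.e. produced by [cap_runs],
#' which marks its output), reads must be capped at least as hard:
#' uncapped reads carrying longer runs than the reference's cap would
#' have their run-length sequencing errors penalized on one side only.
#' That mismatch is detected via [max_run_length] and is an error.
#'
#' @param reads A [seq_records] object (already filtered and capped).
#' @param reference A [ref_library] capped the same way.
#' @param threshold Identity threshold (default 0.99).
#' @param params An [identity_params] object.
#' @return An object of class `assignment_table`: list with `per_read`
#'   (`data.frame` of `id`, `species`, `identity`), `per_species` (named
#'   integer vector of read counts over all library species, zeros
#'   included) and `unassigned` (character vector of read ids). Counts
#'   plus unassigned always add up to the number of input reads.
#' @export
assign_reads <- function(reads, reference, threshold = 0.99,
                         params = identity_params()) {
  stopifnot(inherits(reads, "seq_records"), inherits(reference, "ref_library"))
  ref_cap <- attr(reference$records, "cap")
  if (!is.null(ref_cap) && length(reads) && max_run_length(reads) > ref_cap)
    stop("cap mismatch: reads contain homopolymer runs up to ",
         max_run_length(reads), " bases but the reference library is ",
         "capped at ", ref_cap,
         "; cap reads and reference to the same k before assignment")
  species_domain <- reference$taxonomy$species
  if (!length(reads)) {
    return(structure(list(per_read = data.frame(id = character(),
                                                species = character(),
                                                identity = numeric()),
                          per_species = setNames(integer(length(species_domain)),
                                                 species_domain),
                          unassigned = character(),
                          threshold = threshold),
                     class = "assignment_table"))
  }
  res <- cluster_against_reference(reads, reference, threshold, params)
  counts <- setNames(integer(length(species_domain)), species_domain)
  tab <- table(res$matched$species)
  counts[names(tab)] <- as.integer(tab)
  structure(list(per_read = res$matched, per_species = counts,
                 unassigned = res$unmatched, threshold = threshold),
            class = "assignment_table")
}

#' @export
print.assignment_table <- function(x, ...) {
  n <- nrow(x$per_read) + length(x$unassigned)
  cat(sprintf("assignment_table: %d/%d reads assigned (%.1f%%) at threshold %s\n",
              nrow(x$per_read), n,
              if (n) 100 * nrow(x$per_read) / n else 0,
              format(x$threshold)))
  top <- sort(x$per_species[x$per_species > 0], decreasing = TRUE)
  top <- utils::head(top, 8)
  for (i in seq_along(top))
    cat(sprintf("  %-30s %6d reads\n", names(top)[i], top[i]))
  invisible(x)
}

#' Cluster unassigned reads into MOTUs
#'
#' De novo greedy clustering of the residual (reference-unmatched) reads;
#' clusters supported by fewer than `min_reads` reads are discarded as
#' probable noise, and the survivors are the molecular operational
#' taxonomic units (MOTUs), ordered by read count (descending; ties by
#' cluster creation order). The MOTU representative is the cluster
#' representative, i.e. its longest member (ties by ascending id).
#'
#' @param reads A [seq_records] object of unassigned reads.
#' @param threshold Identity threshold (default 0.99).
#' @param min_reads Minimum cluster size to survive (default 10).
#' @param params An [identity_params] object.
#' @return A `data.frame` of class `motu_table` with columns `motu`
#'   (1-based rank), `representative` (read id), `read_count`, and
#'   `label` (initially `"unclassified"`; see [classify_motu]). The
#'   representative sequences are attached as attribute `rep_seq`.
#' @export
cluster_residuals <- function(reads, threshold = 0.99, min_reads = 10,
                              params = identity_params()) {
  stopifnot(inherits(reads, "seq_records"))
  if (!length(reads)) {
    out <- data.frame(motu = integer(), representative = character(),
                      read_count = integer(), label = character())
    attr(out, "rep_seq") <- character()
    class(out) <- c("motu_table", "data.frame")
    return(out)
  }
  cs <- greedy_cluster(reads, threshold, params = params, mode = "first_fit")
  sizes <- vapply(cs$clusters, function(cl) nrow(cl$members), integer(1))
  keep <- which(sizes >= min_reads)
  keep <- keep[order(-sizes[keep], keep)]
  reps <- vapply(cs$clusters[keep], function(cl) cl$representative,
                 character(1))
  out <- data.frame(motu = seq_along(keep),
                    representative = reps,
                    read_count = sizes[keep],
                    label = rep("unclassified", length(keep)))
  attr(out, "rep_seq") <- reads$seq[match(reps, reads$id)]
  class(out) <- c("motu_table", "data.frame")
  out
}

#' Classify a MOTU representative against an annotated library
#'
#' Local (Smith-Waterman) alignment of the representative against every
#' sequence of a taxonomy-annotated library. Hits must exceed both a raw
#' alignment score and an identity gate (identity here is matches per
#' alignment column, the local-search convention). The best-scoring
#' surviving hit names the MOTU; when several species tie at the same
#' identity (after rounding, default to 0.1%), the MOTU is named by the
#' deepest taxonomic rank shared by all tied species — e.g. two tied
#' congeners yield `"<Genus> sp."` at genus rank. With no surviving hit
#' the MOTU stays unclassified.
#'
#' @param representative A single sequence (character scalar) or a
#'   [seq_records] object of length 1.
#' @param db A [ref_library] with taxonomy.
#' @param min_score Raw local alignment score gate (default 100,
#'   exclusive).
#' @param min_identity Identity gate (default 0.90, exclusive).
#' @param params An [identity_params] scoring scheme.
#' @param tie_digits Identities are rounded to this many decimals before
#'   tie comparison (default 3, i.e. 0.1%).
#' @return A list of class `taxonomic_hit` with `assigned_name`,
#'   `assigned_rank`, `score`, `identity` and `tied_species`; or the
#'   string `"unclassified"` when no hit passes the gates.
#' @export
classify_motu <- function(representative, db, min_score = 100,
                          min_identity = 0.90, params = identity_params(),
                          tie_digits = 3) {
  s <- if (inherits(representative, "seq_records")) representative$seq[1]
       else canonicalize_seq(representative)
  stopifnot(inherits(db, "ref_library"))
  hits <- lapply(db$records$seq, function(r)
    .sw_stats(s, r, params$match, params$mismatch, params$gap_open,
              params$gap_extend))
  score <- vapply(hits, `[[`, numeric(1), "score")
  ident <- vapply(hits, function(h)
    if (h$columns > 0) h$matches / h$columns else 0, numeric(1))
  ok <- score > min_score & ident > min_identity
  if (!any(ok)) return("unclassified")
  species <- ref_species(db, db$records$id)
  idr <- round(ident, tie_digits)
  best_id <- max(idr[ok])
  tied <- unique(species[ok & idr == best_id])
  if (length(tied) == 1L) {
    return(structure(list(assigned_name = tied, assigned_rank = "species",
                          score = max(score[ok & idr == best_id]),
                          identity = max(ident[ok & idr == best_id]),
                          tied_species = tied),
                     class = "taxonomic_hit"))
  }
  lca <- shared_lineage(db$taxonomy, tied)
  name <- if (is.null(lca)) "unclassified"
          else if (lca$rank == "genus") paste(lca$name, "sp.")
          else lca$name
  structure(list(assigned_name = name,
                 assigned_rank = if (is.null(lca)) NA_character_ else lca$rank,
                 score = max(score[ok & idr == best_id]),
                 identity = max(ident[ok & idr == best_id]),
                 tied_species = tied),
            class = "taxonomic_hit")
}

# deepest rank shared by all species' lineages; NULL when nothing shared
shared_lineage <- function(taxonomy, species) {
  lins <- lapply(species, function(sp) lineage(taxonomy, sp))
  out <- NULL
  for (rank in TAXONOMY_RANKS) {
    vals <- vapply(lins, function(l)
      if (rank %in% names(l)) l[[rank]] else NA_character_, character(1))
    if (anyNA(vals) || length(unique(vals)) != 1L) next
    out <- list(rank = rank, name = vals[1])
  }
  out
}

#' @export
print.taxonomic_hit <- function(x, ...) {
  cat(sprintf("taxonomic_hit: %s (rank %s), score %.0f, identity %.1f%%\n",
              x$assigned_name, x$assigned_rank, x$score, 100 * x$identity))
  if (length(x$tied_species) > 1L)
    cat("  tied species:", paste(x$tied_species, collapse = ", "), "\n")
  invisible(x)
}
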