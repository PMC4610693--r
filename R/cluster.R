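#' Alignment and identity parameters
#'
#' Scoring scheme for the pairwise global alignments that underlie
#' identity clustering. Defaults are the familiar BLASTN-style nucleotide
#' scores: match +2, mismatch -3, gap opening 5, gap extension 2 (a gap of
#' length L costs `gap_open + L * gap_extend`). Identity is the number of
#' identical aligned bases divided by the chosen denominator; the default
#' `shorter_sequence` is the cd-hit convention, `alignment_columns` is
#' offered for sensitivity analysis.
#'
#' @param match Positive match score.
#' @param mismatch Non-negative mismatch penalty.
#' @param gap_open Non-negative gap-opening penalty.
#' @param gap_extend Non-negative per-base gap-extension penalty.
#' @param denominator `"shorter_sequence"` or `"alignment_columns"`.
#' @return An object of class `identity_params`.
#' @export
identity_params <- function(match = 2, mismatch = 3, gap_open = 5,
                            gap_extend = 2,
                            denominator = c("shorter_sequence",
                                            "alignment_columns")) {
  denominator <- match.arg(denominator)
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, denominator = denominator),
            class = "identity_params")
}

denom_code <- function(params) {
  if (params$denominator == "shorter_sequence") 0L else 1L
}

#' Pairwise sequence identity
#'
#' Identity of two sequences under an optimal global (Needleman-Wunsch,
#' affine-gap) alignment: the number of identically aligned A/C/G/T bases
#' divided by the length of the shorter sequence (default) or by the
#' number of alignment columns. Symmetric in its arguments.
#'
#' @param a,b Non-empty sequences (character scalars).
#' @param params An [identity_params] object.
#' @return Identity fraction in `[0, 1]` (can exceed neither bound; a
#'   sequence contained exactly in the other has identity 1 under the
#'   `shorter_sequence` denominator).
#' @examples
#' pairwise_identity("ACGT", "ACGA")            # 0.75
#' pairwise_identity("ACGTACGT", "ACGT")        # 1 (containment)
#' @export
pairwise_identity <- function(a, b, params = identity_params()) {
  a <- canonicalize_seq(a); b <- canonicalize_seq(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a == b) return(1.0)
  st <- .nw_stats(a, b, params$match, params$mismatch, params$gap_open,
                  params$gap_extend)
  den <- if (params$denominator == "shorter_sequence")
    min(nchar(a), nchar(b)) else st$columns
  st$matches / den
}

# identities of one query against many subjects (vectorized in C++)
identity_to_many <- function(query, subjects, params) {
  .identity_vec(query, subjects, params$match, params$mismatch,
                params$gap_open, params$gap_extend, denom_code(params))
}

#' Greedy incremental identity clustering
#'
#' Re-implements the cd-hit clustering semantics: sequences are processed
#' in order of decreasing length (ties broken by ascending id); the first
#' becomes the representative of cluster 0; each subsequent sequence is
#' compared against existing cluster representatives in cluster-creation
#' order and joins one whose identity meets the threshold, otherwise it
#' founds a new cluster with itself as representative. In `first_fit`
#' mode (the cd-hit default, used de novo) the first qualifying
#' representative wins; in `best_fit` mode the representative with the
#' highest identity wins, ties going to the lowest cluster index.
#'
#' @param records A [seq_records] object with unique ids.
#' @param threshold Identity threshold in `(0, 1]`.
#' @param params An [identity_params] object.
#' @param mode `"first_fit"` or `"best_fit"`.
#' @return An object of class `cluster_set`: list with `threshold`,
#'   `params`, and `clusters`, each cluster a list of `index` (0-based
#'   creation order), `representative` (id) and `members` (`data.frame`
#'   of `id`, `length`, `identity` to the representative). The clusters
#'   partition the input ids.
#' @export
greedy_cluster <- function(records, threshold, params = identity_params(),
                           mode = c("first_fit", "best_fit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(records, "seq_records"), length(records) > 0L)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  eps <- 1e-9

  ord <- order(-nchar(records$seq), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- records$seq[ord]

  rep_seq <- character(0)
  assign_to <- integer(length(ids))   # cluster index + 1 per input sequence
  ident <- numeric(length(ids))

  for (i in seq_along(seqs)) {
    s <- seqs[i]
    chosen <- 0L
    chosen_id <- 1.0
    if (length(rep_seq)) {
      if (mode == "first_fit") {
        for (ci in seq_along(rep_seq)) {
          idv <- if (rep_seq[ci] == s) 1.0 else
            identity_to_many(s, rep_seq[ci], params)
          if (idv >= threshold - eps) { chosen <- ci; chosen_id <- idv; break }
        }
      } else {
        bm <- .best_match(s, rep_seq, params$match, params$mismatch,
                          params$gap_open, params$gap_extend,
                          denom_code(params), threshold)
        if (bm$index[1] > 0L) { chosen <- bm$index[1]; chosen_id <- bm$identity[1] }
      }
    }
    if (chosen == 0L) {
      rep_seq <- c(rep_seq, s)
      chosen <- length(rep_seq)
      chosen_id <- 1.0
    }
    assign_to[i] <- chosen
    ident[i] <- chosen_id
  }

  clusters <- vector("list", length(rep_seq))
  for (ci in seq_along(rep_seq)) {
    mem <- which(assign_to == ci)
    rep_i <- mem[match(rep_seq[ci], seqs[mem])]
    # representative listed first, then remaining members in processing order
    mem <- c(rep_i, setdiff(mem, rep_i))
    clusters[[ci]] <- list(index = ci - 1L,
                           representative = ids[rep_i],
                           members = data.frame(id = ids[mem],
                                                length = nchar(seqs[mem]),
                                                identity = ident[mem]))
  }
  structure(list(threshold = threshold, params = params, clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) nrow(cl$members), integer(1))
  cat(sprintf("cluster_set: %d cluster(s) over %d sequence(s) at threshold %s\n",
              length(x$clusters), sum(sizes),
              ifelse(is.na(x$threshold), "NA", format(x$threshold))))
  cat(sprintf("  sizes: %s; singletons: %d\n",
              paste(utils::head(sort(sizes, decreasing = TRUE), 10),
                    collapse = " "),
              sum(sizes == 1L)))
  invisible(x)
}

#' @method summary cluster_set
#' @export
summary.cluster_set <- function(object, ...) {
  sizes <- vapply(object$clusters, function(cl) nrow(cl$members), integer(1))
  out <- list(n_clusters = length(sizes), n_sequences = sum(sizes),
              n_singletons = sum(sizes == 1L), threshold = object$threshold,
              size_table = table(sizes))
  class(out) <- "summary.cluster_set"
  out
}

#' @export
print.summary.cluster_set <- function(x, ...) {
  cat(sprintf("%d sequences in %d clusters (%d singletons) at threshold %s\n",
              x$n_sequences, x$n_clusters, x$n_singletons,
              format(x$threshold)))
  print(x$size_table)
  invisible(x)
}

#' Reference-guided clustering of query sequences
#'
#' Assigns each query to the reference species with the highest identity,
#' provided that identity meets the threshold (cd-hit-est-2d semantics
#' with best-hit attribution); queries reaching no reference are returned
#' unmatched. Matched and unmatched together cover every query exactly
#' once.
#'
#' @param queries A [seq_records] object.
#' @param reference A [ref_library].
#' @param threshold Identity threshold in `(0, 1]` (default 0.99).
#' @param params An [identity_params] object.
#' @return List with `matched` (`data.frame` of `id`, `species`,
#'   `identity`) and `unmatched` (character vector of query ids).
#' @export
cluster_against_reference <- function(queries, reference, threshold = 0.99,
                                      params = identity_params()) {
  stopifnot(inherits(queries, "seq_records"), inherits(reference, "ref_library"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (length(reference$records) == 0L) stop("empty reference library")
  bm <- .best_match(queries$seq, reference$records$seq, params$match,
                    params$mismatch, params$gap_open, params$gap_extend,
                    denom_code(params), threshold)
  hit <- bm$index > 0L
  matched <- data.frame(
    id = queries$id[hit],
    species = ref_species(reference, reference$records$id[bm$index[hit]]),
    identity = bm$identity[hit])
  list(matched = matched, unmatched = queries$id[!hit])
}
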