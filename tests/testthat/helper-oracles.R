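# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# identity via Biostrings' aligner: count identical aligned bases from the
# aligned strings of an optimal global alignment under the same scoring
oracle_identity <- function(a, b, params = identity_params()) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                mismatch = -params$mismatch,
                                                baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = m,
                                       gapOpening = params$gap_open,
                                       gapExtension = params$gap_extend,
                                       type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == sa & pa != "-")
  den <- if (params$denominator == "shorter_sequence")
    min(nchar(a), nchar(b)) else length(pa)
  matches / den
}

# quadratic re-implementation of greedy incremental clustering, coded
# directly from the clustering rule with the oracle aligner
naive_cluster <- function(records, threshold, params = identity_params(),
                          mode = "first_fit") {
  ord <- order(-nchar(records$seq), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  reps <- integer(0)            # indices into seqs
  membership <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    joined <- 0L
    if (length(reps)) {
      idv <- vapply(reps, function(r)
        if (seqs[r] == seqs[i]) 1.0 else
          oracle_identity(seqs[i], seqs[r], params), numeric(1))
      if (mode == "first_fit") {
        hit <- which(idv >= threshold - 1e-9)
        if (length(hit)) joined <- hit[1]
      } else {
        if (max(idv) >= threshold - 1e-9) joined <- which.max(idv)
      }
    }
    if (joined == 0L) {
      reps <- c(reps, i)
      joined <- length(reps)
    }
    membership[i] <- joined
  }
  # return the partition as a list of member id sets, in creation order
  lapply(seq_along(reps), function(ci) sort(ids[membership == ci]))
}

cluster_set_partition <- function(cs) {
  lapply(cs$clusters, function(cl) sort(cl$members$id))
}

# explicit mid-rank Spearman rho
midrank_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# substitute nsub random positions (no indels: keeps optimal alignments
# unambiguous for oracle comparisons)
mutate_subs <- function(seq, nsub) {
  chars <- strsplit(seq, "", TRUE)[[1]]
  pos <- sample(length(chars), min(nsub, length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# a library of `n_fam` sequence families: near-duplicates within families,
# unrelated across; returns seq_records
family_library <- function(n_fam = 3, fam_size = 3, len = 60, max_sub = 4) {
  seqs <- character(0)
  for (f in seq_len(n_fam)) {
    root <- rand_seq(len)
    seqs <- c(seqs, root,
              replicate(fam_size - 1, mutate_subs(root, sample(max_sub, 1))))
  }
  seq_records(sprintf("q%02d", seq_along(seqs)), seqs)
}

# a sequence in which EVERY homopolymer run has length >= 4, so that a
# +/-1 run-length miscall is erased by capping at 3
all_long_run_seq <- function(n_blocks = 15, lens = 4:6) {
  bases <- character(n_blocks)
  bases[1] <- sample(c("A", "C", "G", "T"), 1)
  for (i in seq_len(n_blocks - 1) + 1)
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i - 1]), 1)
  paste(unlist(Map(function(b, l) strrep(b, l), bases,
                   sample(lens, n_blocks, TRUE))), collapse = "")
}

# tiny annotated reference library built by hand for classification tests
toy_db <- function(seqs, genera, species = NULL) {
  n <- length(seqs)
  if (is.null(species)) species <- paste0(genera, " sp", seq_len(n))
  tax <- data.frame(ref_id = sprintf("DB%02d", seq_len(n)),
                    phylum = "Arthropoda", subphylum = "Crustacea",
                    class = "Copepoda", order = "Calanoida",
                    family = "Calanidae", genus = genera, species = species)
  ref_library(seq_records(tax$ref_id, seqs, desc = species), tax)
}
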