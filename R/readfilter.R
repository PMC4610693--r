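#' Read filtering parameters
#'
#' Bundles the three-rule read rejection settings: minimum mean Phred
#' quality, maximum primer mismatches, and minimum post-trim length. The
#' defaults are the standard 454 amplicon settings (mean Phred >= 10, at
#' most two primer mismatches, at least 200 bp after trimming).
#'
#' @param forward_primer Forward primer sequence expected at the start of
#'   every read (after adaptor removal).
#' @param reverse_primer Optional reverse primer; when given, its reverse
#'   complement is searched at the 3' end and trimmed if found within
#'   `max_primer_mismatches`.
#' @param min_mean_quality Minimum mean Phred score (default 10). Set to
#'   `NA` to disable the quality rule (e.g. for FASTA input).
#' @param max_primer_mismatches Maximum Hamming mismatches allowed in the
#'   primer (default 2).
#' @param min_length Minimum length in bp of the trimmed read (default 200).
#' @param adaptor Optional fixed adaptor string clipped from the 5' end
#'   (exact match) before primer matching, for providers that do not
#'   pre-clip adaptors.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(forward_primer, reverse_primer = NULL,
                          min_mean_quality = 10, max_primer_mismatches = 2,
                          min_length = 200, adaptor = NULL) {
  stopifnot(min_length > 0, max_primer_mismatches >= 0)
  forward_primer <- canonicalize_seq(forward_primer)
  if (!is.null(reverse_primer)) reverse_primer <- canonicalize_seq(reverse_primer)
  structure(list(forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 min_mean_quality = min_mean_quality,
                 max_primer_mismatches = as.integer(max_primer_mismatches),
                 min_length = as.integer(min_length),
                 adaptor = adaptor),
            class = "filter_params")
}

#' Mean Phred quality of a read
#'
#' @param quality Non-empty integer vector of Phred scores.
#' @return Arithmetic mean of the scores.
#' @export
mean_quality <- function(quality) {
  if (!length(quality)) stop("empty quality vector")
  mean(quality)
}

#' Match a primer against the start of a read
#'
#' Hamming comparison of the primer against the read prefix, anchored at
#' position 0 (454 amplicons begin with the sequencing primer once the
#' adaptor is clipped). An `N` in the read counts as a mismatch.
#'
#' @param read A [seq_records] object of length 1 or a character scalar.
#' @param primer Primer sequence.
#' @param max_mm Maximum number of mismatches for a hit.
#' @return A list with `found` (logical), `mismatches` (count) and `end`
#'   (0-based exclusive offset of the primer in the read, i.e. the primer
#'   length). A primer longer than the read gives `found = FALSE` with
#'   `mismatches = NA`.
#' @export
match_primer <- function(read, primer, max_mm) {
  s <- if (inherits(read, "seq_records")) read$seq[1] else as.character(read)
  primer <- canonicalize_seq(primer)
  np <- nchar(primer)
  if (np > nchar(s))
    return(list(found = FALSE, mismatches = NA_integer_, end = np))
  pre <- strsplit(substr(s, 1, np), "", TRUE)[[1]]
  pc <- strsplit(primer, "", TRUE)[[1]]
  mm <- sum(pre != pc | pre == "N")
  list(found = mm <= max_mm, mismatches = as.integer(mm), end = np)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(seq, "", TRUE),
                function(ch) paste(rev(ch), collapse = ""), character(1)))
}

#' Filter and trim amplicon reads
#'
#' Applies the three rejection rules in order: (1) mean Phred quality
#' below `min_mean_quality`; (2) more than `max_primer_mismatches`
#' mismatches to the forward primer at the read start; (3) trimmed length
#' below `min_length`. Kept reads have the forward primer removed and,
#' when a reverse primer is configured and its reverse complement is
#' found at the 3' end within the mismatch budget, that tail removed too.
#' The length rule is evaluated on the trimmed sequence.
#'
#' @param reads A [seq_records] object. Qualities are required unless the
#'   quality rule is disabled (`min_mean_quality = NA`).
#' @param params A [filter_params] object.
#' @return An object of class `filter_report`: list with `kept` (trimmed
#'   [seq_records]) and `rejected` (`data.frame` of `id`, `reason` with
#'   reasons `low_quality`, `primer_mismatch`, `too_short`). Every input
#'   read appears in exactly one of the two.
#' @export
filter_reads <- function(reads, params) {
  stopifnot(inherits(reads, "seq_records"), inherits(params, "filter_params"))
  use_q <- !is.na(params$min_mean_quality)
  if (use_q && is.null(reads$qual))
    stop("reads carry no qualities but the mean-quality rule is enabled; ",
         "set min_mean_quality = NA to disable it")
  n <- length(reads)
  reason <- rep(NA_character_, n)
  keep_seq <- character(n)
  keep_qual <- if (!is.null(reads$qual)) vector("list", n)
  rc_rev <- if (!is.null(params$reverse_primer)) revcomp(params$reverse_primer)

  for (i in seq_len(n)) {
    s <- reads$seq[i]
    q <- if (!is.null(reads$qual)) reads$qual[[i]]
    if (!is.null(params$adaptor) && nzchar(params$adaptor) &&
        startsWith(s, params$adaptor)) {
      nc <- nchar(params$adaptor)
      s <- substring(s, nc + 1L)
      if (!is.null(q)) q <- q[-seq_len(nc)]
    }
    if (use_q && mean_quality(q) < params$min_mean_quality) {
      reason[i] <- "low_quality"
      next
    }
    pm <- match_primer(s, params$forward_primer,
                       params$max_primer_mismatches)
    if (is.na(pm$mismatches)) {  # primer longer than read
      reason[i] <- "too_short"
      next
    }
    if (!pm$found) {
      reason[i] <- "primer_mismatch"
      next
    }
    if (pm$end > 0L) {
      s <- substring(s, pm$end + 1L)
      if (!is.null(q)) q <- q[-seq_len(pm$end)]
    }
    if (!is.null(rc_rev) && nchar(s) >= nchar(rc_rev)) {
      tail_s <- substring(s, nchar(s) - nchar(rc_rev) + 1L)
      tm <- match_primer(tail_s, rc_rev, params$max_primer_mismatches)
      if (tm$found) {
        s <- substr(s, 1L, nchar(s) - nchar(rc_rev))
        if (!is.null(q)) q <- q[seq_len(nchar(s))]
      }
    }
    if (nchar(s) < params$min_length) {
      reason[i] <- "too_short"
      next
    }
    keep_seq[i] <- s
    if (!is.null(q)) keep_qual[[i]] <- q
  }

  kept_i <- which(is.na(reason))
  kept <- seq_records(reads$id[kept_i], keep_seq[kept_i],
                      desc = reads$desc[kept_i],
                      qual = if (!is.null(reads$qual)) keep_qual[kept_i])
  rejected <- data.frame(id = reads$id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  structure(list(kept = kept, rejected = rejected, params = params),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d kept, %d rejected\n",
              length(x$kept), nrow(x$rejected)))
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}
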