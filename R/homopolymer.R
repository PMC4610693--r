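#' Homopolymer run detection
#'
#' Decomposes a sequence into its maximal runs of identical bases. The
#' runs tile the sequence exactly, in left-to-right order.
#'
#' @param seq A single sequence (character scalar).
#' @return A `data.frame` with columns `base`, `start` (0-based) and
#'   `length`.
#' @examples
#' find_runs("AAACCG")  # runs (A,0,3), (C,3,2), (G,5,1)
#' @export
find_runs <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  data.frame(base = r$values,
             start = cumsum(c(0L, r$lengths[-length(r$lengths)])),
             length = r$lengths)
}

#' Longest homopolymer run in a sequence set
#'
#' @param x A [seq_records] object or character vector of sequences.
#' @return The maximum run length over all sequences.
#' @examples
#' max_run_length(c("AATT", "CCC"))  # 3
#' @export
max_run_length <- function(x) {
  seqs <- if (inherits(x, "seq_records")) x$seq else as.character(x)
  stopifnot(length(seqs) > 0L)
  max(vapply(seqs, function(s) max(rle(strsplit(s, "", TRUE)[[1]])$lengths),
             integer(1)))
}

#' Cap homopolymer runs at a maximum length
#'
#' Replaces every homopolymer run longer than `k` by exactly `k` copies of
#' its base, leaving everything else untouched. This is the pyrosequencing
#' denoising device that makes reads with run-length miscalls commensurate
#' with a reference library capped the same way. Capping is idempotent and
#' commutes with reverse complementation.
#'
#' When applied to a [seq_records] object with qualities, the quality
#' values of the removed positions (the tail of each over-long run) are
#' dropped so that quality length continues to match sequence length.
#'
#' @param x A character vector of sequences or a [seq_records] object.
#' @param k Maximum run length to retain (`k >= 1`).
#' @return Object of the same type as `x`, with no run longer than `k`.
#' @examples
#' cap_runs("AAACCCCGG", 3)  # "AAACCCGG"
#' @export
cap_runs <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("'k' must be a single count >= 1")
  k <- as.integer(k)
  if (inherits(x, "seq_records")) {
    if (is.null(x$qual)) {
      x$seq <- cap_runs_chr(x$seq, k)
      attr(x, "cap") <- k
      return(x)
    }
    for (i in seq_along(x$seq)) {
      r <- rle(strsplit(x$seq[i], "", TRUE)[[1]])
      keep_lens <- pmin(r$lengths, k)
      # retain the first keep_lens[j] positions of each run
      offs <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
      keep_idx <- unlist(Map(function(o, l) o + seq_len(l), offs, keep_lens))
      chars <- strsplit(x$seq[i], "", TRUE)[[1]]
      x$seq[i] <- paste(chars[keep_idx], collapse = "")
      x$qual[[i]] <- x$qual[[i]][keep_idx]
    }
    attr(x, "cap") <- k
    return(x)
  }
  cap_runs_chr(as.character(x), k)
}

cap_runs_chr <- function(seqs, k) {
  pat <- sprintf("(.)\\1{%d,}", k)
  rep <- paste0(rep("\\1", k), collapse = "")
  gsub(pat, rep, seqs, perl = TRUE)
}

#' Stepwise homopolymer reduction of a sequence library
#'
#' Shortens every homopolymer run of length `n` or more by one base, i.e.
#' caps runs at `n - 1`. Chaining the reduction from the library's longest
#' run length down to `k + 1` telescopes to [cap_runs] at `k`; applied
#' repeatedly it yields the family of run-capped reference libraries
#' ("5-mer", "4-mer", "3-mer", "2-mer") used to study the effect of run
#' length on species resolution.
#'
#' @param records A [seq_records] object.
#' @param n Run length to reduce (`n >= 2`); runs of length `>= n` become
#'   `n - 1`.
#' @return A new [seq_records] object; a `cap` attribute records `n - 1`.
#' @examples
#' stepwise_reduce(seq_records("s", "GGGGGG"), 6)$seq  # "GGGGG"
#' @export
stepwise_reduce <- function(records, n) {
  stopifnot(inherits(records, "seq_records"))
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be a single count >= 2")
  out <- cap_runs(records, as.integer(n) - 1L)
  attr(out, "cap") <- as.integer(n) - 1L
  out
}
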