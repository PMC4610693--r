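#' Sequence record sets
#'
#' `seq_records()` builds the package's basic sequence container: a set of
#' uniquely identified DNA sequences over the alphabet \{A, C, G, T, N\},
#' optionally carrying per-base Phred quality scores. All pipeline stages
#' consume and produce this container.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of residues (same length as `id`). Sequences
#'   are canonicalized: uppercased, `U` mapped to `T`, any other character
#'   mapped to `N`.
#' @param desc Optional character vector of free-text descriptions.
#' @param qual Optional list of integer vectors of Phred scores (0--60),
#'   one per sequence, each the same length as its sequence.
#'
#' @return An object of class `seq_records`: a list with elements `id`,
#'   `desc`, `seq` and `qual` (`NULL` when no qualities are attached).
#' @examples
#' x <- seq_records(c("s1", "s2"), c("acgu", "TTNT"))
#' x$seq  # "ACGT" "TTNT"
#' @export
seq_records <- function(id, seq, desc = NULL, qual = NULL) {
  id <- as.character(id)
  seq <- canonicalize_seq(as.character(seq))
  if (length(id) != length(seq))
    stop("'id' and 'seq' must have the same length")
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq)))
    stop("empty sequences are not allowed (ids: ",
         paste(id[!nzchar(seq)], collapse = ", "), ")")
  if (is.null(desc)) desc <- rep("", length(id))
  if (!is.null(qual)) {
    stopifnot(length(qual) == length(seq))
    qual <- lapply(qual, as.integer)
    bad <- which(lengths(qual) != nchar(seq))
    if (length(bad))
      stop("quality length differs from sequence length for record(s): ",
           paste(id[bad], collapse = ", "))
    rng <- range(unlist(qual, use.names = FALSE), 0L)
    if (rng[1] < 0L || rng[2] > 93L)
      stop("Phred scores must lie in [0, 93]")
  }
  structure(list(id = id, desc = as.character(desc), seq = seq, qual = qual),
            class = "seq_records")
}

canonicalize_seq <- function(seq) {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  gsub("[^ACGT]", "N", seq)
}

#' @export
length.seq_records <- function(x) length(x$id)

#' @export
`[.seq_records` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(id = x$id[i], desc = x$desc[i], seq = x$seq[i],
                 qual = if (!is.null(x$qual)) x$qual[i]),
            class = "seq_records")
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("seq_records: %d sequence(s), widths %s%s\n", length(x),
              if (length(x)) paste(range(nchar(x$seq)), collapse = "-") else "-",
              if (is.null(x$qual)) "" else ", with qualities"))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- x$seq[i]
    cat(sprintf("  %s  %s%s\n", x$id[i],
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Read and write FASTA files
#'
#' `read_fasta()` parses a (possibly multi-line) FASTA file into a
#' [seq_records] set; the record id is the first whitespace-delimited token
#' of the header and the remainder becomes the description. `write_fasta()`
#' is its inverse; the round trip preserves ids and residues exactly.
#'
#' @param path File path.
#' @param x A [seq_records] object.
#' @param width Line width used when writing.
#' @return `read_fasta()` returns a [seq_records] object (empty for an
#'   empty file); `write_fasta()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(seq_records("s1", "ACGT", desc = "toy"), f)
#' read_fasta(f)$seq
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (!length(content)) return(seq_records(character(), character()))
  first <- content[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " does not start with '>'")
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(x), desc = desc)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "seq_records"))
  s <- Biostrings::BStringSet(x$seq)
  names(s) <- ifelse(nzchar(x$desc), paste(x$id, x$desc), x$id)
  Biostrings::writeXStringSet(s, path, width = width)
  invisible(path)
}

#' Read and write FASTQ files (Sanger Phred+33)
#'
#' Strict four-line-record FASTQ with Phred+33 quality encoding, the
#' dialect in which the SRA distributes 454 runs. Records whose quality
#' string length differs from the sequence length are rejected with an
#' error naming the record.
#'
#' @param path File path.
#' @param x A [seq_records] object with qualities.
#' @return `read_fastq()` returns a [seq_records] object with integer
#'   Phred qualities; `write_fastq()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' read_fastq(f)$qual[[1]]  # 40 40 40 40
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(seq_records(character(), character(), qual = list()))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4")
  head_l <- lines[seq(1, length(lines), by = 4)]
  seq_l <- lines[seq(2, length(lines), by = 4)]
  plus_l <- lines[seq(3, length(lines), by = 4)]
  qual_l <- lines[seq(4, length(lines), by = 4)]
  if (any(!startsWith(head_l, "@")))
    stop("malformed FASTQ: header line missing '@' at record ",
         which(!startsWith(head_l, "@"))[1])
  if (any(!startsWith(plus_l, "+")))
    stop("malformed FASTQ: separator line missing '+' at record ",
         which(!startsWith(plus_l, "+"))[1])
  headers <- substring(head_l, 2)
  id <- sub("\\s.*$", "", headers)
  bad <- which(nchar(seq_l) != nchar(qual_l))
  if (length(bad))
    stop("sequence/quality length mismatch for record(s): ",
         paste(id[bad], collapse = ", "))
  qual <- lapply(qual_l, function(q) utf8ToInt(q) - 33L)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id, seq_l, desc = desc, qual = qual)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "seq_records"))
  if (is.null(x$qual)) stop("records carry no qualities")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$id)) {
    header <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(c(paste0("@", header), x$seq[i], "+",
                 intToUtf8(x$qual[[i]] + 33L)), con)
  }
  invisible(path)
}

# Fixed rank order of the taxonomy table, most to least inclusive.
TAXONOMY_RANKS <- c("phylum", "subphylum", "class", "order", "family",
                    "genus", "species")

#' Read and write the taxonomy table
#'
#' The reference taxonomy is a flat tab-separated table with columns
#' `ref_id`, `phylum`, `subphylum`, `class`, `order`, `family`, `genus`,
#' `species`; `-` marks an absent rank (some phyla have no subphylum).
#' Each species appears exactly once and maps to exactly one reference
#' sequence id.
#'
#' @param path File path.
#' @param taxonomy A taxonomy `data.frame` as returned by `read_taxonomy()`.
#' @return `read_taxonomy()` returns a `data.frame` with the eight columns
#'   above, absent ranks as `NA`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  need <- c("ref_id", TAXONOMY_RANKS)
  if (!all(need %in% names(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df[df == "-"] <- NA_character_
  validate_taxonomy(df)
  df
}

validate_taxonomy <- function(df) {
  if (anyDuplicated(df$species))
    stop("duplicate species in taxonomy: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  if (anyDuplicated(df$ref_id))
    stop("ref_id not unique in taxonomy: ",
         paste(unique(df$ref_id[duplicated(df$ref_id)]), collapse = ", "))
  if (any(is.na(df$species)))
    stop("species rank may not be absent")
  invisible(df)
}

#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(taxonomy, path) {
  out <- taxonomy[, c("ref_id", TAXONOMY_RANKS)]
  out[is.na(out)] <- "-"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Taxonomic lineage of a species
#'
#' Returns the ordered `(rank, name)` lineage of a species from a taxonomy
#' table, skipping absent ranks.
#'
#' @param taxonomy Taxonomy `data.frame` (see [read_taxonomy]).
#' @param species Species name.
#' @return Named character vector: names are ranks (most inclusive first),
#'   values are taxon names.
#' @export
lineage <- function(taxonomy, species) {
  row <- taxonomy[taxonomy$species == species, , drop = FALSE]
  if (nrow(row) != 1L) stop("species not in taxonomy: ", species)
  v <- unlist(row[1, TAXONOMY_RANKS])
  v[!is.na(v)]
}

#' Reference library
#'
#' Couples species-labelled reference sequences (one sequence per species,
#' the Sanger-library design) with their ranked taxonomy.
#'
#' @param records A [seq_records] set of reference sequences.
#' @param taxonomy Taxonomy `data.frame` whose `ref_id` column matches the
#'   record ids one-to-one.
#' @return An object of class `ref_library` with elements `records` and
#'   `taxonomy`.
#' @export
ref_library <- function(records, taxonomy) {
  stopifnot(inherits(records, "seq_records"))
  validate_taxonomy(taxonomy)
  if (!setequal(records$id, taxonomy$ref_id) ||
      length(records) != nrow(taxonomy))
    stop("record ids and taxonomy ref_ids must match one-to-one")
  structure(list(records = records, taxonomy = taxonomy),
            class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat(sprintf("ref_library: %d species, sequence widths %s\n",
              length(x$records),
              paste(range(nchar(x$records$seq)), collapse = "-")))
  phyla <- unique(x$taxonomy$phylum)
  cat("  phyla:", paste(phyla[!is.na(phyla)], collapse = ", "), "\n")
  invisible(x)
}

# species label for a reference record id
ref_species <- function(library, ids) {
  library$taxonomy$species[match(ids, library$taxonomy$ref_id)]
}

#' Write and read cluster sets in `.clstr`-style text
#'
#' Serializes a [greedy_cluster] result as text blocks in the style of
#' cd-hit's `.clstr` reports: a `>Cluster n` line (numbered from 0 in
#' creation order) followed by one line per member giving its length, id
#' and identity to the cluster representative; the representative line
#' ends in `*`. Identities are printed with enough digits that
#' `read_clusters(write_clusters(x))` reproduces ids and identities.
#'
#' @param clusters A `cluster_set` (see [greedy_cluster]).
#' @param path File path.
#' @return `write_clusters()` returns `path` invisibly; `read_clusters()`
#'   returns a `cluster_set` (threshold and scoring parameters are not
#'   stored in the text format and come back as `NA`).
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in clusters$clusters) {
    writeLines(sprintf(">Cluster %d", cl$index), con)
    m <- cl$members
    for (i in seq_len(nrow(m))) {
      if (m$id[i] == cl$representative) {
        writeLines(sprintf("%d\t%dnt, >%s... *", i - 1L, m$length[i], m$id[i]),
                   con)
      } else {
        writeLines(sprintf("%d\t%dnt, >%s... at %.10f%%", i - 1L, m$length[i],
                           m$id[i], 100 * m$identity[i]), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>Cluster ", lines)
  if (!length(starts) && length(lines))
    stop("malformed cluster file: no '>Cluster' blocks")
  ends <- c(starts[-1] - 1L, length(lines))
  clusters <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- as.integer(sub("^>Cluster ", "", lines[starts[k]]))
    body <- lines[seq(starts[k] + 1L, ends[k])]
    len <- as.integer(sub("^\\d+\t(\\d+)nt.*$", "\\1", body))
    id <- sub("^.*>([^.]*)\\.\\.\\..*$", "\\1", body)
    is_rep <- grepl("\\*\\s*$", body)
    ident <- rep(NA_real_, length(body))
    ident[is_rep] <- 1.0
    ident[!is_rep] <-
      as.numeric(sub("^.* at ([0-9.]+)%$", "\\1", body[!is_rep])) / 100
    clusters[[k]] <- list(index = idx, representative = id[is_rep][1],
                          members = data.frame(id = id, length = len,
                                               identity = ident))
  }
  structure(list(threshold = NA_real_, params = NULL, clusters = clusters),
            class = "cluster_set")
}
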