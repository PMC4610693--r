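test_that("FASTA parsing canonicalizes, folds lines, and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 desc", "acgt"), f)
  x <- read_fasta(f)
  expect_equal(x$id, "s1")
  expect_equal(x$seq, "ACGT")
  expect_equal(x$desc, "desc")

  writeLines(c(">a", "AC", "GT", ">b", "TTTT"), f)
  x <- read_fasta(f)
  expect_equal(x$seq, c("ACGT", "TTTT"))

  # U -> T, other characters -> N
  writeLines(c(">u", "acgu", ">w", "AxG-T"), f)
  x <- read_fasta(f)
  expect_equal(x$seq, c("ACGT", "ANGNT"))

  # round trip on a random record set
  set.seed(11)
  y <- seq_records(paste0("r", 1:5),
                   replicate(5, rand_seq(sample(40:90, 1))),
                   desc = c("", "two words", "", "x", ""))
  write_fasta(y, f)
  z <- read_fasta(f)
  expect_equal(z$id, y$id)
  expect_equal(z$seq, y$seq)
})

test_that("FASTA errors: empty file and malformed header", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_length(read_fasta(f), 0L)
  writeLines(c("ACGT", ">s1", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("FASTQ decodes Phred+33 and enforces length agreement", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  expect_equal(read_fastq(f)$qual[[1]], c(40L, 40L, 40L, 40L))
  writeLines(c("@r1", "ACGT", "+", "!!!!"), f)
  expect_equal(read_fastq(f)$qual[[1]], c(0L, 0L, 0L, 0L))
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "r1")

  # round trip including qualities
  set.seed(12)
  y <- seq_records(c("a", "b"), c(rand_seq(30), rand_seq(45)),
                   qual = list(sample(0:40, 30, TRUE), sample(0:40, 45, TRUE)))
  write_fastq(y, f)
  z <- read_fastq(f)
  expect_equal(z$seq, y$seq)
  expect_equal(z$qual, y$qual)
})

test_that("taxonomy table parses sparse ranks and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("ref_id", "phylum", "subphylum", "class", "order",
                 "family", "genus", "species"), collapse = "\t")
  writeLines(c(hdr,
    "MT0564\tArthropoda\tCrustacea\tCopepoda\tCalanoida\tCalanidae\tCalanus\tCalanus helgolandicus",
    "PH001\tPhoronida\t-\tPhoronida cl\tPhoronida or\tPhoronidae\tPhoronis\tPhoronis sp1"), f)
  tx <- read_taxonomy(f)
  lin <- lineage(tx, "Calanus helgolandicus")
  expect_equal(unname(lin[c("genus", "species")]),
               c("Calanus", "Calanus helgolandicus"))
  # absent subphylum skipped from the lineage
  expect_false("subphylum" %in% names(lineage(tx, "Phoronis sp1")))

  writeLines(c(hdr,
    "A1\tX\t-\tX\tX\tX\tX\tSame species",
    "A2\tX\t-\tX\tX\tX\tX\tSame species"), f)
  expect_error(read_taxonomy(f), "duplicate species")
  writeLines(c(hdr,
    "A1\tX\t-\tX\tX\tX\tX\tSp one",
    "A1\tX\t-\tX\tX\tX\tX\tSp two"), f)
  expect_error(read_taxonomy(f), "ref_id")

  # write/read round trip is the identity
  writeLines(c(hdr,
    "MT0564\tArthropoda\tCrustacea\tCopepoda\tCalanoida\tCalanidae\tCalanus\tCalanus helgolandicus",
    "PH001\tPhoronida\t-\tPhoronida cl\tPhoronida or\tPhoronidae\tPhoronis\tPhoronis sp1"), f)
  tx <- read_taxonomy(f)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tx, f2)
  expect_equal(read_taxonomy(f2), tx, ignore_attr = TRUE)
})

test_that("cluster text blocks number from 0 and round-trip", {
  x <- seq_records(c("s1", "s2", "s3"),
                   c("ACGTACGTAC", "ACGTACGTAC", "TTTTTTCCCC"))
  cs <- greedy_cluster(x, 0.99)
  f <- withr::local_tempfile(fileext = ".clstr")
  write_clusters(cs, f)
  lines <- readLines(f)
  expect_equal(lines[1], ">Cluster 0")
  expect_true(">Cluster 1" %in% lines)
  expect_true(any(grepl("\\*$", lines)))  # representative marker

  back <- read_clusters(f)
  expect_equal(cluster_set_partition(back), cluster_set_partition(cs))
  for (k in seq_along(cs$clusters)) {
    expect_equal(back$clusters[[k]]$members$identity,
                 cs$clusters[[k]]$members$identity, tolerance = 1e-9)
    expect_equal(back$clusters[[k]]$representative,
                 cs$clusters[[k]]$representative)
  }

  # single singleton cluster: one block whose member line is starred
  one <- greedy_cluster(seq_records("only", "ACGTT"), 0.95)
  write_clusters(one, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  expect_match(lines[2], "\\*$")
})

test_that("seq_records enforces its invariants", {
  expect_error(seq_records(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(seq_records("a", ""), "empty")
  expect_error(seq_records("a", "ACGT", qual = list(1:3)), "quality length")
  x <- seq_records(c("a", "b"), c("ACGT", "GGCC"))
  expect_equal(x["b"]$seq, "GGCC")
})
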