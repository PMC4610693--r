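test_that("hp accuracy interpolates between the two anchors", {
  m <- error_model()
  expect_equal(hp_accuracy(3, m), 0.99)
  expect_equal(hp_accuracy(9, m), 0.64)
  mid <- hp_accuracy(6, m)
  expect_gt(mid, 0.64)
  expect_lt(mid, 0.99)
  # short runs inherit the smallest anchor's accuracy
  expect_equal(hp_accuracy(1, m), 0.99)
  expect_equal(hp_accuracy(2, m), 0.99)
  # accuracy is non-increasing in run length
  acc <- hp_accuracy(1:12, m)
  expect_true(all(diff(acc) <= 1e-12))
  expect_error(error_model(hp_anchors = numeric()), "anchor")
  expect_error(error_model(hp_anchors = c("3" = 0.5, "9" = 0.9)),
               "non-increasing")
})

test_that("simulated reference hits the identity window and is reproducible", {
  cfg <- sim_config(n_species = 10, seq_length = 220, n_reads = 10, seed = 81)
  set.seed(81)
  lib <- simulate_reference(cfg, seed = NULL)
  ids <- motu454:::all_pairwise_identity(lib$records$seq)
  expect_true(all(ids >= cfg$identity_range[1] - 0.01))
  expect_true(all(ids <= cfg$identity_range[2] + 0.01))
  # homopolymer seeding reaches the configured maximum
  expect_gte(max_run_length(lib$records), 4L)
  # determinism
  lib2 <- simulate_reference(cfg, seed = 81)
  set.seed(81); lib3 <- simulate_reference(cfg, seed = NULL)
  expect_identical(lib2$records$seq, lib3$records$seq)
  # taxonomy is internally consistent and has congeneric pairs sometimes;
  # at minimum every species label is unique and matches its genus prefix
  expect_false(anyDuplicated(lib$taxonomy$species) > 0)
  expect_true(all(startsWith(lib$taxonomy$species, lib$taxonomy$genus)))
})

test_that("an infeasible identity window fails with the achieved range", {
  # random-sequence alignments floor well above 30% identity under this
  # scoring, so the window below is unreachable
  cfg <- sim_config(n_species = 6, seq_length = 150, n_reads = 10,
                    identity_range = c(0.30, 0.32), seed = 82)
  set.seed(82)
  expect_error(simulate_reference(cfg, seed = NULL, max_attempts = 2),
               "achieved")
})

test_that("run-length miscall frequency tracks the error model", {
  m <- error_model()
  set.seed(83)
  for (k in c(3, 7)) {
    n <- 3000
    run <- paste(rep("A", k), collapse = "")
    hits <- vapply(seq_len(n), function(i)
      nrow(apply_hp_errors(run, m)$events) > 0, logical(1))
    p_exp <- 1 - hp_accuracy(k, m)
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(mean(hits) - p_exp), 3 * se + 1e-12)
  }
  # miscalls change run length by exactly one
  set.seed(84)
  out <- replicate(500, nchar(apply_hp_errors("AAAAAAA", m)$seq))
  expect_true(all(out %in% c(6L, 7L, 8L)))
})

test_that("zero-error reads equal their sources; chimeras record two parents", {
  cfg <- sim_config(n_species = 6, seq_length = 180, n_reads = 50,
                    forward_primer = "", seed = 85)
  set.seed(85)
  lib <- simulate_reference(cfg, seed = NULL)
  m0 <- error_model(hp_anchors = c("3" = 1), substitution_rate = 0,
                    chimera_rate = 0)
  rr <- simulate_reads(lib, cfg, m0)
  src <- setNames(lib$records$seq, lib$taxonomy$species)
  expect_identical(rr$reads$seq, unname(src[rr$truth$species]))
  expect_true(all(is.na(rr$truth$chimera_parent)))
  expect_equal(lengths(rr$reads$qual), nchar(rr$reads$seq))

  mch <- error_model(hp_anchors = c("3" = 1), substitution_rate = 0,
                     chimera_rate = 1)
  rr2 <- simulate_reads(lib, cfg, mch)
  expect_true(all(!is.na(rr2$truth$chimera_parent)))
  expect_true(all(rr2$truth$chimera_parent != rr2$truth$species))
})

test_that("capping erases pure run-length errors when all runs clear the cap", {
  # a library whose every homopolymer run has length >= 4: after capping
  # at 3, a +/-1 run-length miscall lands on the same capped sequence
  set.seed(86)
  s <- all_long_run_seq(n_blocks = 15)
  m_hp <- error_model(substitution_rate = 0, chimera_rate = 0)
  agree <- vapply(1:100, function(i) {
    read <- apply_hp_errors(s, m_hp)$seq
    cap_runs(read, 3) == cap_runs(s, 3)
  }, logical(1))
  # only runs of length >= 4 exist... those that stay >= 3 after an
  # under-call cap to the same 3-mer; over-calls likewise
  expect_true(all(agree))
})

test_that("simulate_study writes a complete, reproducible fixture set", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- sim_config(n_species = 6, seq_length = 150, n_reads = 40,
                    n_aliquots = 2, seed = 87)
  st1 <- simulate_study(cfg, outdir = dir1)
  st2 <- simulate_study(cfg, outdir = dir2)
  for (f in c("reference.fasta", "taxonomy.tsv", "aliquot1.fastq",
              "aliquot2.fastq", "truth1.tsv", "truth2.tsv", "config.json")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # the fixture round-trips through the readers
  lib <- ref_library(read_fasta(file.path(dir1, "reference.fasta")),
                     read_taxonomy(file.path(dir1, "taxonomy.tsv")))
  expect_equal(lib$records$seq, st1$library$records$seq)
  fq <- read_fastq(file.path(dir1, "aliquot1.fastq"))
  expect_equal(fq$seq, st1$aliquots[[1]]$reads$seq)
  # different seeds give different reads
  cfg2 <- sim_config(n_species = 6, seq_length = 150, n_reads = 40,
                     n_aliquots = 2, seed = 88)
  st3 <- simulate_study(cfg2)
  expect_false(identical(st1$aliquots[[1]]$reads$seq,
                         st3$aliquots[[1]]$reads$seq))
})

test_that("presets resolve species by index against the simulated library", {
  cfg <- preset_config("zpdna", seed = 89, n_reads = 50)
  st <- simulate_study(cfg)
  sp <- st$library$taxonomy$species
  expect_setequal(st$truth_species, sp[1:12])
  # contaminant reads present from the 13th species
  reads_sp <- unique(st$aliquots[[1]]$truth$species)
  expect_true(sp[13] %in% reads_sp)
  expect_true(all(reads_sp %in% sp[1:13]))
})
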