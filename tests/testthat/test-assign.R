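test_that("zero-error reads recover per-species counts exactly", {
  cfg <- sim_config(n_species = 10, seq_length = 200, n_reads = 150,
                    forward_primer = "", seed = 61)
  set.seed(61)
  lib <- simulate_reference(cfg, seed = NULL)
  m0 <- error_model(hp_anchors = c("3" = 1), substitution_rate = 0,
                    chimera_rate = 0)
  rr <- simulate_reads(lib, cfg, m0)
  at <- assign_reads(rr$reads, lib, 0.99)
  expect_length(at$unassigned, 0L)
  truth_counts <- table(rr$truth$species)
  expect_equal(at$per_species[names(truth_counts)],
               setNames(as.integer(truth_counts), names(truth_counts)))
  # conservation
  expect_equal(sum(at$per_species) + length(at$unassigned), length(rr$reads))
})

test_that("reads from an absent species are unassigned", {
  set.seed(62)
  refl <- toy_db(replicate(3, rand_seq(150)), paste0("Gen", 1:3))
  alien <- seq_records(paste0("x", 1:5),
                       replicate(5, rand_seq(150)))
  at <- assign_reads(alien, refl, 0.99)
  expect_equal(nrow(at$per_read), 0L)
  expect_setequal(at$unassigned, alien$id)
  expect_true(all(at$per_species == 0L))
})

test_that("a cap mismatch between reads and a capped reference errors out", {
  set.seed(63)
  refl <- toy_db(replicate(3, rand_seq(150)), paste0("Gen", 1:3))
  refl$records <- cap_runs(refl$records, 3)
  reads <- seq_records("r1", paste0("AAAAAA", rand_seq(100)))
  expect_error(assign_reads(reads, refl, 0.99), "cap mismatch")
  # capping the reads the same way clears the guard
  expect_no_error(assign_reads(cap_runs(reads, 3), refl, 0.99))
})

test_that("assigned fraction degrades monotonically with substitution rate", {
  cfg <- sim_config(n_species = 8, seq_length = 250, n_reads = 120,
                    forward_primer = "", seed = 64)
  set.seed(64)
  lib <- simulate_reference(cfg, seed = NULL)
  frac <- vapply(c(0, 0.005, 0.02), function(rate) {
    set.seed(640)
    m <- error_model(hp_anchors = c("3" = 1), substitution_rate = rate,
                     chimera_rate = 0)
    rr <- simulate_reads(lib, cfg, m)
    at <- assign_reads(rr$reads, lib, 0.99)
    nrow(at$per_read) / length(rr$reads)
  }, numeric(1))
  expect_equal(frac[1], 1.0)
  expect_true(all(diff(frac) <= 0))
  expect_gt(frac[1], frac[3])
  expect_gt(frac[3], 0)
})

test_that("residual MOTUs respect the minimum-read rule", {
  set.seed(65)
  s <- rand_seq(150)
  nine <- seq_records(paste0("r", 1:9), rep(s, 9))
  expect_equal(nrow(cluster_residuals(nine, min_reads = 10)), 0L)
  ten <- seq_records(paste0("r", 1:10), rep(s, 10))
  m <- cluster_residuals(ten, min_reads = 10)
  expect_equal(nrow(m), 1L)
  expect_equal(m$read_count, 10L)

  # two divergent read groups of 50 each become two MOTUs, largest first
  s2 <- rand_seq(150)
  both <- seq_records(paste0("r", 1:110),
                      c(rep(s, 60), rep(s2, 50)))
  m2 <- cluster_residuals(both, min_reads = 10)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$read_count, c(60L, 50L))

  # a laxer rule only adds MOTUs (5-read what-if is a superset)
  mixed <- seq_records(paste0("r", 1:67),
                       c(rep(s, 60), rep(s2, 7)))
  m10 <- cluster_residuals(mixed, min_reads = 10)
  m5 <- cluster_residuals(mixed, min_reads = 5)
  expect_true(all(m10$representative %in% m5$representative))
  expect_gt(nrow(m5), nrow(m10))
})

test_that("MOTU classification: best hit, LCA on ties, identity gate", {
  set.seed(66)
  base <- rand_seq(200)
  calanus1 <- base
  calanus2 <- mutate_subs(base, 2)       # congener, close to both
  other <- rand_seq(200)                 # unrelated genus
  db <- toy_db(c(calanus1, calanus2, other),
               c("Calanus", "Calanus", "Temora"),
               c("Calanus helgolandicus", "Calanus finmarchicus",
                 "Temora longicornis"))

  # equidistant from the two congeners -> genus-level call
  # (a sequence between the two: flip one of the two differing bases)
  diff_pos <- which(strsplit(calanus1, "")[[1]] != strsplit(calanus2, "")[[1]])
  mid <- calanus1
  substr(mid, diff_pos[1], diff_pos[1]) <-
    substr(calanus2, diff_pos[1], diff_pos[1])
  hit <- classify_motu(mid, db)
  expect_s3_class(hit, "taxonomic_hit")
  expect_equal(hit$assigned_name, "Calanus sp.")
  expect_equal(hit$assigned_rank, "genus")
  expect_setequal(hit$tied_species,
                  c("Calanus helgolandicus", "Calanus finmarchicus"))

  # unambiguous single best hit -> species rank
  near <- mutate_subs(other, 1)
  hit2 <- classify_motu(near, db)
  expect_equal(hit2$assigned_name, "Temora longicornis")
  expect_equal(hit2$assigned_rank, "species")

  # identity below the 90% gate -> unclassified
  far <- mutate_subs(base, 40)  # 20% divergence
  expect_identical(classify_motu(far, db), "unclassified")

  # score gate: a very short representative cannot exceed score 100
  short_rep <- substr(base, 1, 40)       # max raw score 80 < 100
  expect_identical(classify_motu(short_rep, db), "unclassified")
})

test_that("classification is invariant to database record order", {
  set.seed(67)
  base <- rand_seq(180)
  seqs <- c(base, mutate_subs(base, 2), mutate_subs(base, 2), rand_seq(180))
  genera <- c("Acartia", "Acartia", "Acartia", "Oithona")
  species <- c("Acartia clausi", "Acartia tonsa", "Acartia negligens",
               "Oithona similis")
  rep_seq <- mutate_subs(base, 1)
  perms <- list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))
  names_seen <- vapply(perms, function(p) {
    db <- toy_db(seqs[p], genera[p], species[p])
    hit <- classify_motu(rep_seq, db)
    if (identical(hit, "unclassified")) "unclassified" else hit$assigned_name
  }, character(1))
  expect_length(unique(names_seen), 1L)
})
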