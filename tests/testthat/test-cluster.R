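test_that("pairwise identity matches hand values and the independent aligner", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  # containment scores 1 under the shorter-sequence denominator
  expect_equal(pairwise_identity("ACGTACGT", "ACGT"), 1.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")

  # cross-check against Biostrings on substitution-mutated pairs
  set.seed(41)
  for (i in 1:25) {
    a <- rand_seq(sample(30:70, 1))
    b <- mutate_subs(a, sample(0:6, 1))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
                 tolerance = 1e-9)
  }
})

test_that("pairwise identity is symmetric and 1 iff clean containment", {
  set.seed(42)
  for (i in 1:20) {
    a <- rand_seq(sample(20:60, 1))
    b <- if (i %% 2) mutate_subs(a, sample(0:5, 1)) else rand_seq(sample(20:60, 1))
    expect_identical(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  # substring containment
  a <- rand_seq(50)
  expect_equal(pairwise_identity(a, substr(a, 10, 35)), 1.0)
  # one mismatch in the contained copy drops below 1
  inner <- mutate_subs(substr(a, 10, 35), 1)
  expect_lt(pairwise_identity(a, inner), 1.0)
})

test_that("greedy clustering groups duplicates and respects its contract", {
  x <- seq_records(c("s1", "s2", "s3"),
                   c("ACGTACGT", "ACGTACGT", "TTTTCCCC"))
  cs <- greedy_cluster(x, 0.99)
  expect_length(cs$clusters, 2L)
  pair <- cs$clusters[[which(vapply(cs$clusters,
                                    function(cl) nrow(cl$members),
                                    integer(1)) == 2L)]]
  expect_setequal(pair$members$id, c("s1", "s2"))
  expect_equal(pair$representative, "s1")  # tie on length -> ascending id

  # a permissive threshold collapses similar sequences to one cluster
  set.seed(43)
  root <- rand_seq(50)
  y <- seq_records(paste0("r", 1:6),
                   c(root, replicate(5, mutate_subs(root, sample(1:10, 1)))))
  expect_length(greedy_cluster(y, 0.5)$clusters, 1L)
  expect_error(greedy_cluster(y, 0), "threshold")
  expect_error(greedy_cluster(y, 1.2), "threshold")
})

test_that("cluster sets partition the input and indices run from 0", {
  set.seed(44)
  lib <- family_library(n_fam = 4, fam_size = 3, len = 50)
  for (t in c(0.7, 0.9, 0.99)) {
    cs <- greedy_cluster(lib, t)
    ids <- unlist(cluster_set_partition(cs))
    expect_setequal(ids, lib$id)
    expect_equal(length(ids), length(lib))
    expect_equal(vapply(cs$clusters, `[[`, integer(1), "index"),
                 seq_along(cs$clusters) - 1L)
    # member identities meet the threshold (representative exempt at 1.0)
    for (cl in cs$clusters)
      expect_true(all(cl$members$identity >= t - 1e-9))
  }
})

test_that("greedy clustering agrees with the naive quadratic oracle", {
  set.seed(45)
  for (rep in 1:30) {
    lib <- family_library(n_fam = sample(2:4, 1), fam_size = sample(2:3, 1),
                          len = sample(40:60, 1))
    t <- sample(c(0.75, 0.85, 0.9), 1)
    mode <- sample(c("first_fit", "best_fit"), 1)
    mine <- cluster_set_partition(greedy_cluster(lib, t, mode = mode))
    ref <- naive_cluster(lib, t, mode = mode)
    expect_equal(mine, ref)
  }
})

test_that("degenerate thresholds give all-singletons or one cluster", {
  set.seed(46)
  lib <- family_library(n_fam = 3, fam_size = 2, len = 40, max_sub = 3)
  ids <- motu454:::all_pairwise_identity(lib$seq)
  hi <- greedy_cluster(lib, 1.0)
  expect_length(hi$clusters, length(lib))       # all below 1.0 -> singletons
  lo <- greedy_cluster(lib, min(ids) - 0.01, mode = "best_fit")
  expect_length(lo$clusters, 1L)                # everything joins
})

test_that("reference-guided assignment picks the best species or none", {
  set.seed(47)
  a <- rand_seq(120); b <- rand_seq(120); c <- rand_seq(120)
  refl <- toy_db(c(a, b, c), c("GenA", "GenB", "GenC"))
  sp <- refl$taxonomy$species

  q <- seq_records(c("exact", "far"), c(a, rand_seq(120)))
  res <- cluster_against_reference(q, refl, 0.99)
  expect_equal(res$matched$id, "exact")
  expect_equal(res$matched$species, sp[1])
  expect_equal(res$matched$identity, 1.0)
  expect_equal(res$unmatched, "far")

  # 5% divergence from everything stays unmatched at 0.99
  q2 <- seq_records("div", mutate_subs(a, 6))
  expect_equal(cluster_against_reference(q2, refl, 0.99)$unmatched, "div")
  # ... but matches the nearest species when the threshold allows
  res2 <- cluster_against_reference(q2, refl, 0.90)
  expect_equal(res2$matched$species, sp[1])

  # coverage: matched and unmatched partition the queries
  q3 <- seq_records(paste0("q", 1:6),
                    c(a, mutate_subs(a, 1), b, mutate_subs(b, 30),
                      rand_seq(120), c))
  res3 <- cluster_against_reference(q3, refl, 0.97)
  expect_setequal(c(res3$matched$id, res3$unmatched), q3$id)
})

test_that("zero-error simulated reads all match their source species", {
  cfg <- sim_config(n_species = 8, seq_length = 220, n_reads = 120,
                    forward_primer = "", seed = 48)
  set.seed(48)
  lib <- simulate_reference(cfg, seed = NULL)
  m0 <- error_model(hp_anchors = c("3" = 1), substitution_rate = 0,
                    chimera_rate = 0)
  rr <- simulate_reads(lib, cfg, m0)
  res <- cluster_against_reference(rr$reads, lib, 0.99)
  expect_length(res$unmatched, 0L)
  expect_equal(res$matched$species[match(rr$truth$id, res$matched$id)],
               rr$truth$species)
})
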