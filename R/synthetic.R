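#' 454-style sequencing error model
#'
#' Pyrosequencing's dominant error mode is mis-calling the length of
#' homopolymer runs: base-call accuracy decays with run length. The
#' model anchors per-run accuracy at two published operating points --
#' 99% correct calls for 3-base runs and 64% for 9-mers -- and
#' interpolates log-linearly in run length between them. A miscalled run
#' changes length by exactly one base, split between under- and
#' over-calls by `hp_bias`. Substitutions and single-breakpoint chimeras
#' are modeled independently per base and per read.
#'
#' @param hp_anchors Named numeric vector: names are run lengths,
#'   values the probability of calling the run length correctly.
#'   Default `c("3" = 0.99, "9" = 0.64)`.
#' @param hp_bias Probability that a miscall shortens (rather than
#'   lengthens) the run (default 0.5).
#' @param substitution_rate Per-base substitution probability
#'   (default 0.002).
#' @param chimera_rate Per-read probability of a two-parent chimera
#'   (default 0.01).
#' @return An object of class `error_model`.
#' @export
error_model <- function(hp_anchors = c("3" = 0.99, "9" = 0.64),
                        hp_bias = 0.5, substitution_rate = 0.002,
                        chimera_rate = 0.01) {
  if (!length(hp_anchors)) stop("at least one accuracy anchor is required")
  k <- as.numeric(names(hp_anchors))
  if (anyNA(k)) stop("hp_anchors must be named by run length")
  ord <- order(k)
  hp_anchors <- hp_anchors[ord]
  if (any(hp_anchors < 0 | hp_anchors > 1) || hp_bias < 0 || hp_bias > 1 ||
      substitution_rate < 0 || substitution_rate > 1 ||
      chimera_rate < 0 || chimera_rate > 1)
    stop("probabilities must lie in [0, 1]")
  if (is.unsorted(rev(hp_anchors)))
    stop("accuracy must be non-increasing in run length")
  structure(list(hp_anchors = hp_anchors, hp_bias = hp_bias,
                 substitution_rate = substitution_rate,
                 chimera_rate = chimera_rate),
            class = "error_model")
}

#' Homopolymer call accuracy at a given run length
#'
#' Log-linear interpolation of per-run call accuracy between the model's
#' anchors; run lengths at or below the smallest anchor take that
#' anchor's value, and lengths beyond the largest anchor extrapolate the
#' last segment (clamped to `[0, 1]`).
#'
#' @param k Run length (>= 1); vectorized.
#' @param model An [error_model].
#' @return Probability of calling a k-run's length correctly.
#' @examples
#' m <- error_model()
#' hp_accuracy(3, m)  # 0.99
#' hp_accuracy(9, m)  # 0.64
#' @export
hp_accuracy <- function(k, model = error_model()) {
  stopifnot(all(k >= 1))
  ka <- as.numeric(names(model$hp_anchors))
  la <- log(pmax(model$hp_anchors, 1e-12))
  if (length(ka) == 1L) return(rep(model$hp_anchors[[1]], length(k)))
  lp <- stats::approx(ka, la, xout = pmin(pmax(k, min(ka)), max(ka)),
                      rule = 2)$y
  # extrapolate beyond the largest anchor along the last segment
  over <- k > max(ka)
  if (any(over)) {
    n <- length(ka)
    slope <- (la[n] - la[n - 1]) / (ka[n] - ka[n - 1])
    lp[over] <- la[n] + slope * (k[over] - ka[n])
  }
  pmin(pmax(exp(lp), 0), 1)
}

#' Apply homopolymer run-length errors to a sequence
#'
#' Visits every maximal run of the sequence and, with probability
#' `1 - hp_accuracy(k)` for a run of length `k`, shortens or lengthens
#' it by one base (direction drawn by `hp_bias`). Draws come from the
#' global RNG stream.
#'
#' @param seq A single sequence.
#' @param model An [error_model].
#' @return List with `seq` (the mutated sequence) and `events`
#'   (`data.frame` of `start`, `base`, `run_length`, `delta` for each
#'   miscalled run; zero rows when all runs were called correctly).
#' @export
apply_hp_errors <- function(seq, model) {
  runs <- find_runs(seq)
  miss <- runif(nrow(runs)) >= hp_accuracy(runs$length, model)
  if (!any(miss)) {
    return(list(seq = seq,
                events = data.frame(start = integer(), base = character(),
                                    run_length = integer(), delta = integer())))
  }
  delta <- integer(nrow(runs))
  delta[miss] <- ifelse(runif(sum(miss)) < model$hp_bias, -1L, 1L)
  new_lengths <- pmax(runs$length + delta, 0L)
  out <- paste(rep(runs$base, new_lengths), collapse = "")
  list(seq = out,
       events = data.frame(start = runs$start[miss],
                           base = runs$base[miss],
                           run_length = runs$length[miss],
                           delta = delta[miss]))
}

#' Simulation configuration
#'
#' Settings for the synthetic reference library and 454-style read sets.
#' Defaults emulate the design of an equimolar pooled-DNA mock community:
#' a ~450 bp V1-V2-like amplicon library of 30 species with pairwise
#' identities in 0.90--0.98 and seeded homopolymer runs up to 9 bases,
#' sequenced as two technical-replicate aliquots of 2000 reads each.
#'
#' @param n_species Number of species in the written reference library.
#' @param seq_length Approximate amplicon length in bp.
#' @param identity_range Target range of pairwise identities between
#'   species.
#' @param hp_max_run Longest homopolymer run seeded into the library.
#' @param hp_density Seeded homopolymer runs per bp of the root sequence.
#' @param truth_species Species names truly present in the sample;
#'   `NULL` means all library species.
#' @param contaminants Named numeric vector of read fractions for library
#'   species that are *not* in `truth_species` but leak into the sample
#'   (the contamination scenario); fractions must sum to < 1.
#' @param n_hidden_species Extra species simulated on the same tree but
#'   withheld from the written reference library; their reads can only be
#'   recovered as de novo MOTUs (the natural-sample scenario).
#' @param hidden_fraction Total read fraction drawn from hidden species.
#' @param abundance `"uniform"`, `"lognormal"`, or `"fixed"`.
#' @param lognormal_sigma Log-sd of the lognormal abundance model.
#' @param abundance_vector Named fractions when `abundance = "fixed"`.
#' @param n_reads Reads per aliquot.
#' @param n_aliquots Number of technical replicates.
#' @param forward_primer Primer string prepended to every simulated read
#'   (a standard 18S forward-primer sequence by default; the pipeline
#'   trims it back off).
#' @param seed Mandatory RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 30, seq_length = 450,
                       identity_range = c(0.90, 0.98), hp_max_run = 9,
                       hp_density = 0.015, truth_species = NULL,
                       contaminants = NULL, n_hidden_species = 0,
                       hidden_fraction = 0, abundance = "uniform",
                       lognormal_sigma = 1, abundance_vector = NULL,
                       n_reads = 2000, n_aliquots = 2,
                       forward_primer = "ACCTGGTTGATCCTGCCAGT",
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_species >= 2, seq_length >= 50,
            length(identity_range) == 2, identity_range[1] < identity_range[2])
  if (!is.null(contaminants) && sum(contaminants) + hidden_fraction >= 1)
    stop("contaminant and hidden fractions must sum to < 1")
  structure(list(n_species = n_species, seq_length = seq_length,
                 identity_range = identity_range, hp_max_run = hp_max_run,
                 hp_density = hp_density, truth_species = truth_species,
                 contaminants = contaminants,
                 n_hidden_species = n_hidden_species,
                 hidden_fraction = hidden_fraction,
                 abundance = abundance, lognormal_sigma = lognormal_sigma,
                 abundance_vector = abundance_vector, n_reads = n_reads,
                 n_aliquots = n_aliquots, forward_primer = forward_primer,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant homopolymer runs of length 4..max_run into a sequence
seed_homopolymers <- function(seq, density, max_run) {
  n <- nchar(seq)
  n_runs <- max(1L, round(density * n))
  lens <- sample(4:max_run, n_runs, replace = TRUE)
  lens[1] <- max_run  # guarantee the maximum is realized
  pos <- sort(sample.int(n - max_run - 1L, n_runs))
  chars <- strsplit(seq, "", TRUE)[[1]]
  for (i in seq_len(n_runs)) {
    b <- sample(c("A", "C", "G", "T"), 1)
    chars[pos[i]:(pos[i] + lens[i] - 1L)] <- b
  }
  paste(chars, collapse = "")
}

mutate_branch <- function(seq, div, indel_prob = 0.25) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", TRUE)[[1]]
  nsub <- rbinom(1, n, min(div, 1))
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  }
  if (runif(1) < indel_prob) {
    l <- sample(1:3, 1)
    p <- sample.int(length(chars) - l, 1)
    if (runif(1) < 0.5) chars <- chars[-(p:(p + l - 1L))]
    else chars <- append(chars, sample(c("A", "C", "G", "T"), l, TRUE),
                         after = p)
  }
  paste(chars, collapse = "")
}

#' Simulate a species reference library with taxonomy
#'
#' Evolves a homopolymer-seeded root amplicon along a random bifurcating
#' species tree, calibrating branch lengths so realized pairwise
#' identities (measured with [pairwise_identity]) fall inside the
#' configured window; the calibration is re-tuned a bounded number of
#' times and fails loudly with the achieved range if the window proves
#' infeasible. The taxonomy is read off the tree: shallow clades become
#' genera, deeper ones families and orders, so congeneric tie cases for
#' the lowest-common-ancestor rule exist by construction.
#'
#' @param config A [sim_config].
#' @param seed Optional seed (defaults to `config$seed`); the function
#'   draws from the global RNG stream.
#' @param max_attempts Calibration attempts before giving up.
#' @return A [ref_library]. When `config$n_hidden_species > 0` the extra
#'   species are attached as attribute `hidden` (their own
#'   `ref_library`), withheld from the main library.
#' @export
simulate_reference <- function(config, seed = config$seed, max_attempts = 8) {
  if (!is.null(seed)) set.seed(seed)
  n_total <- config$n_species + config$n_hidden_species
  lo <- config$identity_range[1]; hi <- config$identity_range[2]
  d_min_t <- 1 - hi; d_max_t <- 1 - lo
  tol <- 0.01

  root <- seed_homopolymers(random_seq(config$seq_length),
                            config$hp_density, config$hp_max_run)
  tree <- ape::rtree(n_total)
  D <- ape::cophenetic.phylo(tree)
  Dv <- D[upper.tri(D)]
  a <- (d_max_t - d_min_t) / (max(Dv) - min(Dv))
  cc <- max(0, (d_min_t - a * min(Dv)) / 2)

  achieved <- c(NA_real_, NA_real_)
  for (attempt in seq_len(max_attempts)) {
    tr <- tree
    tr$edge.length <- tr$edge.length * a
    tips <- tr$edge[, 2] <= ape::Ntip(tr)
    tr$edge.length[tips] <- tr$edge.length[tips] + cc
    seqs <- evolve_tree(root, tr)
    ids <- all_pairwise_identity(seqs)
    achieved <- range(ids)
    if (achieved[1] >= lo - tol && achieved[2] <= hi + tol) {
      lib <- build_library(seqs, tr, config)
      return(lib)
    }
    # feedback: map realized divergence range onto the target range
    d_min_r <- 1 - achieved[2]; d_max_r <- 1 - achieved[1]
    f <- (d_max_t - d_min_t) / max(d_max_r - d_min_r, 1e-6)
    cc_new <- max(0, (d_min_t - (d_min_r - 2 * cc) * f) / 2)
    a <- a * f
    cc <- cc_new
  }
  stop(sprintf(paste0("could not calibrate pairwise identities to [%.3f, ",
                      "%.3f] after %d attempts (achieved [%.3f, %.3f])"),
               lo, hi, max_attempts, achieved[1], achieved[2]))
}

# evolve root sequence down the tree; returns named vector by tip label
evolve_tree <- function(root, tree) {
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  ntip <- ape::Ntip(tree)
  seqs <- vector("character", ntip + tree$Nnode)
  seqs[ntip + 1L] <- root
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs[child] <- mutate_branch(seqs[parent], tree$edge.length[e])
  }
  setNames(seqs[seq_len(ntip)], tree$tip.label)
}

all_pairwise_identity <- function(seqs, params = identity_params()) {
  n <- length(seqs)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    out <- c(out, identity_to_many(seqs[i], seqs[(i + 1):n], params))
  }
  out
}

# derive taxonomy labels from tree depth and assemble the ref_library
build_library <- function(seqs, tree, config) {
  n_total <- length(seqs)
  D <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  rng <- range(D[upper.tri(D)])
  cut_at <- function(f) stats::cutree(hc, h = rng[1] + f * diff(rng))
  genus_g <- cut_at(0.25)
  family_g <- cut_at(0.55)
  order_g <- cut_at(0.80)
  phylum_g <- stats::cutree(hc, k = min(2L, n_total))

  tips <- tree$tip.label
  species <- character(n_total)
  genus_name <- paste0("Genus", genus_g[tips])
  within <- stats::ave(seq_len(n_total), genus_g[tips],
                       FUN = seq_along)
  species <- paste0(genus_name, " sp", within)
  tax <- data.frame(
    ref_id = sprintf("REF%04d", seq_len(n_total)),
    phylum = paste0("Phylum", phylum_g[tips]),
    subphylum = ifelse(phylum_g[tips] == 1L, "Subphylum1", NA_character_),
    class = paste0("Class", phylum_g[tips]),
    order = paste0("Order", order_g[tips]),
    family = paste0("Family", family_g[tips]),
    genus = genus_name,
    species = species)
  records <- seq_records(tax$ref_id, unname(seqs[tips]), desc = species)

  n_vis <- config$n_species
  vis <- seq_len(n_vis)
  lib <- ref_library(records[vis], tax[vis, ])
  if (config$n_hidden_species > 0) {
    hid <- (n_vis + 1L):n_total
    attr(lib, "hidden") <- ref_library(records[hid], tax[hid, ])
  }
  lib
}

#' Simulate a 454-style read set with ground truth
#'
#' Draws each read's source species from the contaminant-adjusted
#' abundance vector, copies its reference sequence, optionally recombines
#' it with a second parent at a single breakpoint (chimera), applies
#' run-length miscalls ([apply_hp_errors]) and substitutions, and emits
#' Phred qualities (high baseline, degraded across homopolymer runs).
#' Every read has exactly one ground-truth record.
#'
#' @param library A [ref_library] (with optional `hidden` attribute, see
#'   [simulate_reference]).
#' @param config A [sim_config].
#' @param model An [error_model].
#' @param aliquot Aliquot number (used in read ids).
#' @return List with `reads` (a [seq_records] with qualities) and
#'   `truth` (`data.frame` of `id`, `species`, `chimera_parent`,
#'   `n_hp_events`, `n_substitutions`).
#' @export
simulate_reads <- function(library, config, model = error_model(),
                           aliquot = 1L) {
  stopifnot(inherits(library, "ref_library"), inherits(config, "sim_config"))
  hidden <- attr(library, "hidden")
  pool_seqs <- library$records$seq
  pool_species <- library$taxonomy$species
  if (!is.null(hidden)) {
    pool_seqs <- c(pool_seqs, hidden$records$seq)
    pool_species <- c(pool_species, hidden$taxonomy$species)
  }
  names(pool_seqs) <- pool_species

  truth_sp <- config$truth_species
  if (is.null(truth_sp)) truth_sp <- library$taxonomy$species
  prob <- abundance_probs(config, truth_sp, pool_species)

  n <- config$n_reads
  src <- sample(names(prob), n, replace = TRUE, prob = prob)
  ids <- sprintf("A%dR%05d", aliquot, seq_len(n))
  seqs <- character(n)
  quals <- vector("list", n)
  parent2 <- rep(NA_character_, n)
  n_hp <- integer(n)
  n_sub <- integer(n)

  for (i in seq_len(n)) {
    s <- pool_seqs[[src[i]]]
    if (runif(1) < model$chimera_rate && length(pool_seqs) > 1L) {
      other <- sample(setdiff(names(pool_seqs), src[i]), 1)
      bp <- runif(1, 0.3, 0.7)
      s2 <- pool_seqs[[other]]
      s <- paste0(substr(s, 1, round(bp * nchar(s))),
                  substr(s2, round(bp * nchar(s2)) + 1L, nchar(s2)))
      parent2[i] <- other
    }
    hp <- apply_hp_errors(s, model)
    s <- hp$seq
    n_hp[i] <- nrow(hp$events)
    if (model$substitution_rate > 0) {
      chars <- strsplit(s, "", TRUE)[[1]]
      pos <- which(runif(length(chars)) < model$substitution_rate)
      for (p in pos)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      n_sub[i] <- length(pos)
      s <- paste(chars, collapse = "")
    }
    q <- read_quality(s)
    if (nzchar(config$forward_primer)) {
      s <- paste0(config$forward_primer, s)
      q <- c(sample(38:40, nchar(config$forward_primer), TRUE), q)
    }
    seqs[i] <- s
    quals[[i]] <- q
  }
  reads <- seq_records(ids, seqs, desc = src, qual = quals)
  truth <- data.frame(id = ids, species = src, chimera_parent = parent2,
                      n_hp_events = n_hp, n_substitutions = n_sub)
  list(reads = reads, truth = truth)
}

# high baseline quality, degraded across homopolymer runs >= 3
read_quality <- function(seq) {
  n <- nchar(seq)
  q <- sample(30:40, n, replace = TRUE)
  runs <- find_runs(seq)
  long <- runs[runs$length >= 3L, , drop = FALSE]
  for (j in seq_len(nrow(long))) {
    idx <- (long$start[j] + 1L):(long$start[j] + long$length[j])
    q[idx] <- sample(18:28, length(idx), replace = TRUE)
  }
  q
}

abundance_probs <- function(config, truth_sp, pool_species) {
  if (!all(truth_sp %in% pool_species))
    stop("truth species missing from the library: ",
         paste(setdiff(truth_sp, pool_species), collapse = ", "))
  contam_frac <- if (is.null(config$contaminants)) 0
                 else sum(config$contaminants)
  hidden_frac <- config$hidden_fraction
  main_frac <- 1 - contam_frac - hidden_frac
  w <- switch(config$abundance,
    uniform = setNames(rep(1, length(truth_sp)), truth_sp),
    lognormal = setNames(rlnorm(length(truth_sp), 0, config$lognormal_sigma),
                         truth_sp),
    fixed = {
      v <- config$abundance_vector[truth_sp]
      if (anyNA(v)) stop("abundance_vector must cover all truth species")
      v
    },
    stop("unknown abundance model: ", config$abundance))
  prob <- main_frac * w / sum(w)
  if (!is.null(config$contaminants)) {
    if (!all(names(config$contaminants) %in% pool_species))
      stop("contaminant species missing from the library")
    prob <- c(prob, config$contaminants)
  }
  if (hidden_frac > 0) {
    # the pool is c(visible, hidden) species in order
    hidden_sp <- utils::tail(pool_species, config$n_hidden_species)
    prob <- c(prob, setNames(rep(hidden_frac / length(hidden_sp),
                                 length(hidden_sp)), hidden_sp))
  }
  prob
}

#' Simulate a full study and write its fixture set to disk
#'
#' Runs [simulate_reference] once and [simulate_reads] per aliquot under
#' the single RNG stream seeded by `config$seed`, then writes the
#' reference FASTA, taxonomy TSV, per-aliquot FASTQ files, per-aliquot
#' truth tables and a JSON echo of the configuration. Identical seeds
#' give byte-identical fixtures.
#'
#' @param config A [sim_config].
#' @param outdir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param model An [error_model].
#' @return Invisibly, a list with `library`, `aliquots` (list of
#'   [simulate_reads] results), `truth_species` and `paths`.
#' @export
simulate_study <- function(config, outdir = NULL, model = error_model()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  library <- simulate_reference(config, seed = NULL)
  config <- resolve_preset(config, library)
  # aliquots are technical replicates of one pool: the community abundance
  # vector is drawn once per study, not once per aliquot
  if (config$abundance == "lognormal") {
    truth_sp <- config$truth_species
    if (is.null(truth_sp)) truth_sp <- library$taxonomy$species
    config$abundance_vector <- setNames(
      rlnorm(length(truth_sp), 0, config$lognormal_sigma), truth_sp)
    config$abundance <- "fixed"
  }
  aliquots <- lapply(seq_len(config$n_aliquots), function(a)
    simulate_reads(library, config, model, aliquot = a))
  truth_sp <- config$truth_species
  if (is.null(truth_sp)) truth_sp <- library$taxonomy$species

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(reference = file.path(outdir, "reference.fasta"),
                  taxonomy = file.path(outdir, "taxonomy.tsv"),
                  config = file.path(outdir, "config.json"))
    write_fasta(library$records, paths$reference)
    write_taxonomy(library$taxonomy, paths$taxonomy)
    for (a in seq_along(aliquots)) {
      fq <- file.path(outdir, sprintf("aliquot%d.fastq", a))
      tt <- file.path(outdir, sprintf("truth%d.tsv", a))
      write_fastq(aliquots[[a]]$reads, fq)
      write.table(aliquots[[a]]$truth, tt, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths[[sprintf("aliquot%d", a)]] <- fq
      paths[[sprintf("truth%d", a)]] <- tt
    }
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(list(library = library, aliquots = aliquots,
                 truth_species = truth_sp, paths = paths))
}

#' Preset study configurations
#'
#' Three miniature study designs: `"alldna"` (all 30 library species
#' pooled equimolar), `"zpdna"` (a 12-species subset of the 30-species
#' library plus one known library species leaking in at 5% of reads --
#' the contamination scenario), and `"zphts"` (a natural-sample stand-in:
#' 15 in-library species with lognormal abundances plus 3 species
#' withheld from the reference so that their reads surface only as de
#' novo MOTUs).
#'
#' @param preset One of `"alldna"`, `"zpdna"`, `"zphts"`.
#' @param seed RNG seed.
#' @param n_reads Reads per aliquot.
#' @return A [sim_config].
#' @export
preset_config <- function(preset = c("alldna", "zpdna", "zphts"), seed,
                          n_reads = 2000) {
  preset <- match.arg(preset)
  base <- sim_config(seed = seed, n_reads = n_reads)
  if (preset == "alldna") return(base)
  # species names are deterministic only after the library is built, so
  # presets select by index; simulate_study resolves them.
  if (preset == "zpdna") {
    cfg <- sim_config(seed = seed, n_reads = n_reads,
                      truth_species = I(1:12), contaminants = c(`13` = 0.05))
    attr(cfg, "by_index") <- TRUE
    return(cfg)
  }
  cfg <- sim_config(seed = seed, n_reads = n_reads,
                    truth_species = I(1:15), n_hidden_species = 3,
                    hidden_fraction = 0.15, abundance = "lognormal")
  attr(cfg, "by_index") <- TRUE
  cfg
}

#' Resolve an index-based preset against a simulated library
#'
#' Preset configurations refer to species by library index (the library
#' does not exist until it is simulated); this replaces those indices by
#' the actual species names of `library`.
#'
#' @param config A [sim_config] from [preset_config].
#' @param library The simulated [ref_library].
#' @return The resolved [sim_config].
#' @export
resolve_preset <- function(config, library) {
  if (is.null(attr(config, "by_index"))) return(config)
  sp <- library$taxonomy$species
  if (!is.null(config$truth_species))
    config$truth_species <- sp[as.integer(config$truth_species)]
  if (!is.null(config$contaminants))
    names(config$contaminants) <- sp[as.integer(names(config$contaminants))]
  attr(config, "by_index") <- NULL
  config
}
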