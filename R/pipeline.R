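#' Pipeline configuration
#'
#' Names every input and threshold of the full read-analysis pipeline:
#' filter, homopolymer capping, reference assignment, residual MOTU
#' clustering, and MOTU classification.
#'
#' @param reads A [seq_records] object, a FASTQ path, or a list of either
#'   (one element per sample aliquot).
#' @param reference A [ref_library], or a length-2 list/character vector
#'   `c(fasta, taxonomy_tsv)` of file paths.
#' @param filter A [filter_params] object, or `NULL` to skip filtering
#'   (reads already clean and trimmed).
#' @param cap_k Homopolymer cap applied to both reads and reference
#'   before assignment (default 3).
#' @param assign_threshold Reference-assignment identity threshold
#'   (default 0.99).
#' @param residual_threshold De novo clustering threshold for unassigned
#'   reads (default 0.99).
#' @param min_reads Minimum reads for a residual cluster to survive as a
#'   MOTU (default 10).
#' @param min_score,min_identity Gates of the MOTU classification search
#'   (defaults 100 and 0.90).
#' @param params An [identity_params] scoring scheme.
#' @param truth Optional character vector of species truly present, for
#'   detection accounting.
#' @param outdir Optional output directory for intermediates and the run
#'   manifest.
#' @param seed Optional seed recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, reference, filter = NULL, cap_k = 3,
                            assign_threshold = 0.99,
                            residual_threshold = 0.99, min_reads = 10,
                            min_score = 100, min_identity = 0.90,
                            params = identity_params(), truth = NULL,
                            outdir = NULL, seed = NULL) {
  structure(list(reads = reads, reference = reference, filter = filter,
                 cap_k = cap_k, assign_threshold = assign_threshold,
                 residual_threshold = residual_threshold,
                 min_reads = min_reads, min_score = min_score,
                 min_identity = min_identity, params = params,
                 truth = truth, outdir = outdir, seed = seed),
            class = "pipeline_config")
}

load_reads <- function(x) {
  if (inherits(x, "seq_records")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_fastq(x))
  stop("cannot interpret reads input")
}

load_reference <- function(x) {
  if (inherits(x, "ref_library")) return(x)
  if (length(x) == 2L)
    return(ref_library(read_fasta(x[[1]]), read_taxonomy(x[[2]])))
  stop("reference must be a ref_library or c(fasta, taxonomy) paths")
}

#' Run the full read-analysis pipeline
#'
#' For every aliquot: quality/primer/length filtering, homopolymer
#' capping of reads and reference to the same level, best-hit assignment
#' against the reference library at the assignment threshold, de novo
#' clustering of the residual reads into MOTUs with the minimum-read
#' rule, and taxonomic classification of each MOTU representative with
#' the score/identity gates and the lowest-shared-rank tie rule. With
#' two or more aliquots the between-aliquot reproducibility correlation
#' is computed; with a `truth` composition a detection report per
#' aliquot. When `outdir` is set all intermediates and a manifest
#' logging every parameter are written; reruns with identical inputs are
#' byte-identical.
#'
#' @param config A [pipeline_config].
#' @return Object of class `motu_pipeline`: list with `aliquots` (each
#'   holding `filter`, `assignment`, `motus`, `detection`),
#'   `correlation` (between the first two aliquots, when available),
#'   and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  reference <- load_reference(config$reference)
  ref_capped <- reference
  ref_capped$records <- cap_runs(reference$records, config$cap_k)

  reads_in <- config$reads
  if (!is.list(reads_in) || inherits(reads_in, "seq_records"))
    reads_in <- list(reads_in)

  aliquots <- vector("list", length(reads_in))
  for (a in seq_along(reads_in)) {
    reads <- load_reads(reads_in[[a]])
    stage <- list()
    if (!is.null(config$filter)) {
      stage$filter <- filter_reads(reads, config$filter)
      kept <- stage$filter$kept
    } else {
      stage$filter <- NULL
      kept <- reads
    }
    capped <- cap_runs(kept, config$cap_k)
    stage$assignment <- assign_reads(capped, ref_capped,
                                     threshold = config$assign_threshold,
                                     params = config$params)
    residual <- capped[match(stage$assignment$unassigned, capped$id)]
    stage$motus <- cluster_residuals(residual,
                                     threshold = config$residual_threshold,
                                     min_reads = config$min_reads,
                                     params = config$params)
    if (nrow(stage$motus)) {
      rep_seqs <- attr(stage$motus, "rep_seq")
      for (m in seq_len(nrow(stage$motus))) {
        hit <- classify_motu(rep_seqs[m], ref_capped,
                             min_score = config$min_score,
                             min_identity = config$min_identity,
                             params = config$params)
        stage$motus$label[m] <- if (identical(hit, "unclassified"))
          "unclassified" else hit$assigned_name
      }
    }
    if (!is.null(config$truth))
      stage$detection <- detection_report(stage$assignment, config$truth)
    aliquots[[a]] <- stage
  }

  correlation <- NULL
  if (length(aliquots) >= 2L) {
    p1 <- read_profile(aliquots[[1]]$assignment, "aliquot1")
    p2 <- read_profile(aliquots[[2]]$assignment, "aliquot2")
    correlation <- profile_correlation(p1, p2)
  }

  out <- structure(list(aliquots = aliquots, correlation = correlation,
                        config = config),
                   class = "motu_pipeline")
  if (!is.null(config$outdir)) write_pipeline_outputs(out, reference)
  out
}

write_pipeline_outputs <- function(out, reference) {
  config <- out$config
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  for (a in seq_along(out$aliquots)) {
    st <- out$aliquots[[a]]
    pre <- file.path(config$outdir, sprintf("aliquot%d", a))
    if (!is.null(st$filter)) {
      write_fasta(st$filter$kept, paste0(pre, "_kept.fasta"))
      write.table(st$filter$rejected, paste0(pre, "_rejected.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(st$assignment$per_read, paste0(pre, "_assign.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(st$motus), paste0(pre, "_motus.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    n_aliquots = length(out$aliquots),
    cap_k = config$cap_k,
    assign_threshold = config$assign_threshold,
    residual_threshold = config$residual_threshold,
    min_reads = config$min_reads,
    min_score = config$min_score,
    min_identity = config$min_identity,
    scoring = unclass(config$params),
    filter = if (!is.null(config$filter)) unclass(config$filter),
    seed = config$seed,
    n_reference_species = length(reference$records))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out)
}

#' @export
print.motu_pipeline <- function(x, ...) {
  cat(sprintf("motu_pipeline: %d aliquot(s)\n", length(x$aliquots)))
  for (a in seq_along(x$aliquots)) {
    st <- x$aliquots[[a]]
    n_in <- if (!is.null(st$filter))
      length(st$filter$kept) + nrow(st$filter$rejected)
    else nrow(st$assignment$per_read) + length(st$assignment$unassigned)
    cat(sprintf(
      "  aliquot %d: %d reads in, %d kept, %d assigned, %d MOTU(s)\n",
      a, n_in,
      nrow(st$assignment$per_read) + length(st$assignment$unassigned),
      nrow(st$assignment$per_read), nrow(st$motus)))
    if (!is.null(st$detection))
      cat(sprintf("    detection: %.1f%% of truth, %d unexpected\n",
                  100 * st$detection$detection_rate,
                  length(st$detection$unexpected)))
  }
  if (!is.null(x$correlation))
    cat(sprintf("  aliquot reproducibility: Spearman rho = %.3f (p = %.3g)\n",
                x$correlation$rho, x$correlation$p_value))
  invisible(x)
}

#' Benchmark against a deposited reference library and read runs
#'
#' Reproduces the headline numbers of the original study design given
#' local copies of the deposited data: the threshold-by-cap delineation
#' sweep of the Sanger reference library and, per sequencing run, the
#' filter / cap / assign pipeline with detection accounting. The
#' deposited data are not shipped with the package; supply paths to a
#' reference FASTA, its taxonomy TSV, and the per-aliquot FASTQ files.
#'
#' @param ref_fasta,taxonomy_tsv Reference library files.
#' @param fastq_paths Character vector of read files (one per aliquot).
#' @param filter A [filter_params] for the runs.
#' @param thresholds,caps Sweep settings (defaults mirror the study).
#' @return List with `sweep` (a `delineation_sweep`) and `pipeline` (a
#'   `motu_pipeline` over the runs).
#' @export
benchmark_deposited <- function(ref_fasta, taxonomy_tsv, fastq_paths,
                                filter,
                                thresholds = c(0.97, 0.98, 0.99, 1.00),
                                caps = c(Inf, 5, 4, 3, 2)) {
  reference <- ref_library(read_fasta(ref_fasta), read_taxonomy(taxonomy_tsv))
  sweep <- threshold_sweep(reference, thresholds, caps)
  pipe <- run_pipeline(pipeline_config(
    reads = as.list(fastq_paths), reference = reference, filter = filter,
    truth = reference$taxonomy$species))
  list(sweep = sweep, pipeline = pipe)
}
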