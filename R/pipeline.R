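# Pipeline orchestration: declarative configuration, validation, staged
# execution with a manifest, and deterministic reruns.

#' Build and validate a pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()], filling documented
#' defaults for unset fields and recording which fields were defaulted (the
#' manifest reports them). Validation checks that every referenced path
#' exists and that numeric parameters are in range; it fails before any
#' stage runs.
#'
#' @param reads path to input reads (FASTA or FASTQ, by extension).
#' @param out_dir output directory.
#' @param databases named list of reference databases, each a list with
#'   `fasta` and `lineages` paths.
#' @param rrna_alignment aligned FASTA to train the rRNA profile HMM
#'   (exactly one of `rrna_alignment`/`hmm` required).
#' @param hmm path to a serialized profile HMM ([write_hmm()]).
#' @param contigs,protein_refs,protein_annotations,obo,slim,seed_table
#'   optional functional-arm inputs; all six must be given to enable it.
#' @param rrna_threshold fragment-calling threshold in bits (default: 0.25
#'   bits per match state).
#' @param k mapper k-mer size; `min_identity` mapper identity floor.
#' @param rank_thresholds per-rank identity thresholds.
#' @param n_workers mapping workers.
#' @param seed global seed recorded in the manifest.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(reads, out_dir, databases,
                            rrna_alignment = NULL, hmm = NULL,
                            contigs = NULL, protein_refs = NULL,
                            protein_annotations = NULL, obo = NULL,
                            slim = NULL, seed_table = NULL,
                            rrna_threshold = NULL, k = NULL,
                            min_identity = NULL, rank_thresholds = NULL,
                            n_workers = NULL, seed = NULL) {
  defaults <- list(k = 8L, min_identity = 75,
                   rank_thresholds = default_rank_thresholds(),
                   n_workers = 1L, seed = 1L)
  cfg <- list(reads = reads, out_dir = out_dir, databases = databases,
              rrna_alignment = rrna_alignment, hmm = hmm,
              contigs = contigs, protein_refs = protein_refs,
              protein_annotations = protein_annotations, obo = obo,
              slim = slim, seed_table = seed_table,
              rrna_threshold = rrna_threshold, k = k,
              min_identity = min_identity,
              rank_thresholds = rank_thresholds, n_workers = n_workers,
              seed = seed)
  defaulted <- character(0)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
      defaulted <- c(defaulted, nm)
    }
  }
  if (is.null(cfg$rrna_threshold)) {
    defaulted <- c(defaulted, "rrna_threshold") # resolved once model known
  }
  cfg$defaulted <- defaulted
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  fail <- function(...) stop("validation error: ", ..., call. = FALSE)
  need_file <- function(path, what) {
    if (!is.null(path) && !file.exists(path)) {
      fail(what, " path does not exist: ", path)
    }
  }
  need_file(config$reads, "reads")
  if (is.null(config$reads)) fail("reads path is required")
  if (!length(config$databases)) fail("at least one database is required")
  if (is.null(names(config$databases)) ||
      any(!nzchar(names(config$databases)))) {
    fail("databases must be a named list")
  }
  for (nm in names(config$databases)) {
    need_file(config$databases[[nm]]$fasta, paste0("database '", nm, "'"))
    need_file(config$databases[[nm]]$lineages,
              paste0("database '", nm, "' lineage"))
  }
  if (is.null(config$rrna_alignment) && is.null(config$hmm)) {
    fail("one of rrna_alignment or hmm is required")
  }
  need_file(config$rrna_alignment, "rrna_alignment")
  need_file(config$hmm, "hmm")
  fun_args <- c("contigs", "protein_refs", "protein_annotations", "obo",
                "slim", "seed_table")
  given <- !vapply(config[fun_args], is.null, logical(1))
  if (any(given) && !all(given)) {
    fail("functional analysis needs all of: ",
         paste(fun_args, collapse = ", "))
  }
  for (a in fun_args) need_file(config[[a]], a)
  if (config$k < 4L) fail("k must be >= 4")
  if (config$min_identity < 0 || config$min_identity > 100) {
    fail("min_identity must be in [0, 100]")
  }
  if (config$n_workers < 1L) fail("n_workers must be >= 1")
  invisible(config)
}

read_any_reads <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, "@")) read_fastq(path) else
    read_fasta(path)
}

#' Run the full profiling pipeline
#'
#' Stages: read ingestion, rRNA profile-HMM build (or load), fragment
#' extraction, per-database mapping and taxonomic profiling, multi-database
#' integration, optional functional analysis (gene prediction,
#' identification, GOSlim and SEED rollups), comparison across databases
#' and visualization. Every stage's output is written under
#' `config$out_dir`, together with `manifest.json` recording inputs,
#' parameters (including every filled default), stage statistics, the seed
#' and the package version. A failing stage writes a `FAILED` marker naming
#' itself, retains prior outputs and aborts. Reruns with the same config
#' reproduce identical tables.
#'
#' @param config a validated [pipeline_config()].
#' @return named list of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(manifest = file.path(out, "manifest.json"))
  stats <- list()
  stage <- "setup"
  on_fail <- function(e) {
    write_lines_utf8(c(paste0("FAILED at stage: ", stage),
                       conditionMessage(e)),
                     file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "ingest"
    reads <- read_any_reads(config$reads)
    stats$n_reads <- nrow(reads)

    stage <- "hmm"
    hmm <- if (!is.null(config$hmm)) read_hmm(config$hmm) else
      build_profile_hmm(read_fasta(config$rrna_alignment,
                                   allow_gaps = TRUE))
    threshold <- config$rrna_threshold %||% default_hmm_threshold(hmm)
    paths$hmm <- file.path(out, "rrna_model.hmm")
    write_hmm(hmm, paths$hmm)

    stage <- "extract"
    frags <- extract_fragments(reads, hmm, threshold)
    stats$n_fragments <- nrow(frags)
    paths$fragments <- file.path(out, "fragments.fasta")
    write_fasta(seq_records(frags$read_id, frags$fragment,
                            desc = paste0(frags$strand, " score=",
                                          sprintf("%.2f", frags$score))),
                paths$fragments)

    stage <- "profile"
    queries <- seq_records(frags$read_id, frags$fragment)
    profiles <- list()
    for (db in names(config$databases)) {
      refs <- read_fasta(config$databases[[db]]$fasta)
      lineages <- read_lineage_table(config$databases[[db]]$lineages)
      index <- build_kmer_index(refs, k = config$k)
      hits <- map_all(queries, index, n_workers = config$n_workers,
                      min_identity = config$min_identity)
      paths[[paste0("hits_", db)]] <- file.path(out,
                                                paste0("hits_", db, ".tsv"))
      write_hits_table(hits, paths[[paste0("hits_", db)]])
      asg <- assign_lineages(hits, lineages, config$rank_thresholds)
      profiles[[db]] <- build_taxonomic_profile(asg, db)
      stats[[paste0("n_assigned_", db)]] <- nrow(hits)
      paths[[paste0("profile_", db)]] <-
        file.path(out, paste0("profile_", db, ".tsv"))
      write_profile_table(profiles[[db]],
                          paths[[paste0("profile_", db)]])
    }

    stage <- "integrate"
    if (length(profiles) > 1L) {
      integrated <- integrate_profiles(profiles)
      paths$profile_integrated <- file.path(out, "profile_integrated.tsv")
      write_profile_table(integrated, paths$profile_integrated)
    }

    stage <- "compare"
    if (length(profiles) > 1L) {
      comp <- compare_profiles(profiles, "genus")
      paths$comparison <- file.path(out, "comparison_genus.tsv")
      write_comparison_table(comp, paths$comparison)
      paths$global_view <- file.path(out, "global_view.svg")
      export_global_view(comp, paths$global_view)
    }

    stage <- "functional"
    if (!is.null(config$contigs)) {
      contigs <- read_fasta(config$contigs)
      genes <- predict_genes(contigs)
      stats$n_genes <- nrow(genes)
      refs <- read_fasta(config$protein_refs, alphabet = "protein")
      ann <- read.delim(config$protein_annotations,
                        stringsAsFactors = FALSE)
      idents <- identify_genes(genes, refs, ann,
                               n_workers = config$n_workers,
                               min_identity = config$min_identity)
      stats$n_annotated_genes <- nrow(idents)
      ontology <- read_obo(config$obo)
      slim_ids <- readLines(config$slim, warn = FALSE)
      slim_ids <- slim_ids[nzchar(slim_ids)]
      goslim <- rollup_goslim(idents, ontology, slim_ids)
      paths$goslim <- file.path(out, "functional_goslim.tsv")
      write_profile_table(goslim, paths$goslim)
      seed_prof <- rollup_seed(idents, read_seed_table(config$seed_table))
      paths$seed <- file.path(out, "functional_seed.tsv")
      write_profile_table(seed_prof, paths$seed)
    }

    stage <- "visualize"
    layouts <- lapply(profiles, layout_sample_view)
    paths$sample_view <- file.path(out, "sample_view.html")
    export_html(layouts, list(title = "sample view"), paths$sample_view)

    stage <- "manifest"
    manifest <- list(
      tool = "metaprof",
      version = as.character(utils::packageVersion("metaprof")),
      seed = config$seed,
      inputs = Filter(Negate(is.null),
                      list(reads = config$reads,
                           databases = config$databases,
                           rrna_alignment = config$rrna_alignment,
                           hmm = config$hmm, contigs = config$contigs)),
      parameters = list(rrna_threshold = threshold, k = config$k,
                        min_identity = config$min_identity,
                        rank_thresholds = as.list(config$rank_thresholds),
                        n_workers = config$n_workers),
      defaulted_parameters = config$defaulted,
      statistics = stats)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }, error = on_fail)
  invisible(paths)
}

#' Write / read a mapper hits table
#'
#' Tab-separated, columns `query_id`, `ref_id`, `identity`, `aln_len`,
#' `score`, `qstart`, `qend`, `rstart`, `rend`, `strand`.
#'
#' @param hits data frame from [map_all()].
#' @param path file path.
#' @return `path` (write) or the hits data frame (read).
#' @export
write_hits_table <- function(hits, path) {
  header <- paste(c("query_id", "ref_id", "identity", "aln_len", "score",
                    "qstart", "qend", "rstart", "rend", "strand"),
                  collapse = "\t")
  lines <- c(header,
             if (nrow(hits)) {
               paste(hits$query_id, hits$ref_id,
                     sprintf("%.4f", hits$identity), hits$aln_len,
                     sprintf("%.4f", hits$score), hits$qstart, hits$qend,
                     hits$rstart, hits$rend, hits$strand, sep = "\t")
             })
  write_lines_utf8(lines, path)
}

#' @rdname write_hits_table
#' @export
read_hits_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(query_id = "character", ref_id = "character",
                            strand = "character"))
}
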