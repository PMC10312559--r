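# End-to-end pipeline runner and run configuration. The command-line
# entry point (inst/cli/ampliref.R) is a thin argument-parsing layer over
# these functions.

#' Build a validated run configuration
#'
#' Collects every knob of the three pipeline stages plus input/output
#' locations into one validated object that is serialized verbatim into
#' each stage's provenance record. A YAML file with the same field names
#' can be loaded with [read_run_config()]; explicit arguments override
#' file values.
#'
#' @param forward,reverse Primer sequences (IUPAC codes allowed).
#' @param corpus Path to the corpus FASTA.
#' @param acc2taxid Path to the accession-to-taxid map.
#' @param nodes,names Paths to the taxdump-dialect taxonomy files.
#' @param membership Optional membership-map path.
#' @param out_dir Output directory; each stage writes to a subdirectory.
#' @param min_length,max_length,max_mismatch,n_max_variants Seed-stage
#'   knobs, see [seed_params()].
#' @param rank,max_to_blast,sample_size_per_stratum,max_iterations
#'   Expansion-stage knobs, see [expansion_params()].
#' @param min_identity,max_evalue,min_coverage Similarity filter knobs,
#'   see [similarity_params()].
#' @param na_mode Dereplication NA-filter mode, see
#'   [filter_na_lineages()].
#' @param method Search backend, `"internal"` or `"blast"`.
#' @param rng_seed Single seed from which all stage randomness derives.
#' @param db_name Output file prefix for the final database.
#' @return A `run_config` list.
#' @export
run_config <- function(forward, reverse, corpus, acc2taxid, nodes, names,
                       membership = NULL, out_dir = "ampliref_out",
                       min_length = 50L, max_length = 2000L,
                       max_mismatch = 3L, n_max_variants = 25L,
                       rank = "genus", max_to_blast = 1000L,
                       sample_size_per_stratum = 1L, max_iterations = 100L,
                       min_identity = 70, max_evalue = 10,
                       min_coverage = 0.5, na_mode = "all",
                       method = "internal", rng_seed = 1L,
                       db_name = "reference") {
  cfg <- list(forward = forward, reverse = reverse, corpus = corpus,
              acc2taxid = acc2taxid, nodes = nodes, names = names,
              membership = membership, out_dir = out_dir,
              min_length = as.integer(min_length),
              max_length = as.integer(max_length),
              max_mismatch = as.integer(max_mismatch),
              n_max_variants = as.integer(n_max_variants), rank = rank,
              max_to_blast = as.integer(max_to_blast),
              sample_size_per_stratum = as.integer(sample_size_per_stratum),
              max_iterations = as.integer(max_iterations),
              min_identity = min_identity, max_evalue = max_evalue,
              min_coverage = min_coverage, na_mode = na_mode,
              method = method, rng_seed = as.integer(rng_seed),
              db_name = db_name)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (f in c("corpus", "acc2taxid", "nodes", "names")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop(sprintf("input file for '%s' is missing or does not exist: %s",
                   f, cfg[[f]] %||% "<unset>"), call. = FALSE)
    }
  }
  if (!is.null(cfg$membership) && !file.exists(cfg$membership)) {
    stop(sprintf("membership file does not exist: %s", cfg$membership),
         call. = FALSE)
  }
  # validates IUPAC alphabet early, with a clear message
  primer_set(cfg$forward, cfg$reverse)
  stopifnot(cfg$rank %in% LINEAGE_RANKS,
            cfg$na_mode %in% c("all", "any"),
            cfg$method %in% c("internal", "blast"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @param overrides Named list of values taking precedence over the file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  overrides <- overrides[!vapply(overrides, is.null, logical(1L))]
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

#' Run the full reference-database pipeline
#'
#' Stages: seed discovery (in silico PCR), iterative stratified expansion,
#' dereplication/curation. Outputs land under `cfg$out_dir` in
#' `1_seeds/`, `2_expansion/` and `3_derep/`. All randomness derives from
#' `cfg$rng_seed`, so a re-run with the same configuration reproduces the
#' final FASTA and taxonomy files byte for byte.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A list: `seeds` (`seed_result`), `expansion`
#'   (`expansion_result`), `db` (`ref_database`), `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- if (quiet) function(...) invisible() else message
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("loading corpus and taxonomy ...")
  corpus <- read_fasta(cfg$corpus)
  store <- load_taxdump(cfg$nodes, cfg$names, acc2taxid = cfg$acc2taxid,
                        membership = cfg$membership)
  primers <- primer_set(cfg$forward, cfg$reverse)

  say("stage 1/3: seed discovery (in silico PCR)")
  sp <- seed_params(min_product_length = cfg$min_length,
                    max_product_length = cfg$max_length,
                    max_mismatch_per_primer = cfg$max_mismatch,
                    n_max_variants = cfg$n_max_variants,
                    rng_seed = cfg$rng_seed)
  seeds <- find_seeds(primers, corpus, store, sp, method = cfg$method,
                      summary_rank = cfg$rank)
  write_seeds(seeds, file.path(cfg$out_dir, "1_seeds"), params = sp)
  say(sprintf("  %d seeds on %d accessions", nrow(seeds$seeds),
              seeds$summary$accessions_with_seeds))
  if (!nrow(seeds$seeds)) {
    warning("no seeds found; downstream stages produce empty outputs")
    db <- build_reference(empty_similarity_hits()[0, ],
                          out_dir = file.path(cfg$out_dir, "3_derep"),
                          name = cfg$db_name, na_mode = cfg$na_mode)
    return(list(seeds = seeds, expansion = NULL, db = db,
                out_dir = cfg$out_dir))
  }

  say("stage 2/3: iterative stratified expansion")
  ep <- expansion_params(
    rank = cfg$rank, max_to_blast = cfg$max_to_blast,
    sample_size_per_stratum = cfg$sample_size_per_stratum,
    sim = similarity_params(min_percent_identity = cfg$min_identity,
                            max_evalue = cfg$max_evalue,
                            min_query_coverage = cfg$min_coverage),
    rng_seed = cfg$rng_seed, max_iterations = cfg$max_iterations)
  expansion <- expand_seeds(seeds$seeds, corpus, store, ep,
                            method = cfg$method)
  write_expansion(expansion, file.path(cfg$out_dir, "2_expansion"),
                  params = ep)
  say(sprintf("  %d accessions after %d round(s)", nrow(expansion$hits),
              nrow(expansion$iteration_log)))

  say("stage 3/3: dereplication and curation")
  db <- build_reference(expansion$hits,
                        out_dir = file.path(cfg$out_dir, "3_derep"),
                        name = cfg$db_name, na_mode = cfg$na_mode)
  say(sprintf("  %d database entries (%d discarded by NA-lineage filter)",
              nrow(db$entries), nrow(db$discarded_na)))
  write_provenance(file.path(cfg$out_dir, "provenance.json"), "run_pipeline",
                   params = unclass(cfg),
                   inputs = unlist(cfg[c("corpus", "acc2taxid", "nodes",
                                         "names")], use.names = FALSE))
  list(seeds = seeds, expansion = expansion, db = db, out_dir = cfg$out_dir)
}
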