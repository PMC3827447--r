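#' Pipeline configuration
#'
#' Nested configuration for the end-to-end run: synthetic-data (or input
#' directory) settings, the per-stage configurations, the substitution
#' model, and a single global seed that fans out to per-stage seeds.
#'
#' @param sim a [sim_config()] (ignored when `input_dir` is given).
#' @param curation a [curation_config()].
#' @param blocks a [block_config()].
#' @param mask a [mask_config()].
#' @param test a [test_config()].
#' @param model list with `name` (`"wag"`/`"poisson"`), `gamma_shape`,
#'   `n_categories`.
#' @param input_dir optional directory of pre-built per-locus FASTA
#'   alignments to ingest instead of simulating.
#' @param out_dir output directory (default `"diplophylo_run"`).
#' @param seed global integer seed.
#' @param do_asr,do_topotest run the ancestral-state and topology-test
#'   stages (they require the study taxon set; default TRUE).
#' @param sitelik_loci cap on the number of loci entering the site-
#'   likelihood stage (NULL = all).
#' @export
pipeline_config <- function(sim = sim_config(), curation = curation_config(),
                            blocks = block_config(), mask = mask_config(),
                            test = test_config(), model = list(),
                            input_dir = NULL, out_dir = "diplophylo_run",
                            seed = 1L, do_asr = TRUE, do_topotest = TRUE,
                            sitelik_loci = NULL) {
  model <- utils::modifyList(
    list(name = "wag", gamma_shape = 1, n_categories = 4L), model)
  structure(list(sim = sim, curation = curation, blocks = blocks,
                 mask = mask, test = test, model = model,
                 input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), do_asr = do_asr,
                 do_topotest = do_topotest, sitelik_loci = sitelik_loci),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; section
#' keys mirror the corresponding constructor arguments. Unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("sim", "curation", "blocks", "mask", "test", "model",
             "input_dir", "out_dir", "seed", "do_asr", "do_topotest",
             "sitelik_loci")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  build <- function(section, fn) {
    if (is.null(raw[[section]])) return(fn())
    args <- raw[[section]]
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop("unknown keys in section '", section, "': ",
           paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  pipeline_config(sim = build("sim", sim_config),
                  curation = build("curation", curation_config),
                  blocks = build("blocks", block_config),
                  mask = build("mask", mask_config),
                  test = build("test", test_config),
                  model = raw$model %||% list(),
                  input_dir = raw$input_dir,
                  out_dir = raw$out_dir %||% "diplophylo_run",
                  seed = raw$seed %||% 1L,
                  do_asr = raw$do_asr %||% TRUE,
                  do_topotest = raw$do_topotest %||% TRUE,
                  sitelik_loci = raw$sitelik_loci)
}

# documented seed-splitting rule: stage k of a run with global seed s uses
# (s * 101 + k) mod (2^31 - 1), so stages can be re-run in isolation
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 101 + k) %% (2^31 - 1))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> leading-ambiguity trimming -> locus
#' selection (representative sequences, missing-data ceiling) -> conserved-
#' block filtering -> uninformative-column cleanup -> consensus-divergence
#' filtering -> low-signal masking -> length/occupancy filtering ->
#' concatenation and matrix statistics -> parsimony ancestral states ->
#' site log-likelihoods -> topology tests. Artifacts are written under
#' `cfg$out_dir`; the returned (and written) manifest accounts for every
#' sequence: `sequences_in` always equals `sequences_kept` plus the sum of
#' per-stage removals.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `alignments`, `supermatrix`, `stats_pre`,
#'   `stats_post`, `reduction`, `asr`, `topotest`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  ## 1. simulate or ingest
  if (is.null(cfg$input_dir)) {
    sim <- cfg$sim
    sim$seed <- stage_seed(cfg$seed, 1L)
    alns <- simulate_ortholog_set(sim)
  } else {
    alns <- read_ortholog_set(cfg$input_dir)
  }
  if (!length(alns)) stop("stage simulate/ingest: no alignments")
  sequences_in <- sum(vapply(alns, function(a) nrow(a$mat), integer(1)))
  taxa_all <- sort(unique(unlist(lapply(alns, function(a) a$taxon))))
  log_stage("ingest: %d loci, %d sequences", length(alns), sequences_in)
  removed <- c(locus_selection = 0L, divergence = 0L,
               length_occupancy = 0L)

  ## 2. leading-ambiguity trimming (masking, no removals)
  alns <- lapply(alns, trim_leading_ambiguity,
                 window = cfg$curation$lead_window)

  ## 3. locus selection: one representative per taxon, missing ceiling
  alns <- lapply(alns, representative_per_taxon)
  n_after_rep <- sum(vapply(alns, function(a) nrow(a$mat), integer(1)))
  removed["locus_selection"] <- sequences_in - n_after_rep
  missing_pct <- vapply(alns, function(a)
    100 * mean(a$mat == "-" | a$mat == "?" | a$mat == "X"), numeric(1))
  drop <- missing_pct > cfg$curation$scafos_missing_max
  removed["locus_selection"] <- removed["locus_selection"] +
    sum(vapply(alns[drop], function(a) nrow(a$mat), integer(1)))
  alns <- alns[!drop]
  pre_matrix <- if (length(alns)) concatenate(unname(alns), taxa_all)
                else NULL
  stats_pre <- if (!is.null(pre_matrix)) matrix_stats(pre_matrix) else NULL

  ## 4./5. conserved blocks, then all-gap/singleton column cleanup
  alns <- lapply(alns, function(a) {
    if (nrow(a$mat) < 2L) return(a)
    drop_uninformative_columns(apply_mask(a, select_blocks(a, cfg$blocks)))
  })

  ## 6. consensus-divergence (paralog) filter
  alns <- lapply(alns, function(a) {
    if (nrow(a$mat) < 2L || ncol(a$mat) == 0L) return(a)
    out <- remove_divergent(a, cfg$curation$divergence_threshold)
    removed["divergence"] <<- removed["divergence"] +
      length(attr(out, "removed"))
    out
  })

  ## 7. low-signal masking
  mask_cfg <- cfg$mask
  alns <- lapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    if (nrow(a$mat) < 2L || ncol(a$mat) < mask_cfg$window) return(a)
    mc <- mask_cfg
    mc$seed <- stage_seed(cfg$seed, 2L) + i
    apply_mask(a, mask_low_signal(a, mc))
  })

  ## 8. length and occupancy filters
  n_before <- sum(vapply(alns, function(a) nrow(a$mat), integer(1)))
  lo <- apply_length_and_occupancy(alns, cfg$curation)
  alns <- lo$alignments
  sequences_kept <- sum(vapply(alns, function(a) nrow(a$mat), integer(1)))
  removed["length_occupancy"] <- n_before - sequences_kept
  log_stage("curation: %d loci, %d sequences kept", length(alns),
            sequences_kept)

  ## 9. concatenate and summarize
  if (!length(alns)) stop("stage length_occupancy: no loci survived")
  sm <- concatenate(unname(alns), taxa_all)
  stats_post <- matrix_stats(sm)
  reduction <- if (!is.null(stats_pre))
    inclusion_report(stats_pre, stats_post) else NULL
  write_supermatrix(sm, file.path(cfg$out_dir, "supermatrix.fasta"),
                    partition_path = file.path(cfg$out_dir,
                                               "partitions.txt"))

  ## 10. ancestral states on the reference topology
  asr <- NULL
  have_study_taxa <- all(STUDY_TAXA %in% sm$taxa)
  if (cfg$do_asr) {
    asr <- lapply(millipede_characters(), fitch,
                  tree = millipede_topology())
    for (nm in names(asr))
      utils::write.table(asr_table(asr[[nm]]),
                         file.path(cfg$out_dir, paste0("asr_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## 11./12. site log-likelihoods and topology tests
  topo <- NULL
  if (cfg$do_topotest && have_study_taxa) {
    sub <- sm
    if (!is.null(cfg$sitelik_loci) &&
        cfg$sitelik_loci < nrow(sm$partitions)) {
      keep <- seq_len(cfg$sitelik_loci)
      cols <- unlist(lapply(keep, function(i)
        sm$partitions$start[i]:sm$partitions$end[i]))
      sub <- structure(list(taxa = sm$taxa,
                            mat = sm$mat[, cols, drop = FALSE],
                            partitions = sm$partitions[keep, ]),
                       class = "supermatrix")
    }
    mdl <- rate_model(cfg$model$name, cfg$model$gamma_shape,
                      cfg$model$n_categories)
    trees <- list(bayesian = millipede_topology("bayesian"),
                  ml = millipede_topology("ml"))
    slm <- site_loglik_matrix(trees, sub, mdl, optimize = TRUE,
                              max_rounds = 5L)
    tc <- cfg$test
    tc$seed <- stage_seed(cfg$seed, 3L)
    topo <- run_battery(slm, tc)
    write_topotest(topo, file.path(cfg$out_dir, "topotest.tsv"))
  }

  manifest <- data.frame(
    stage = c("input", "removed_locus_selection", "removed_divergence",
              "removed_length_occupancy", "kept"),
    sequences = c(sequences_in, unname(removed), sequences_kept))
  stopifnot(sequences_in == sequences_kept + sum(removed))
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats_tab <- data.frame(
    quantity = c("n_loci", "n_columns", "n_gap", "n_missing", "pct_gap",
                 "pct_missing"),
    pre = if (!is.null(stats_pre))
      c(stats_pre$n_loci, stats_pre$n_columns, stats_pre$n_gap,
        stats_pre$n_missing, stats_pre$pct_gap, stats_pre$pct_missing)
      else NA,
    post = c(stats_post$n_loci, stats_post$n_columns, stats_post$n_gap,
             stats_post$n_missing, stats_post$pct_gap,
             stats_post$pct_missing))
  utils::write.table(stats_tab, file.path(cfg$out_dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(alignments = alns, supermatrix = sm, stats_pre = stats_pre,
       stats_post = stats_post, reduction = reduction, asr = asr,
       topotest = topo, manifest = manifest)
}
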