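# End-to-end orchestration: simulate -> preprocess -> expression ->
# splicing -> enrichment, with a single configuration, deterministic
# outputs under a fixed seed, and a machine-readable run report.

#' Build and validate a pipeline configuration
#'
#' @param simulation list of [sim_config()] arguments for the synthetic
#'   experiment (the pipeline's input stage).
#' @param contrasts list of 2-vectors `c(a, b)` (tested as `a` minus `b`),
#'   or strings `"a:b"`. Default: all pairwise contrasts of the simulated
#'   conditions, later condition first.
#' @param fold_threshold expression fold-change cutoff (linear, > 1).
#' @param alpha_expression BH-adjusted significance cutoff for expression.
#' @param alpha_splicing per-test raw cutoff for the dual splicing tests.
#' @param z_threshold,min_replicates presence-call parameters
#'   (see [detect_present()]).
#' @param min_genes minimum in-universe gene-set size for enrichment.
#' @param floor_epsilon background-correction floor (linear units).
#' @param gene_sets_gmt optional GMT path for over-representation analysis.
#' @param footprint_gmt optional GMT path of splicing-factor target sets
#'   for the footprint overlap test.
#' @param seed master seed for the simulation stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = list(),
                            contrasts = NULL,
                            fold_threshold = 2.0,
                            alpha_expression = 0.05,
                            alpha_splicing = 0.01,
                            z_threshold = 2,
                            min_replicates = 3L,
                            min_genes = 10L,
                            floor_epsilon = 1,
                            gene_sets_gmt = NULL,
                            footprint_gmt = NULL,
                            seed = 1L) {
  simulation$seed <- simulation$seed %||% seed
  sim_cfg <- do.call(sim_config, simulation)
  parse_contrast <- function(x) {
    if (is.character(x) && length(x) == 1L && grepl(":", x, fixed = TRUE))
      x <- strsplit(x, ":", fixed = TRUE)[[1L]]
    if (length(x) != 2L) stop_config("contrast must name exactly two conditions")
    as.character(x)
  }
  if (is.null(contrasts)) {
    conds <- sim_cfg$conditions
    contrasts <- list()
    for (i in seq_along(conds)) for (j in seq_len(i - 1L))
      contrasts[[length(contrasts) + 1L]] <- c(conds[i], conds[j])
  } else {
    contrasts <- lapply(contrasts, parse_contrast)
  }
  for (ct in contrasts)
    if (!all(ct %in% sim_cfg$conditions))
      stop_config("contrast condition(s) not simulated: %s",
                  paste(setdiff(ct, sim_cfg$conditions), collapse = ", "))
  if (fold_threshold <= 1) stop_config("fold_threshold must be > 1")
  for (a in c("alpha_expression", "alpha_splicing")) {
    v <- get(a)
    if (v <= 0 || v >= 1) stop_config("%s must lie in (0, 1)", a)
  }
  for (path in c(gene_sets_gmt, footprint_gmt))
    if (!is.null(path) && !file.exists(path))
      stop_config("file not found: %s", path)
  structure(list(simulation = sim_cfg, contrasts = contrasts,
                 fold_threshold = fold_threshold,
                 alpha_expression = alpha_expression,
                 alpha_splicing = alpha_splicing,
                 z_threshold = z_threshold,
                 min_replicates = as.integer(min_replicates),
                 min_genes = as.integer(min_genes),
                 floor_epsilon = floor_epsilon,
                 gene_sets_gmt = gene_sets_gmt,
                 footprint_gmt = footprint_gmt,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose top-level fields are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$contrasts) && is.matrix(cfg$contrasts))
    cfg$contrasts <- asplit(cfg$contrasts, 1L)
  if (!is.null(cfg$contrasts) && is.character(cfg$contrasts))
    cfg$contrasts <- as.list(cfg$contrasts)
  if (!is.null(cfg$simulation)) cfg$simulation <- as.list(cfg$simulation)
  do.call(pipeline_config, cfg)
}

contrast_tag <- function(ct) paste(ct, collapse = "_vs_")

#' Run the complete analysis pipeline
#'
#' Simulates an experiment, preprocesses it (background correction,
#' cross-hybridizer removal, probe-effect correction, presence calls),
#' computes per-contrast differential expression and dual-test splicing
#' calls, optionally runs gene-set enrichment and footprint overlap, writes
#' every stage output as TSV/JSON under `out_dir`, and returns a run
#' report. Identical configuration and seed produce byte-identical output
#' files.
#'
#' @param config a [pipeline_config()] (or list / JSON path coercible to
#'   one).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress stage progress messages.
#' @return A `run_report` list with per-stage row counts and per-contrast
#'   DE / AS counts; also written (minus the volatile timestamp) to
#'   `run_report.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
  }
  stage <- "simulate"
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("exonsplice")),
                 stages = list(), contrasts = list())
  result <- tryCatch({
    ## simulate
    sim <- simulate_experiment(config$simulation)
    write_sim_experiment(sim, out_dir)
    report$stages$simulate <- list(
      n_probes = nrow(sim$intensities$values),
      n_samples = ncol(sim$intensities$values),
      n_transcripts = nrow(sim$truth$abundance),
      n_planted_de = nrow(sim$truth$de_events),
      n_planted_as = nrow(sim$truth$as_events))
    say(stage, "%d probes x %d samples", nrow(sim$intensities$values),
        ncol(sim$intensities$values))

    ## preprocess
    stage <- "preprocess"
    corrected <- background_correct(sim$intensities, sim$annotation,
                                    floor_epsilon = config$floor_epsilon)
    dropped <- drop_cross_hyb(corrected, sim$annotation)
    effects <- estimate_probe_effects(dropped$matrix, sim$annotation)
    corrected <- apply_probe_effects(dropped$matrix, effects)
    presence <- detect_present(sim$intensities, sim$annotation, sim$design,
                               z_threshold = config$z_threshold,
                               min_replicates = config$min_replicates)
    write_intensity_tsv(corrected, file.path(out_dir, "corrected.tsv"))
    write_tsv(as.data.frame(effects), file.path(out_dir, "probe_effects.tsv"))
    write_tsv(data.frame(transcript_id = rownames(presence$present),
                         presence$present, check.names = FALSE),
              file.path(out_dir, "presence.tsv"))
    report$stages$preprocess <- list(
      n_cross_hyb_dropped = length(dropped$report$dropped_probes),
      n_empty_probesets = length(dropped$report$empty_probesets),
      n_present_any = sum(rowSums(presence$present) > 0))
    say(stage, "%d cross-hyb probes dropped; %d transcripts present somewhere",
        length(dropped$report$dropped_probes),
        sum(rowSums(presence$present) > 0))

    ## expression
    stage <- "expression"
    expr <- summarize_transcripts(corrected, sim$annotation)
    write_tsv(data.frame(transcript_id = rownames(expr), unclass(expr),
                         check.names = FALSE),
              file.path(out_dir, "expression.tsv"))
    report$stages$expression <- list(n_transcripts = nrow(expr))

    gene_of_tx <- unique(genomic_probes(sim$annotation)[, c("transcript_id",
                                                            "gene_id")])
    tx2gene <- stats::setNames(gene_of_tx$gene_id, gene_of_tx$transcript_id)

    ## per-contrast analyses
    for (ct in config$contrasts) {
      tag <- contrast_tag(ct)
      stage <- paste0("expression:", tag)
      de <- moderated_t_test(expr, sim$design, ct)
      de <- fold_change_filter(de, threshold_fold = config$fold_threshold,
                               alpha = config$alpha_expression)
      write_tsv(as.data.frame(de), file.path(out_dir, paste0("de_", tag, ".tsv")))
      de_hits <- attr(de, "significant")

      stage <- paste0("splicing:", tag)
      present_tx <- present_transcripts(presence, ct)
      si <- splicing_index(corrected, expr, sim$annotation,
                           transcripts = present_tx)
      midas <- midas_test(si, sim$design, conditions = ct)
      mads <- mads_test(si, sim$design, condition_pair = ct)
      calls <- consensus_splicing_calls(midas, mads,
                                        alpha = config$alpha_splicing,
                                        annotation = sim$annotation)
      mean_si <- function(cond) rowMeans(
        si$probeset_si[calls$probesets$probeset_id,
                       design_samples(sim$design, cond), drop = FALSE])
      as_table <- cbind(calls$probesets[, c("probeset_id", "transcript_id",
                                            "gene_id")],
                        stats::setNames(data.frame(mean_si(ct[1L]), mean_si(ct[2L])),
                                        paste0("mean_si_", ct)),
                        calls$probesets[, c("p_midas", "p_mads", "adj_p_midas",
                                            "adj_p_mads", "called")])
      write_tsv(as_table, file.path(out_dir, paste0("splicing_", tag, ".tsv")))

      as_genes <- called_spliced(calls, "gene")
      de_genes <- unique(unname(tx2gene[de_hits]))
      report$contrasts[[tag]] <- list(
        n_tested_transcripts = nrow(de),
        n_de_transcripts = length(de_hits),
        n_de_genes = length(de_genes),
        n_tested_probesets = nrow(calls$probesets),
        n_as_probesets = calls$n_called_probesets,
        n_as_transcripts = calls$n_called_transcripts,
        n_as_genes = length(as_genes),
        as_to_de_gene_ratio = if (length(de_genes))
          length(as_genes) / length(de_genes) else NA)
      say(stage, "%d DE transcripts, %d AS transcripts",
          length(de_hits), calls$n_called_transcripts)

      ## enrichment (optional)
      if (!is.null(config$gene_sets_gmt) || !is.null(config$footprint_gmt)) {
        stage <- paste0("enrichment:", tag)
        present_genes <- unique(unname(
          tx2gene[rownames(presence$present)[
            rowSums(presence$present[, ct, drop = FALSE]) > 0]]))
        say(stage, "universe: %d genes present in either condition",
            length(present_genes))
        if (!is.null(config$gene_sets_gmt) && length(as_genes)) {
          sets <- read_gmt(config$gene_sets_gmt)
          enr <- annotation_enrichment(intersect(as_genes, present_genes),
                                       sets, present_genes,
                                       min_genes = config$min_genes)
          write_tsv(as.data.frame(enr),
                    file.path(out_dir, paste0("enrichment_as_", tag, ".tsv")))
          report$contrasts[[tag]]$n_enriched_sets <- sum(enr$adj_p < 0.05)
        }
        if (!is.null(config$footprint_gmt) && length(as_genes)) {
          targets <- read_gmt(config$footprint_gmt)
          # skip (with a note) target sets with no member in this universe
          # rather than aborting the whole run
          in_universe <- vapply(names(targets), function(nm)
            length(intersect(set_members(targets, nm), present_genes)) > 0,
            logical(1L))
          if (any(!in_universe))
            say(stage, "footprint: %d target set(s) have no gene in the universe; skipped",
                sum(!in_universe))
          targets <- targets[in_universe]
          fp <- lapply(names(targets), function(nm) {
            r <- footprint_overlap_test(intersect(as_genes, present_genes),
                                        set_members(targets, nm),
                                        present_genes)
            data.frame(target_set = nm, N = r$N, K = r$K, n = r$n, k = r$k,
                       expected = r$expected, p = r$p,
                       overlap_genes = paste(sort(r$overlap_genes),
                                             collapse = ","),
                       stringsAsFactors = FALSE)
          })
          if (length(fp))
            write_tsv(do.call(rbind, fp),
                      file.path(out_dir, paste0("footprint_", tag, ".tsv")))
        }
      }
    }

    ## presence Venn across conditions
    stage <- "venn"
    cond_sets <- lapply(colnames(presence$present), function(cond)
      rownames(presence$present)[presence$present[, cond]])
    names(cond_sets) <- colnames(presence$present)
    if (all(lengths(cond_sets) == 0L)) {
      report$stages$venn <- list(note = "no transcript present anywhere")
    } else {
      vp <- venn_partition(cond_sets)
      write_tsv(data.frame(region = names(vp$counts),
                           count = as.integer(vp$counts)),
                file.path(out_dir, "venn_presence.tsv"))
      report$stages$venn <- as.list(vp$counts)
    }
    report
  }, exonsplice_error = function(e) {
    writeLines(sprintf("incomplete: failed at stage '%s'", stage),
               file.path(out_dir, "INCOMPLETE"))
    stop_with(class(e)[1L], "pipeline failed at stage '%s': %s",
              stage, conditionMessage(e))
  })

  ## provenance: resolved config and report (both deterministic)
  cfg_out <- unclass(config)
  cfg_out$simulation <- unclass(cfg_out$simulation)
  jsonlite::write_json(cfg_out, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  jsonlite::write_json(result, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$timestamp <- format(Sys.time(), tz = "UTC")
  class(result) <- "run_report"
  invisible(result)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d)\n", x$seed))
  for (tag in names(x$contrasts)) {
    ct <- x$contrasts[[tag]]
    cat(sprintf("  %s: %d DE transcripts, %d AS transcripts (%d probesets)\n",
                tag, ct$n_de_transcripts, ct$n_as_transcripts,
                ct$n_as_probesets))
  }
  invisible(x)
}
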