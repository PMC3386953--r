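# Shared fixtures: everything is generated in code at test time.

toy_intensity <- function(values = matrix(c(100, 101, 102, 103, 104, 105),
                                          nrow = 3, byrow = TRUE),
                          probes = c("P1", "P2", "P3"),
                          samples = c("s1", "s2"),
                          background_corrected = FALSE) {
  dimnames(values) <- list(probes, samples)
  intensity_matrix(values, background_corrected = background_corrected)
}

# two transcripts (2 + 1 probesets), plus optional background probes
toy_annotation_df <- function(n_background = 0L) {
  g <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    probeset_id = c("PS1", "PS1", "PS2", "PS2", "PS3", "PS3"),
    transcript_id = c("T1", "T1", "T1", "T1", "T2", "T2"),
    gene_id = c("G1", "G1", "G1", "G1", "G2", "G2"),
    exon_index = c(1L, 1L, 2L, 2L, 1L, 1L),
    cross_hyb_flag = FALSE,
    probe_kind = "genomic",
    stringsAsFactors = FALSE)
  if (n_background > 0L) {
    b <- data.frame(
      probe_id = sprintf("BG%d", seq_len(n_background)),
      probeset_id = "", transcript_id = "", gene_id = "",
      exon_index = NA_integer_, cross_hyb_flag = FALSE,
      probe_kind = "background", stringsAsFactors = FALSE)
    g <- rbind(g, b)
  }
  g
}

toy_design <- function(conditions = c("A", "B"), replicates = 3L) {
  sample_design(data.frame(
    sample_id = sprintf("s_%s_r%d", rep(conditions, each = replicates),
                        rep(seq_len(replicates), length(conditions))),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions))))
}

small_sim_config <- function(...) {
  defaults <- list(n_transcripts = 60, exons_per_transcript = c(3, 5),
                   probes_per_probeset = c(3, 4), n_background_probes = 100,
                   seed = 101)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# standard preprocessing chain on a simulated experiment
preprocess_chain <- function(sim, floor_epsilon = 1) {
  corrected <- background_correct(sim$intensities, sim$annotation,
                                  floor_epsilon = floor_epsilon)
  dropped <- drop_cross_hyb(corrected, sim$annotation)
  # cross-hyb removal can leave single-probe probesets; that warning is
  # expected here and tested explicitly elsewhere
  effects <- withCallingHandlers(
    estimate_probe_effects(dropped$matrix, sim$annotation),
    warning = function(w) {
      if (grepl("single-probe", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  corrected <- apply_probe_effects(dropped$matrix, effects)
  presence <- detect_present(sim$intensities, sim$annotation, sim$design)
  expr <- summarize_transcripts(corrected, sim$annotation)
  list(corrected = corrected, effects = effects, presence = presence,
       expr = expr, cross_hyb_report = dropped$report)
}

# wrap a bare probeset-SI matrix so the splicing tests can consume it
# (one probe per probeset, so probe- and probeset-level views coincide)
fake_si <- function(probeset_si) {
  ids <- rownames(probeset_si)
  structure(list(probe_si = probeset_si, probeset_si = probeset_si,
                 probe_map = data.frame(probe_id = ids, probeset_id = ids,
                                        transcript_id = ids, gene_id = ids,
                                        stringsAsFactors = FALSE),
                 probeset_map = NULL),
            class = "splicing_index_matrix")
}
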