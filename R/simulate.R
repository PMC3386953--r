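# Synthetic exon-array experiment generator.
#
# Generative model (linear fluorescence units):
#   I(p, s) = bg(p, s) + PSI(ps(p), cond(s)) *
#             2^( a(tx(p), cond(s)) + affinity(p) + eps(p, s) ) + xh(p)
# with bg ~ Normal(background_mean, background_sd) censored at 0,
# eps ~ Normal(0, noise_sd), PSI = 1 for constitutive probesets, and a
# condition-independent linear offset xh for cross-hybridizing probes.
# Background probes carry only the bg term. Splicing is modelled as
# probeset-level inclusion (PSI) multiplying the transcript's linear
# abundance: because the splicing index is expression-normalized, only the
# relative probeset signal needs to change for a splicing event to exist.

#' Simulation configuration for synthetic exon-array experiments
#'
#' Defaults emulate a small activation-course design: 3 conditions
#' (`naive`, `TCR`, `TCR_CD28`) x 4 replicates, probesets of 3-4 probes
#' nested in multi-exon transcripts, log-normal probe affinities,
#' multiplicative log-normal noise and additive linear background.
#' Desk-scale transcript counts are the default; array scale is a
#' configuration choice.
#'
#' @param n_transcripts number of transcripts (one gene each).
#' @param exons_per_transcript integer range `c(lo, hi)`; one probeset per
#'   exon.
#' @param probes_per_probeset integer range `c(lo, hi)`.
#' @param conditions character vector of condition labels.
#' @param replicates replicates per condition (>= 2).
#' @param baseline_log2_mean,baseline_log2_sd per-transcript baseline
#'   log2 abundance distribution.
#' @param probe_affinity_sd sd of per-probe affinity (log2 units).
#' @param noise_sd sd of multiplicative noise (log2 units).
#' @param background_mean,background_sd additive background (linear units).
#' @param n_background_probes number of pure-background probes.
#' @param frac_de fraction of transcripts with a planted expression change.
#' @param de_log2fc magnitude of the planted log2 fold change (sign is
#'   randomized per transcript).
#' @param frac_as fraction of transcripts with one planted splicing event.
#' @param delta_inclusion PSI drop in the affected condition, in (0, 1]:
#'   the affected probeset has PSI `1 - delta_inclusion` there and 1
#'   elsewhere.
#' @param affected_condition condition receiving the planted changes;
#'   default the last condition label.
#' @param frac_cross_hyb fraction of genomic probes flagged cross-hybridizing.
#' @param cross_hyb_offset condition-independent additive offset (linear
#'   units) for cross-hybridizing probes.
#' @param seed master seed; split into a structure seed (which transcripts /
#'   probesets carry events, affinities, flags) and a noise seed (background
#'   and eps draws), so two runs sharing `structure_seed` plant identical
#'   events under different noise.
#' @param structure_seed,noise_seed optional explicit sub-seeds.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 200,
                       exons_per_transcript = c(4L, 8L),
                       probes_per_probeset = c(3L, 4L),
                       conditions = c("naive", "TCR", "TCR_CD28"),
                       replicates = 4L,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       probe_affinity_sd = 0.5,
                       noise_sd = 0.25,
                       background_mean = 50,
                       background_sd = 10,
                       n_background_probes = 200L,
                       frac_de = 0.1,
                       de_log2fc = 2,
                       frac_as = 0.1,
                       delta_inclusion = 0.4,
                       affected_condition = NULL,
                       frac_cross_hyb = 0.02,
                       cross_hyb_offset = 200,
                       seed = 1L,
                       structure_seed = NULL,
                       noise_seed = NULL) {
  cfg <- as.list(environment())
  cfg$conditions <- as.character(conditions)
  cfg$affected_condition <- affected_condition %||% cfg$conditions[length(cfg$conditions)]
  if (cfg$n_transcripts < 1L) stop_config("n_transcripts must be >= 1")
  if (length(cfg$conditions) < 2L || anyDuplicated(cfg$conditions))
    stop_config("need >= 2 distinct condition labels")
  if (!cfg$affected_condition %in% cfg$conditions)
    stop_config("affected_condition '%s' not among conditions", cfg$affected_condition)
  if (cfg$replicates < 2L) stop_config("replicates must be >= 2")
  for (fr in c("frac_de", "frac_as", "frac_cross_hyb"))
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1) stop_config("%s must lie in [0, 1]", fr)
  if (cfg$delta_inclusion <= 0 || cfg$delta_inclusion > 1)
    stop_config("delta_inclusion must lie in (0, 1]")
  for (sd in c("baseline_log2_sd", "probe_affinity_sd", "noise_sd", "background_sd"))
    if (cfg[[sd]] < 0) stop_config("%s must be >= 0", sd)
  if (cfg$background_mean < 0) stop_config("background_mean must be >= 0")
  rng_ok <- function(r) length(r) %in% 1:2 && all(r >= 1) && (length(r) == 1 || r[1] <= r[2])
  if (!rng_ok(cfg$exons_per_transcript) || !rng_ok(cfg$probes_per_probeset))
    stop_config("exons_per_transcript / probes_per_probeset must be valid integer ranges")
  if (is.null(cfg$structure_seed) || is.null(cfg$noise_seed)) {
    set.seed(as.integer(seed))
    sub <- sample.int(.Machine$integer.max - 1L, 2L)
    cfg$structure_seed <- cfg$structure_seed %||% sub[1L]
    cfg$noise_seed <- cfg$noise_seed %||% sub[2L]
  }
  structure(cfg, class = "sim_config")
}

# integer draw from an inclusive range that may be degenerate
rint <- function(range, n) {
  if (length(range) == 1L || range[1] == range[2])
    rep(as.integer(range[1]), n)
  else
    sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a complete exon-array experiment with ground truth
#'
#' Generates intensities, annotation, design and the planted truth under the
#' model documented in this file. Identical configuration (hence identical
#' structure and noise seeds) gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_experiment` with elements
#'   `intensities` ([intensity_matrix]), `annotation`
#'   ([probe_annotation]), `design` ([sample_design]) and `truth`, a
#'   `ground_truth` list holding the planted abundance matrix, expression
#'   events, splicing events (PSI per condition), presence flags, probe
#'   affinities and cross-hybridizer ids.
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config

  ## ---- structure phase ----
  set.seed(cfg$structure_seed)
  n_t <- as.integer(cfg$n_transcripts)
  tx_ids <- sprintf("T%05d", seq_len(n_t))
  gene_ids <- sprintf("G%05d", seq_len(n_t))
  n_exons <- rint(cfg$exons_per_transcript, n_t)

  ps_tx_idx <- rep.int(seq_len(n_t), n_exons)
  ps_exon <- unlist(lapply(n_exons, seq_len), use.names = FALSE)
  ps_ids <- sprintf("%s_PS%02d", tx_ids[ps_tx_idx], ps_exon)
  n_ps <- length(ps_ids)

  n_probes_per_ps <- rint(cfg$probes_per_probeset, n_ps)
  probe_ps_idx <- rep.int(seq_len(n_ps), n_probes_per_ps)
  probe_num <- unlist(lapply(n_probes_per_ps, seq_len), use.names = FALSE)
  probe_ids_g <- sprintf("%s_P%d", ps_ids[probe_ps_idx], probe_num)
  n_g <- length(probe_ids_g)
  probe_tx_idx <- ps_tx_idx[probe_ps_idx]

  conds <- cfg$conditions
  n_c <- length(conds)
  n_s <- n_c * cfg$replicates
  design <- sample_design(data.frame(
    sample_id = sprintf("s_%s_r%d", rep(conds, each = cfg$replicates),
                        rep(seq_len(cfg$replicates), n_c)),
    condition = rep(conds, each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), n_c)))

  # abundance: baseline + planted expression changes in the affected condition
  baseline <- stats::rnorm(n_t, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  abundance <- matrix(baseline, n_t, n_c, dimnames = list(tx_ids, conds))
  n_de <- round(cfg$frac_de * n_t)
  if (n_de > n_t) stop_config("config requests more DE transcripts than transcripts")
  de_idx <- if (n_de > 0) sort(sample.int(n_t, n_de)) else integer(0)
  de_sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  abundance[de_idx, cfg$affected_condition] <-
    abundance[de_idx, cfg$affected_condition] + de_sign * cfg$de_log2fc
  de_events <- data.frame(transcript_id = tx_ids[de_idx],
                          condition = rep(cfg$affected_condition, n_de),
                          log2fc = de_sign * cfg$de_log2fc,
                          stringsAsFactors = FALSE)

  # operational presence truth: expected raw log2 signal clears the expected
  # detection threshold (background mean + 2 sd on the log2 scale, delta
  # method for the background moments)
  if (cfg$background_mean > 0) {
    mu_b <- log2(cfg$background_mean)
    sd_b <- cfg$background_sd / (cfg$background_mean * log(2))
    presence <- log2(cfg$background_mean + 2^abundance) > mu_b + 2 * sd_b
  } else {
    presence <- abundance > -Inf
  }
  dimnames(presence) <- dimnames(abundance)

  # splicing events: one probeset per chosen transcript; transcripts must be
  # present in every condition and have >= 2 probesets so the splicing index
  # has within-transcript contrast
  n_as <- round(cfg$frac_as * n_t)
  if (n_as > n_t) stop_config("config requests more AS transcripts than transcripts")
  psi <- matrix(1, n_ps, n_c, dimnames = list(ps_ids, conds))
  as_events <- data.frame(probeset_id = character(0), transcript_id = character(0),
                          condition = character(0), psi_ref = numeric(0),
                          psi_alt = numeric(0), stringsAsFactors = FALSE)
  if (n_as > 0) {
    eligible <- which(rowSums(presence) == n_c & n_exons >= 2L)
    if (length(eligible) < n_as)
      stop_config("only %d transcript(s) eligible for planted splicing, %d requested",
                  length(eligible), n_as)
    as_tx <- sort(sample(eligible, n_as))
    as_ps_idx <- vapply(as_tx, function(t) {
      cand <- which(ps_tx_idx == t)
      cand[sample.int(length(cand), 1L)]
    }, 1L)
    psi_alt <- 1 - cfg$delta_inclusion
    psi[as_ps_idx, cfg$affected_condition] <- psi_alt
    as_events <- data.frame(probeset_id = ps_ids[as_ps_idx],
                            transcript_id = tx_ids[as_tx],
                            condition = rep(cfg$affected_condition, n_as),
                            psi_ref = 1, psi_alt = psi_alt,
                            stringsAsFactors = FALSE)
  }

  affinity <- stats::rnorm(n_g, 0, cfg$probe_affinity_sd)
  n_xh <- round(cfg$frac_cross_hyb * n_g)
  xh_idx <- if (n_xh > 0) sort(sample.int(n_g, n_xh)) else integer(0)
  is_xh <- seq_len(n_g) %in% xh_idx

  n_bg <- as.integer(cfg$n_background_probes)
  bg_ids <- if (n_bg > 0) sprintf("BG%05d", seq_len(n_bg)) else character(0)

  annotation <- probe_annotation(data.frame(
    probe_id = c(probe_ids_g, bg_ids),
    probeset_id = c(ps_ids[probe_ps_idx], rep("", n_bg)),
    transcript_id = c(tx_ids[probe_tx_idx], rep("", n_bg)),
    gene_id = c(gene_ids[probe_tx_idx], rep("", n_bg)),
    exon_index = c(ps_exon[probe_ps_idx], rep(NA_integer_, n_bg)),
    cross_hyb_flag = c(is_xh, rep(FALSE, n_bg)),
    probe_kind = c(rep("genomic", n_g), rep("background", n_bg)),
    stringsAsFactors = FALSE))

  ## ---- noise phase ----
  set.seed(cfg$noise_seed)
  cond_of_sample <- match(design$condition, conds)
  bg_draw <- matrix(stats::rnorm((n_g + n_bg) * n_s, cfg$background_mean,
                                 cfg$background_sd), n_g + n_bg, n_s)
  bg_draw <- pmax(bg_draw, 0)
  eps <- matrix(stats::rnorm(n_g * n_s, 0, cfg$noise_sd), n_g, n_s)

  a_ps <- abundance[probe_tx_idx, cond_of_sample, drop = FALSE]
  psi_ps <- psi[probe_ps_idx, cond_of_sample, drop = FALSE]
  signal <- psi_ps * 2^(a_ps + affinity + eps)
  if (n_xh > 0) signal[xh_idx, ] <- signal[xh_idx, ] + cfg$cross_hyb_offset
  values <- rbind(bg_draw[seq_len(n_g), , drop = FALSE] + signal,
                  bg_draw[n_g + seq_len(n_bg), , drop = FALSE])
  dimnames(values) <- list(c(probe_ids_g, bg_ids), design$sample_id)

  truth <- structure(list(
    abundance = abundance,
    de_events = de_events,
    as_events = as_events,
    psi = psi,
    presence = presence,
    affinity = data.frame(probe_id = probe_ids_g, affinity = affinity,
                          stringsAsFactors = FALSE),
    cross_hyb = probe_ids_g[xh_idx],
    affected_condition = cfg$affected_condition
  ), class = "ground_truth")

  structure(list(intensities = intensity_matrix(values),
                 annotation = annotation,
                 design = design,
                 truth = truth,
                 config = cfg),
            class = "sim_experiment")
}

#' Simulate a null experiment (no planted events)
#'
#' Identical to [simulate_experiment()] with `frac_de` and `frac_as` forced
#' to zero; used for type-I error calibration of the downstream tests.
#'
#' @param config a [sim_config()].
#' @return A `sim_experiment`; `truth$de_events` and `truth$as_events` are
#'   empty.
#' @export
simulate_null <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  config$frac_de <- 0
  config$frac_as <- 0
  simulate_experiment(config)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(paste0("sim_experiment: %d probes x %d samples; %d transcripts; ",
                     "%d planted DE, %d planted AS, %d cross-hyb probes\n"),
              nrow(x$intensities$values), ncol(x$intensities$values),
              nrow(x$truth$abundance), nrow(x$truth$de_events),
              nrow(x$truth$as_events), length(x$truth$cross_hyb)))
  invisible(x)
}

#' Write all simulation artifacts as plain-text tables
#'
#' Emits `intensities.tsv`, `annotation.tsv`, `design.tsv` and the ground
#' truth tables (`truth_*.tsv`) into `dir`.
#'
#' @param experiment a `sim_experiment`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_tsv(experiment$intensities, file.path(dir, "intensities.tsv"))
  write_probe_annotation(experiment$annotation, file.path(dir, "annotation.tsv"))
  write_sample_design(experiment$design, file.path(dir, "design.tsv"))
  tr <- experiment$truth
  write_tsv(data.frame(transcript_id = rownames(tr$abundance),
                       tr$abundance, check.names = FALSE),
            file.path(dir, "truth_abundance.tsv"))
  write_tsv(tr$de_events, file.path(dir, "truth_de_events.tsv"))
  write_tsv(tr$as_events, file.path(dir, "truth_as_events.tsv"))
  write_tsv(data.frame(transcript_id = rownames(tr$presence),
                       tr$presence, check.names = FALSE),
            file.path(dir, "truth_presence.tsv"))
  write_tsv(tr$affinity, file.path(dir, "truth_affinity.tsv"))
  write_tsv(data.frame(probe_id = tr$cross_hyb), file.path(dir, "truth_cross_hyb.tsv"))
  invisible(dir)
}
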