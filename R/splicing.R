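# Differential splicing: per-probe splicing index, two independent
# probeset-level tests (one-way ANOVA in the MIDAS style; empirical-Bayes
# moderated t in the MADS style) and the dual-test consensus rule that a
# probeset is alternatively spliced only when BOTH tests reject at the
# chosen alpha (raw p-values; the conjunction is the error control).

#' Compute the splicing index
#'
#' The splicing index of a probe in a sample is the ratio of the probe's
#' background-corrected intensity to its transcript's average expression —
#' equivalently, on the log2 scale used here,
#' `SI(p, s) = log2 I(p, s) - E(t(p), s)`. Transcription-level changes
#' cancel by construction: scaling all probes of a transcript in a sample
#' changes no SI value. The probeset-level SI is the unweighted mean of its
#' probes' SI.
#'
#' @param m the corrected [intensity_matrix] the expression matrix was
#'   computed from (background-corrected, cross-hybridizers dropped, probe
#'   effects applied).
#' @param expr the matching `expression_matrix` from
#'   [summarize_transcripts()].
#' @param annotation a [probe_annotation].
#' @param transcripts optional transcript subset (e.g. those present in
#'   both compared conditions); probes of other transcripts are excluded.
#'   Probes whose transcript has no expression value at all raise an error.
#' @return A `splicing_index_matrix` list: `probe_si` and `probeset_si`
#'   (log2 matrices), plus `probe_map` / `probeset_map` linking rows to
#'   transcripts and genes.
#' @export
splicing_index <- function(m, expr, annotation, transcripts = NULL) {
  g <- genomic_probes(annotation)
  g <- g[g$probe_id %in% probe_ids(m), , drop = FALSE]
  if (!is.null(transcripts))
    g <- g[g$transcript_id %in% transcripts, , drop = FALSE]
  if (!nrow(g)) stop_data("no probes left for splicing-index computation")
  missing_tx <- setdiff(unique(g$transcript_id), rownames(expr))
  if (length(missing_tx))
    stop_data("transcript(s) without expression values: %s",
              paste(utils::head(missing_tx, 5L), collapse = ", "))
  samples <- sample_ids(m)
  probe_si <- log2(m$values[g$probe_id, samples, drop = FALSE]) -
    unclass(expr)[g$transcript_id, samples, drop = FALSE]
  ps_counts <- as.vector(table(g$probeset_id)[sort(unique(g$probeset_id))])
  probeset_si <- rowsum(probe_si, g$probeset_id) / ps_counts
  ps_map <- unique(g[, c("probeset_id", "transcript_id", "gene_id")])
  ps_map <- ps_map[match(rownames(probeset_si), ps_map$probeset_id), ]
  rownames(ps_map) <- NULL
  structure(list(probe_si = probe_si,
                 probeset_si = probeset_si,
                 probe_map = g[, c("probe_id", "probeset_id", "transcript_id",
                                   "gene_id")],
                 probeset_map = ps_map),
            class = "splicing_index_matrix")
}

#' @export
print.splicing_index_matrix <- function(x, ...) {
  cat(sprintf("splicing_index_matrix: %d probes / %d probesets x %d samples\n",
              nrow(x$probe_si), nrow(x$probeset_si), ncol(x$probe_si)))
  invisible(x)
}

#' MIDAS-style differential splicing test (one-way ANOVA)
#'
#' Per probeset, a one-way ANOVA of the per-sample probeset-level splicing
#' index grouped by condition; the p-value is the upper tail of the
#' F(k-1, N-k) reference. In the two-condition case this is algebraically
#' identical to the equal-variance two-sample t-test (F = t^2).
#'
#' @param si a `splicing_index_matrix`.
#' @param design a [sample_design].
#' @param conditions >= 2 condition labels to compare (default: all in the
#'   design).
#' @return A data.frame `probeset_id`, `F`, `p`, `degenerate` (TRUE when
#'   both between- and within-group variation vanish; such probesets get
#'   p = 1).
#' @export
midas_test <- function(si, design, conditions = unique(design$condition)) {
  if (length(conditions) < 2L)
    stop_config("midas_test needs >= 2 conditions")
  design <- design[design$condition %in% conditions, , drop = FALSE]
  reps <- table(design$condition)
  if (any(reps < 2L))
    stop_data("condition '%s' has fewer than 2 replicates",
              names(reps)[reps < 2L][1L])
  y <- si$probeset_si[, design$sample_id, drop = FALSE]
  groups <- design$condition
  k <- length(conditions)
  n <- ncol(y)
  grand <- rowMeans(y)
  ssb <- 0
  ssw <- 0
  for (cond in conditions) {
    yc <- y[, groups == cond, drop = FALSE]
    mc <- rowMeans(yc)
    ssb <- ssb + ncol(yc) * (mc - grand)^2
    ssw <- ssw + rowSums((yc - mc)^2)
  }
  df1 <- k - 1L
  df2 <- n - k
  Fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  degenerate <- ssw < 1e-300 & ssb < 1e-300
  p[degenerate] <- 1
  Fstat[degenerate] <- 0
  data.frame(probeset_id = rownames(y), F = unname(Fstat), p = unname(p),
             degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}

#' MADS-style differential splicing test (moderated t on the splicing index)
#'
#' Per probeset, an empirical-Bayes moderated t of the probeset-level
#' splicing index between exactly two conditions, sharing one pair of
#' variance-prior hyperparameters across all probesets (same machinery as
#' [moderated_t_test()]). A probe-aware variant combining per-probe
#' moderated-t p-values by Fisher's method is available behind
#' `method = "probe_fisher"`; it is not the default because correlation
#' between probes of a probeset inflates the Fisher combination.
#'
#' @param si a `splicing_index_matrix`.
#' @param design a [sample_design].
#' @param condition_pair exactly two condition labels.
#' @param prior_df,prior_var hyperparameter overrides as in
#'   [moderated_t_test()]; `prior_df = 0` gives the ordinary t.
#' @param method `"probeset"` (default) or `"probe_fisher"`.
#' @return A data.frame `probeset_id`, `delta_si`, `t`, `p` (two-sided),
#'   `adj_p` (informational); hyperparameters in attributes.
#' @export
mads_test <- function(si, design, condition_pair, prior_df = NULL,
                      prior_var = NULL, method = c("probeset", "probe_fisher")) {
  method <- match.arg(method)
  if (length(condition_pair) != 2L)
    stop_config("mads_test compares exactly 2 conditions")
  cols1 <- design_samples(design, condition_pair[1L])
  cols2 <- design_samples(design, condition_pair[2L])
  if (method == "probeset") {
    res <- eb_moderated_t(si$probeset_si, cols1, cols2,
                          prior_df = prior_df, prior_var = prior_var)
    out <- data.frame(probeset_id = rownames(res), delta_si = res$log2fc,
                      t = res$t, p = res$p, adj_p = res$adj_p,
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    probe_res <- eb_moderated_t(si$probe_si, cols1, cols2,
                                prior_df = prior_df, prior_var = prior_var)
    res <- probe_res
    ps_of <- si$probe_map$probeset_id[match(rownames(probe_res),
                                            si$probe_map$probe_id)]
    chi <- rowsum(-2 * log(pmax(probe_res$p, 1e-300)), ps_of)
    df <- 2 * as.vector(table(ps_of)[rownames(chi)])
    p <- stats::pchisq(chi[, 1L], df = df, lower.tail = FALSE)
    delta <- rowsum(probe_res$log2fc, ps_of)[, 1L] /
      as.vector(table(ps_of)[rownames(chi)])
    out <- data.frame(probeset_id = rownames(chi), delta_si = unname(delta),
                      t = NA_real_, p = unname(p),
                      adj_p = bh_adjust(unname(p)),
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  attr(out, "prior_df") <- attr(res, "prior_df")
  attr(out, "prior_var") <- attr(res, "prior_var")
  attr(out, "method") <- method
  out
}

#' Dual-test consensus splicing calls
#'
#' A probeset is called alternatively spliced only when its p-value is
#' below `alpha` in BOTH tests (raw p-values; no multiple-testing
#' correction — the conjunction of two independent tests is the error
#' control, and BH-adjusted columns are emitted for information only). A
#' transcript is called when at least one of its probesets is called.
#'
#' @param p_midas,p_mads named numeric vectors (probeset -> p), or the
#'   data.frames returned by [midas_test()] / [mads_test()]. Their probeset
#'   universes must match exactly.
#' @param alpha per-test significance threshold (default 0.01).
#' @param annotation a [probe_annotation] for the transcript/gene roll-up.
#' @return A `splicing_call_table` list: `probesets` (data.frame with
#'   `p_midas`, `p_mads`, `adj_p_midas`, `adj_p_mads`, `called`),
#'   `transcripts`, `genes` (roll-ups), and `alpha`.
#' @export
consensus_splicing_calls <- function(p_midas, p_mads, alpha = 0.01, annotation) {
  as_pvec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$p, x$probeset_id) else x
  }
  pm <- as_pvec(p_midas)
  pa <- as_pvec(p_mads)
  if (!setequal(names(pm), names(pa))) {
    diff <- c(setdiff(names(pm), names(pa)), setdiff(names(pa), names(pm)))
    stop_data("probeset universes differ between the two tests: %s",
              paste(utils::head(diff, 10L), collapse = ", "))
  }
  pa <- pa[names(pm)]
  g <- unique(genomic_probes(annotation)[, c("probeset_id", "transcript_id",
                                             "gene_id")])
  idx <- match(names(pm), g$probeset_id)
  tab <- data.frame(probeset_id = names(pm),
                    transcript_id = g$transcript_id[idx],
                    gene_id = g$gene_id[idx],
                    p_midas = unname(pm), p_mads = unname(pa),
                    adj_p_midas = bh_adjust(unname(pm)),
                    adj_p_mads = bh_adjust(unname(pa)),
                    called = unname(pm < alpha & pa < alpha),
                    stringsAsFactors = FALSE)
  tx <- stats::aggregate(called ~ transcript_id, data = tab, FUN = any)
  gn <- stats::aggregate(called ~ gene_id, data = tab, FUN = any)
  structure(list(probesets = tab,
                 transcripts = tx,
                 genes = gn,
                 alpha = alpha,
                 n_called_probesets = sum(tab$called),
                 n_called_transcripts = sum(tx$called)),
            class = "splicing_call_table")
}

#' @export
print.splicing_call_table <- function(x, ...) {
  cat(sprintf("splicing_call_table: %d/%d probesets called at p<%g in both tests (%d transcripts)\n",
              x$n_called_probesets, nrow(x$probesets), x$alpha,
              x$n_called_transcripts))
  invisible(x)
}

#' Transcripts or genes called alternatively spliced
#'
#' @param calls a `splicing_call_table`.
#' @param level `"transcript"`, `"gene"` or `"probeset"`.
#' @return Character vector of called ids.
#' @export
called_spliced <- function(calls, level = c("transcript", "gene", "probeset")) {
  level <- match.arg(level)
  switch(level,
         transcript = calls$transcripts$transcript_id[calls$transcripts$called],
         gene = calls$genes$gene_id[calls$genes$called],
         probeset = calls$probesets$probeset_id[calls$probesets$called])
}
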