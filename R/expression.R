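# Transcript-level expression: summarization, empirical-Bayes moderated-t
# differential expression with fold-change filtering, and Venn partitioning
# of presence calls.

#' Summarize probe intensities to transcript expression
#'
#' The expression level of a transcript in a sample is the mean log2
#' background-corrected, affinity-corrected intensity of all of its
#' surviving probes.
#'
#' @param m a background-corrected [intensity_matrix] (cross-hybridizing
#'   probes already dropped, probe effects applied).
#' @param annotation a [probe_annotation].
#' @return A numeric matrix, transcripts x samples, of log2 expression,
#'   with class `expression_matrix`. Transcripts with zero surviving probes
#'   are excluded (with a message).
#' @export
summarize_transcripts <- function(m, annotation) {
  if (!m$background_corrected)
    stop_data("summarize_transcripts expects a background-corrected matrix")
  g <- genomic_probes(annotation)
  lost <- setdiff(unique(g$transcript_id),
                  unique(g$transcript_id[g$probe_id %in% probe_ids(m)]))
  if (length(lost))
    message(sprintf("summarize_transcripts: %d transcript(s) with no surviving probes excluded",
                    length(lost)))
  g <- g[g$probe_id %in% probe_ids(m), , drop = FALSE]
  if (!nrow(g)) stop_data("no genomic probes shared between matrix and annotation")
  logm <- log2(m$values[g$probe_id, , drop = FALSE])
  counts <- as.vector(table(g$transcript_id)[sort(unique(g$transcript_id))])
  expr <- rowsum(logm, g$transcript_id) / counts
  class(expr) <- c("expression_matrix", class(expr))
  expr
}

# --- empirical-Bayes moderated t machinery ----------------------------------
# Shared by transcript-level differential expression and the MADS-style
# splicing test. Hyperparameters (prior df d0, prior variance s0^2) are fit
# by moment-matching the distribution of log residual variances: with
# s_g^2 ~ s0^2 * F(d_g, d0), e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)
# has mean log s0^2 + digamma(d0/2) - log(d0/2) and variance
# trigamma(d_g/2) + trigamma(d0/2); the trigamma equation is inverted by
# Newton iteration.

trigamma_inverse <- function(y) {
  if (y <= 0) stop_config("trigamma_inverse needs y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

# Moment-matching fit of (d0, s0^2) from residual variances s2 on df degrees
# of freedom. Returns d0 = Inf when the observed spread of log s2 does not
# exceed its sampling expectation.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) {
    warning("all residual variances are zero; using infinite prior df")
    return(list(d0 = Inf, s02 = 0))
  }
  if (any(!ok))
    warning(sprintf("%d zero/non-finite residual variance(s) excluded from prior fit",
                    sum(!ok)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  if (n < 2L) return(list(d0 = Inf, s02 = exp(emean)))
  evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

# Core two-group moderated t on a features x samples matrix.
# prior_df: NULL = fit empirically; 0 = ordinary t; Inf = full shrinkage.
eb_moderated_t <- function(y, cols1, cols2, prior_df = NULL, prior_var = NULL) {
  n1 <- length(cols1); n2 <- length(cols2)
  if (n1 < 2L || n2 < 2L)
    stop_data("each condition needs >= 2 replicates for the moderated t")
  y1 <- y[, cols1, drop = FALSE]
  y2 <- y[, cols2, drop = FALSE]
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  df_resid <- n1 + n2 - 2L
  s2 <- (rowSums((y1 - m1)^2) + rowSums((y2 - m2)^2)) / df_resid
  if (is.null(prior_df) || is.null(prior_var)) {
    fit <- fit_variance_prior(s2, df_resid)
    d0 <- prior_df %||% fit$d0
    s02 <- prior_var %||% fit$s02
  } else {
    d0 <- prior_df; s02 <- prior_var
  }
  if (d0 < 0) stop_config("prior df must be >= 0")
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  delta <- m1 - m2
  t_mod <- delta / se
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(mean_1 = m1, mean_2 = m2, log2fc = delta,
             s2 = s2, df_resid = df_resid, t = t_mod,
             df_total = df_total, p = p,
             adj_p = bh_adjust(p),
             row.names = rownames(y), stringsAsFactors = FALSE,
             check.names = FALSE) -> out
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Empirical-Bayes moderated two-group t-test on transcript expression
#'
#' Per transcript, the difference of condition means is tested with a
#' t-statistic whose residual variance is shrunk toward a pooled prior:
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, with the prior
#' degrees of freedom \eqn{d_0} and prior variance \eqn{s_0^2} fit across
#' transcripts by moment-matching the log residual variances, and p-values
#' from a t reference on \eqn{d_0 + d_g} degrees of freedom (normal when
#' \eqn{d_0 = \infty}). Benjamini-Hochberg adjusted p-values are appended.
#'
#' @param expr an `expression_matrix` (transcripts x samples, log2).
#' @param design a [sample_design].
#' @param condition_pair length-2 character vector; the log2 fold change is
#'   `mean(condition_pair[1]) - mean(condition_pair[2])`.
#' @param prior_df override the fitted prior df: `0` reproduces the
#'   ordinary two-sample t, `Inf` forces full shrinkage to the prior
#'   variance; `NULL` (default) fits it empirically.
#' @param prior_var optional prior variance override (used with `prior_df`).
#' @return A `differential_expression` data.frame with columns
#'   `transcript_id`, per-group means, `log2fc`, residual variance `s2` and
#'   df, moderated `t`, `p`, `adj_p`; fitted hyperparameters in
#'   `attr(, "prior_df")` / `attr(, "prior_var")`.
#' @export
moderated_t_test <- function(expr, design, condition_pair,
                             prior_df = NULL, prior_var = NULL) {
  if (length(condition_pair) != 2L)
    stop_config("condition_pair must name exactly two conditions")
  if (!all(condition_pair %in% design$condition))
    stop_config("condition(s) not in design: %s",
                paste(setdiff(condition_pair, design$condition), collapse = ", "))
  cols1 <- design_samples(design, condition_pair[1L])
  cols2 <- design_samples(design, condition_pair[2L])
  res <- eb_moderated_t(unclass(expr), cols1, cols2,
                        prior_df = prior_df, prior_var = prior_var)
  out <- data.frame(transcript_id = rownames(res), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", condition_pair[1L])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", condition_pair[2L])
  attr(out, "prior_df") <- attr(res, "prior_df")
  attr(out, "prior_var") <- attr(res, "prior_var")
  attr(out, "condition_pair") <- condition_pair
  class(out) <- c("differential_expression", "data.frame")
  out
}

#' Apply the fold-change filter to a differential expression table
#'
#' Flags transcripts whose absolute fold change meets the threshold
#' (inclusive boundary by default: exactly 2-fold passes a 2-fold cutoff)
#' and lists those that additionally clear the adjusted-p cutoff.
#'
#' @param table a `differential_expression` table.
#' @param threshold_fold fold-change cutoff on the linear scale (> 1).
#' @param alpha significance cutoff on BH-adjusted p (default 0.05).
#' @param strict if `TRUE`, require strictly greater than the threshold.
#' @return The table with a `passes_fold_filter` column; transcripts
#'   passing both filters are in `attr(, "significant")`.
#' @export
fold_change_filter <- function(table, threshold_fold = 2.0, alpha = 0.05,
                               strict = FALSE) {
  if (threshold_fold <= 1) stop_config("threshold_fold must be > 1")
  cut <- log2(threshold_fold)
  table$passes_fold_filter <- if (strict) abs(table$log2fc) > cut else
    abs(table$log2fc) >= cut
  attr(table, "significant") <-
    table$transcript_id[table$passes_fold_filter & table$adj_p < alpha]
  attr(table, "threshold_fold") <- threshold_fold
  attr(table, "alpha") <- alpha
  table
}

#' Partition named sets into disjoint Venn regions
#'
#' Every id is assigned to exactly one region, labelled by the subset of
#' input sets containing it; region counts therefore always sum to the size
#' of the union.
#'
#' @param named_sets named list (>= 2 entries) of id vectors.
#' @return A `venn_partition` list: `regions` (region label -> ids, labels
#'   joined with `&` in input-set order) and `counts`.
#' @export
venn_partition <- function(named_sets) {
  if (!is.list(named_sets) || length(named_sets) < 2L ||
      is.null(names(named_sets)) || any(!nzchar(names(named_sets))))
    stop_config("venn_partition needs >= 2 named sets")
  labels <- names(named_sets)
  named_sets <- lapply(named_sets, function(s) unique(as.character(s)))
  ids <- unique(unlist(named_sets, use.names = FALSE))
  membership <- vapply(named_sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) membership <- matrix(membership, nrow = 1L,
                                              dimnames = list(NULL, labels))
  key <- apply(membership, 1L, function(row) paste(labels[row], collapse = "&"))
  regions <- split(ids, key)
  structure(list(regions = regions, counts = lengths(regions)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition:\n")
  for (nm in names(x$counts)) cat(sprintf("  {%s}: %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
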