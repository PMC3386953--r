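# Probe-level preprocessing: additive background correction, removal of
# cross-hybridizing probes, probe-affinity estimation by median polish, and
# detection-above-background presence calls.
#
# Conventions fixed here: background is additive in linear units and is
# removed by per-sample mean subtraction with an epsilon floor so log2 stays
# defined; all downstream statistics operate on log2 of the corrected
# values. Quantile or batch normalization is deliberately out of scope.

#' Background-correct an intensity matrix
#'
#' Per sample, subtracts the mean intensity of the background probes (or an
#' explicit constant) from every probe, flooring at `floor_epsilon` so that
#' log2 is always defined.
#'
#' @param m an [intensity_matrix], not yet corrected.
#' @param annotation a [probe_annotation] identifying background probes.
#' @param floor_epsilon positive floor applied after subtraction (linear
#'   units); default 1.
#' @param background_constant optional explicit per-sample constant (scalar
#'   or one value per sample) used when the matrix carries no background
#'   probes.
#' @return A background-corrected `intensity_matrix` (background probe rows
#'   are retained, floored near zero). The subtracted per-sample means are
#'   attached as `attr(, "background_means")`.
#' @export
background_correct <- function(m, annotation, floor_epsilon = 1,
                               background_constant = NULL) {
  if (m$background_corrected)
    stop_data("matrix is already background-corrected")
  if (floor_epsilon <= 0) stop_config("floor_epsilon must be > 0")
  bg_ids <- intersect(background_probes(annotation)$probe_id, probe_ids(m))
  if (length(bg_ids) == 0L && is.null(background_constant))
    stop_data(paste("no background probes in matrix; pass an explicit",
                    "`background_constant` to correct without them"))
  bg_mean <- if (length(bg_ids)) {
    colMeans(m$values[bg_ids, , drop = FALSE])
  } else {
    rep_len(background_constant, ncol(m$values))
  }
  corrected <- sweep(m$values, 2L, bg_mean, `-`)
  corrected <- pmax(corrected, floor_epsilon)
  out <- intensity_matrix(corrected, background_corrected = TRUE)
  attr(out, "background_means") <- stats::setNames(bg_mean, sample_ids(m))
  out
}

#' Drop cross-hybridizing probes
#'
#' Removes every probe flagged `cross_hyb_flag` in the annotation. Probesets
#' left with zero probes are reported so downstream stages can exclude them.
#'
#' @param m an [intensity_matrix] (raw or corrected).
#' @param annotation a [probe_annotation].
#' @return A list with `matrix` (the filtered `intensity_matrix`) and
#'   `report`: `dropped_probes` (ids removed) and `empty_probesets`
#'   (probesets whose every probe was flagged).
#' @export
drop_cross_hyb <- function(m, annotation) {
  g <- genomic_probes(annotation)
  flagged <- g$probe_id[g$cross_hyb_flag]
  keep <- setdiff(probe_ids(m), flagged)
  kept_g <- g[g$probe_id %in% keep, , drop = FALSE]
  empty_ps <- setdiff(unique(g$probeset_id), unique(kept_g$probeset_id))
  out <- intensity_matrix(m$values[keep, , drop = FALSE],
                          background_corrected = m$background_corrected)
  list(matrix = out,
       report = list(dropped_probes = intersect(probe_ids(m), flagged),
                     empty_probesets = empty_ps))
}

# Additive median-polish decomposition of x into
# overall + row + col + residual. Hand-rolled (rather than
# stats::medpolish) so that convergence status is returned and the
# iteration is silent.
median_polish <- function(x, max_iter = 50L, tol = 1e-6) {
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  overall <- 0
  resid <- x
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    rmed <- apply(resid, 1L, stats::median)
    resid <- resid - rmed
    row_eff <- row_eff + rmed
    cm <- stats::median(col_eff)
    overall <- overall + cm
    col_eff <- col_eff - cm
    cmed <- apply(resid, 2L, stats::median)
    resid <- sweep(resid, 2L, cmed)
    col_eff <- col_eff + cmed
    rm2 <- stats::median(row_eff)
    overall <- overall + rm2
    row_eff <- row_eff - rm2
    if (max(abs(rmed)) < tol && max(abs(cmed)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(overall = overall, row = row_eff, col = col_eff,
       residuals = resid, converged = converged, iterations = iter)
}

#' Estimate per-probe affinities by median polish
#'
#' Per transcript, decomposes the log2 background-corrected intensities into
#' sample effect + probe effect + residual by median polish; the probe
#' effects are then re-centered to zero mean within each probeset and
#' returned as affinities. Background probes present in the matrix get
#' affinity 0 so that [apply_probe_effects()] covers every row.
#'
#' @param m a background-corrected [intensity_matrix].
#' @param annotation a [probe_annotation].
#' @param max_iter,tol median-polish iteration controls.
#' @return A `probe_effects` data.frame with columns `probe_id`,
#'   `probeset_id`, `affinity`, and attributes `converged` (logical, all
#'   transcripts) and `n_unconverged`.
#' @export
estimate_probe_effects <- function(m, annotation, max_iter = 50L, tol = 1e-6) {
  if (!m$background_corrected)
    stop_data("probe effects are estimated on background-corrected intensities")
  g <- genomic_probes(annotation)
  g <- g[g$probe_id %in% probe_ids(m), , drop = FALSE]
  if (!nrow(g)) stop_data("no genomic probes shared between matrix and annotation")
  logm <- log2(m$values[g$probe_id, , drop = FALSE])
  aff <- numeric(nrow(g))
  names(aff) <- g$probe_id
  unconverged <- 0L
  for (idx in split(seq_len(nrow(g)), g$transcript_id)) {
    sub <- logm[idx, , drop = FALSE]
    if (nrow(sub) == 1L) {
      aff[idx] <- 0
      next
    }
    mp <- median_polish(sub, max_iter = max_iter, tol = tol)
    if (!mp$converged) unconverged <- unconverged + 1L
    aff[idx] <- mp$row
  }
  # re-center within probesets; single-probe probesets get affinity 0
  ps_of <- g$probeset_id
  aff <- aff - stats::ave(aff, ps_of)
  singles <- names(which(table(ps_of) == 1L))
  if (length(singles))
    warning(sprintf("%d single-probe probeset(s): affinity fixed at 0",
                    length(singles)))
  out <- data.frame(probe_id = g$probe_id, probeset_id = ps_of,
                    affinity = unname(aff), stringsAsFactors = FALSE)
  bg_ids <- setdiff(probe_ids(m), g$probe_id)
  if (length(bg_ids))
    out <- rbind(out, data.frame(probe_id = bg_ids, probeset_id = "",
                                 affinity = 0, stringsAsFactors = FALSE))
  class(out) <- c("probe_effects", "data.frame")
  attr(out, "converged") <- unconverged == 0L
  attr(out, "n_unconverged") <- unconverged
  out
}

#' Remove estimated probe affinities from an intensity matrix
#'
#' Divides each probe's (linear) intensity by `2^affinity`, i.e. subtracts
#' the affinity on the log2 scale. Applying a zero affinity table is the
#' identity; applying `effects` then `-effects` round-trips.
#'
#' @param m an [intensity_matrix].
#' @param effects a `probe_effects` table covering every probe of `m`.
#' @return The corrected `intensity_matrix`.
#' @export
apply_probe_effects <- function(m, effects) {
  idx <- match(probe_ids(m), effects$probe_id)
  if (anyNA(idx))
    stop_data("probe effects missing for probe(s): %s",
              paste(utils::head(probe_ids(m)[is.na(idx)], 5L), collapse = ", "))
  vals <- m$values / 2^effects$affinity[idx]
  intensity_matrix(vals, background_corrected = m$background_corrected)
}

#' Present/absent detection against the background distribution
#'
#' A transcript is detected in a sample when its mean probe log2 intensity
#' exceeds the background log2 mean plus `z_threshold` background standard
#' deviations (computed per sample from the background probes of the
#' uncorrected matrix); it is called present in a condition when detected in
#' at least `min_replicates` of that condition's samples.
#'
#' @param m the raw (uncorrected) [intensity_matrix], background probes
#'   included.
#' @param annotation a [probe_annotation].
#' @param design a [sample_design].
#' @param z_threshold detection z-score threshold (default 2).
#' @param min_replicates minimum detected samples per condition (default 3).
#' @return A `presence_calls` list: `present` (transcripts x conditions
#'   logical matrix), `scores` (transcripts x samples detection z-scores)
#'   and the thresholds used.
#' @export
detect_present <- function(m, annotation, design, z_threshold = 2,
                           min_replicates = 3L) {
  reps <- table(design$condition)
  if (any(reps < min_replicates))
    stop_config("condition '%s' has %d sample(s), fewer than min_replicates = %d",
                names(reps)[reps < min_replicates][1L],
                min(reps), min_replicates)
  bg_ids <- intersect(background_probes(annotation)$probe_id, probe_ids(m))
  if (!length(bg_ids))
    stop_data("presence detection needs background probes in the raw matrix")
  logm <- log2(pmax(m$values, .Machine$double.eps))
  bg_mu <- colMeans(logm[bg_ids, , drop = FALSE])
  bg_sd <- apply(logm[bg_ids, , drop = FALSE], 2L, stats::sd)
  bg_sd <- pmax(bg_sd, .Machine$double.eps)

  g <- genomic_probes(annotation)
  g <- g[g$probe_id %in% probe_ids(m), , drop = FALSE]
  tx_mean <- rowsum(logm[g$probe_id, , drop = FALSE], g$transcript_id) /
    as.vector(table(g$transcript_id)[sort(unique(g$transcript_id))])
  scores <- sweep(sweep(tx_mean, 2L, bg_mu, `-`), 2L, bg_sd, `/`)
  scores <- scores[, design$sample_id, drop = FALSE]
  detected <- scores > z_threshold

  conds <- unique(design$condition)
  present <- vapply(conds, function(cond) {
    rowSums(detected[, design_samples(design, cond), drop = FALSE]) >= min_replicates
  }, logical(nrow(detected)))
  dimnames(present) <- list(rownames(scores), conds)
  structure(list(present = present, scores = scores,
                 z_threshold = z_threshold, min_replicates = min_replicates),
            class = "presence_calls")
}

#' @export
print.presence_calls <- function(x, ...) {
  cat(sprintf("presence_calls: %d transcripts x %d conditions; %d present somewhere\n",
              nrow(x$present), ncol(x$present), sum(rowSums(x$present) > 0)))
  invisible(x)
}

#' Transcripts present in a set of conditions
#'
#' @param calls a `presence_calls` object.
#' @param conditions condition labels; a transcript qualifies when present
#'   in every one of them.
#' @return Character vector of transcript ids.
#' @export
present_transcripts <- function(calls, conditions) {
  stopifnot(all(conditions %in% colnames(calls$present)))
  rownames(calls$present)[
    rowSums(calls$present[, conditions, drop = FALSE]) == length(conditions)]
}
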