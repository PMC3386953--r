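# Data model and TSV/GMT readers and writers.
#
# All tabular I/O is tab-separated with a header row and '\n' line endings.
# Binary array vendor formats (CEL/CDF) are deliberately unsupported: the
# pipeline consumes plain intensity matrices. Gene identifiers are opaque,
# case-sensitive strings; no symbol normalization is performed.

# --- IntensityMatrix ---------------------------------------------------------

#' Construct a probe-level intensity matrix
#'
#' A thin container holding a numeric probes x samples matrix in linear
#' fluorescence units, plus a flag recording whether additive background has
#' already been subtracted (after which values may legitimately sit at the
#' epsilon floor rather than at raw scale).
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param background_corrected logical; has background been subtracted?
#' @return An object of class `intensity_matrix` with elements `values` and
#'   `background_corrected`.
#' @export
intensity_matrix <- function(values, background_corrected = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("intensity matrix values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("intensity matrix requires probe (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop_format("duplicate probe id: %s",
                rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop_format("duplicate sample id: %s",
                colnames(values)[duplicated(colnames(values))][1L])
  if (!all(is.finite(values)))
    stop_format("intensity values must all be finite")
  if (!background_corrected && any(values < 0))
    stop_format("raw (uncorrected) intensities must be non-negative")
  structure(list(values = values,
                 background_corrected = isTRUE(background_corrected)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d probes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$background_corrected) "background-corrected" else "raw"))
  invisible(x)
}

#' @rdname intensity_matrix
#' @param x an `intensity_matrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname intensity_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a probe intensity matrix from TSV
#'
#' First column `probe_id`, remaining columns one per sample; header row
#' required. Declared probe and sample order is preserved. The result is
#' marked as not background-corrected.
#'
#' @param path file path.
#' @return An [intensity_matrix].
#' @export
read_intensity_tsv <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L)
    stop_format("intensity file needs a probe_id column plus >=1 sample: %s", path)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_format("duplicate probe id in %s: %s", path, dup[1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stop_format("non-numeric intensity at row %d, column '%s' of %s",
                  bad[1L, 1L], colnames(vals)[bad[1L, 2L]], path)
    stop_format("non-numeric intensity values in %s", path)
  }
  if (anyNA(vals))
    stop_format("missing intensity cells are not allowed (%s)", path)
  rownames(vals) <- ids
  intensity_matrix(vals, background_corrected = FALSE)
}

#' Write a probe intensity matrix to TSV
#'
#' Deterministic column order (probe_id first, samples as stored) and
#' `\n` line endings; `write_intensity_tsv(read_intensity_tsv(f))` is
#' byte-idempotent.
#'
#' @param m an [intensity_matrix].
#' @param path output file path.
#' @export
write_intensity_tsv <- function(m, path) {
  df <- data.frame(probe_id = probe_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# --- ProbeAnnotation ---------------------------------------------------------

ANNOTATION_COLS <- c("probe_id", "probeset_id", "transcript_id", "gene_id",
                     "exon_index", "cross_hyb_flag", "probe_kind")

#' Construct and validate a probe annotation table
#'
#' Encodes the probe -> probeset -> transcript -> gene nesting of an exon
#' array. Each probe belongs to exactly one probeset, each probeset to one
#' transcript, each transcript to one gene. Rows with
#' `probe_kind == "background"` are background probes and carry empty
#' probeset/transcript/gene fields.
#'
#' @param df data.frame with columns `probe_id`, `probeset_id`,
#'   `transcript_id`, `gene_id`, `exon_index`, `cross_hyb_flag`,
#'   `probe_kind` (one of `"genomic"`, `"background"`).
#' @return A validated `probe_annotation` (a data.frame subclass).
#' @export
probe_annotation <- function(df) {
  missing_cols <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing_cols))
    stop_format("annotation missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[ANNOTATION_COLS]
  for (col in c("probe_id", "probeset_id", "transcript_id", "gene_id", "probe_kind"))
    df[[col]] <- as.character(df[[col]])
  df$exon_index <- as.integer(df$exon_index)
  df$cross_hyb_flag <- as.logical(df$cross_hyb_flag)
  if (!all(df$probe_kind %in% c("genomic", "background")))
    stop_format("probe_kind must be 'genomic' or 'background'")
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop_data("probe assigned to more than one probeset: %s", dup[1L])
  g <- df[df$probe_kind == "genomic", , drop = FALSE]
  b <- df[df$probe_kind == "background", , drop = FALSE]
  if (nrow(b) && any(nzchar(b$probeset_id) | nzchar(b$transcript_id) |
                     nzchar(b$gene_id), na.rm = TRUE))
    stop_data("background probes must not carry probeset/transcript/gene ids")
  if (nrow(g)) {
    if (any(!nzchar(g$probeset_id)) || any(!nzchar(g$transcript_id)) ||
        any(!nzchar(g$gene_id)))
      stop_data("genomic probes require probeset, transcript and gene ids")
    ps2tx <- unique(g[, c("probeset_id", "transcript_id")])
    bad <- ps2tx$probeset_id[duplicated(ps2tx$probeset_id)]
    if (length(bad))
      stop_data("probeset spans more than one transcript: %s", bad[1L])
    tx2gene <- unique(g[, c("transcript_id", "gene_id")])
    bad <- tx2gene$transcript_id[duplicated(tx2gene$transcript_id)]
    if (length(bad))
      stop_data("transcript spans more than one gene: %s", bad[1L])
    if (anyNA(g$exon_index) || any(g$exon_index < 1L))
      stop_data("genomic probes require a 1-based exon_index")
  }
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Read a probe annotation table from TSV
#'
#' @param path file path; columns as in [probe_annotation()].
#' @return A validated `probe_annotation`. Nesting invariants are checked on
#'   load and violations raise a data-integrity error.
#' @export
read_probe_annotation <- function(path) {
  df <- read_tsv_checked(path)
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param annotation a `probe_annotation`.
#' @export
write_probe_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df$cross_hyb_flag <- ifelse(df$cross_hyb_flag, "TRUE", "FALSE")
  write_tsv(df, path)
}

# Convenience subsets used throughout the pipeline.
genomic_probes <- function(annotation)
  annotation[annotation$probe_kind == "genomic", , drop = FALSE]
background_probes <- function(annotation)
  annotation[annotation$probe_kind == "background", , drop = FALSE]

# --- SampleDesign ------------------------------------------------------------

#' Construct and validate a sample design table
#'
#' @param df data.frame with columns `sample_id`, `condition`, `replicate`.
#'   `(condition, replicate)` pairs must be unique and every condition must
#'   have at least two replicates.
#' @return A `sample_design` data.frame.
#' @export
sample_design <- function(df) {
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(df)))
    stop_format("design requires columns: %s", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id))
    stop_data("duplicate sample id: %s", df$sample_id[duplicated(df$sample_id)][1L])
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    stop_format("replicate must be a positive integer")
  key <- paste(df$condition, df$replicate)
  if (anyDuplicated(key))
    stop_data("duplicate (condition, replicate) pair: %s", key[duplicated(key)][1L])
  reps <- table(df$condition)
  if (any(reps < 2L))
    stop_data("condition '%s' has fewer than 2 replicates",
              names(reps)[reps < 2L][1L])
  class(df) <- c("sample_design", "data.frame")
  df
}

#' @rdname sample_design
#' @param path file path.
#' @export
read_sample_design <- function(path) sample_design(read_tsv_checked(path))

#' @rdname sample_design
#' @param design a `sample_design`.
#' @export
write_sample_design <- function(design, path) write_tsv(as.data.frame(design), path)

design_samples <- function(design, condition)
  design$sample_id[design$condition == condition]

# --- GeneSetCollection -------------------------------------------------------

#' Construct a gene-set collection
#'
#' @param sets named list; each element a character vector of member gene
#'   ids. Members are deduplicated; empty sets are rejected.
#' @param descriptions optional character vector parallel to `sets`.
#' @return A `gene_set_collection`: a named list of
#'   `list(description, genes)` entries.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets)) stop_format("gene-set collection may not be empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_format("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stop_format("duplicate gene-set name: %s",
                names(sets)[duplicated(names(sets))][1L])
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  out <- Map(function(genes, desc) {
    genes <- unique(as.character(genes))
    if (!length(genes)) stop_format("empty gene set is not allowed")
    list(description = desc, genes = genes)
  }, sets, descriptions)
  structure(out, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10L))
    cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]]$genes)))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' @rdname gene_set_collection
#' @param collection a `gene_set_collection`.
#' @param set_name a set name.
#' @export
set_members <- function(collection, set_name) collection[[set_name]]$genes

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one field per member gene. Duplicate members
#' within a set are collapsed.
#'
#' @param path file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_format("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop_format("GMT line %d has fewer than 3 fields (%s)", short[1L], path)
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection[[nm]]$description, collection[[nm]]$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Map gene-set members through an ortholog table
#'
#' Each member is replaced by all of its mapped targets (a source may map to
#' zero, one, or several targets, e.g. human symbols onto mouse homologs).
#' Unmapped members are dropped and reported; duplicates arising from the
#' mapping are collapsed; sets left empty are dropped with a warning.
#'
#' @param sets a [gene_set_collection()].
#' @param mapping data.frame whose first two columns are
#'   `(source_id, target_id)`.
#' @return A `gene_set_collection` in target-id space. The dropped members
#'   are attached as `attr(, "unmapped")`, a named list per input set.
#' @export
map_orthologs <- function(sets, mapping) {
  if (!inherits(sets, "gene_set_collection"))
    stop_format("`sets` must be a gene_set_collection")
  mapping <- as.data.frame(mapping)
  if (!nrow(mapping) || ncol(mapping) < 2L)
    stop_format("ortholog mapping table is empty")
  src <- as.character(mapping[[1L]])
  tgt <- as.character(mapping[[2L]])
  unmapped <- list()
  out <- list()
  descs <- character(0)
  for (nm in names(sets)) {
    members <- sets[[nm]]$genes
    hit <- members %in% src
    if (any(!hit)) unmapped[[nm]] <- members[!hit]
    targets <- unique(tgt[src %in% members])
    if (!length(targets)) {
      warning(sprintf("gene set '%s' empty after ortholog mapping; dropped", nm))
      next
    }
    out[[nm]] <- targets
    descs <- c(descs, sets[[nm]]$description)
  }
  if (!length(out))
    stop_data("no gene set survived ortholog mapping")
  if (length(unmapped))
    message(sprintf("map_orthologs: %d unmapped member(s) dropped across %d set(s)",
                    sum(lengths(unmapped)), length(unmapped)))
  res <- gene_set_collection(out, descs)
  attr(res, "unmapped") <- unmapped
  res
}

# --- shared TSV plumbing -----------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  if (file.size(path) == 0L) stop_format("empty file: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}
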