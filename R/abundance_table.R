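#' Construct an abundance table
#'
#' An `abundance_table` couples a taxa-by-samples matrix of relative
#' abundances with per-sample metadata. Columns are renormalized to sum to 1
#' on construction; a warning is recorded when any column deviates from 1 by
#' more than `1e-3` beforehand, since that usually signals counts rather
#' than relative abundances.
#'
#' @param values numeric matrix, taxa in rows (rownames required), samples in
#'   columns (colnames required). All entries must be non-negative.
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `subject_id`, `cohort_id`, `timepoint` (one of
#'   `"pre"`, `"during"`, `"post"`), `day` (integer days since the start of
#'   antibiotics) and optionally `group`.
#' @param normalize renormalize each sample column to sum 1 (default TRUE).
#' @return an object of class `abundance_table` with elements `values`
#'   (matrix) and `metadata` (data.frame, row order matching the columns).
#' @export
abundance_table <- function(values, metadata, normalize = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated taxon identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "cohort_id", "timepoint", "day")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0)
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"group" %in% names(metadata)) metadata$group <- NA_character_
  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent) > 0)
    stop("samples without metadata: ", paste(absent, collapse = ", "))
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  bad_tp <- !metadata$timepoint %in% c("pre", "during", "post")
  if (any(bad_tp))
    stop("invalid timepoint for sample(s): ",
         paste(metadata$sample_id[bad_tp], collapse = ", "))
  incomplete <- !complete.cases(metadata[required])
  if (any(incomplete))
    stop("incomplete metadata for sample(s): ",
         paste(metadata$sample_id[incomplete], collapse = ", "))

  if (normalize) {
    cs <- colSums(values)
    if (any(cs <= 0))
      stop("sample(s) with zero total abundance: ",
           paste(colnames(values)[cs <= 0], collapse = ", "))
    if (any(abs(cs - 1) > 1e-3))
      warning(sprintf("%d sample(s) deviated from sum 1 by > 1e-3 before normalization",
                      sum(abs(cs - 1) > 1e-3)))
    values <- sweep(values, 2, cs, "/")
  }
  structure(list(values = values, metadata = metadata), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("cohorts: %s\n", paste(unique(x$metadata$cohort_id), collapse = ", ")))
  cat(sprintf("timepoints: %s\n",
              paste(names(table(x$metadata$timepoint)), collapse = ", ")))
  invisible(x)
}

#' Taxon and sample accessors
#' @param x an `abundance_table` or `gene_content` object
#' @return character vector of identifiers
#' @export
taxa <- function(x) {
  if (inherits(x, "abundance_table") || inherits(x, "gene_content"))
    return(rownames(x$values))
  rownames(x)
}

#' @rdname taxa
#' @export
samples <- function(x) colnames(x$values)

#' Subset an abundance table by samples
#'
#' Abundances are not renormalized (samples keep their composition); use
#' `renormalize = TRUE` after dropping taxa.
#'
#' @param table an `abundance_table`
#' @param sample_ids,taxon_ids identifiers to keep (NULL keeps all)
#' @param renormalize renormalize columns after subsetting taxa
#' @return an `abundance_table`
#' @export
subset_table <- function(table, sample_ids = NULL, taxon_ids = NULL,
                         renormalize = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (!is.null(taxon_ids)) {
    missing <- setdiff(taxon_ids, rownames(v))
    if (length(missing) > 0)
      stop("unknown taxa: ", paste(missing, collapse = ", "))
    v <- v[taxon_ids, , drop = FALSE]
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(v))
    if (length(missing) > 0)
      stop("unknown samples: ", paste(missing, collapse = ", "))
    v <- v[, sample_ids, drop = FALSE]
  }
  md <- table$metadata[match(colnames(v), table$metadata$sample_id), , drop = FALSE]
  out <- structure(list(values = v, metadata = md), class = "abundance_table")
  if (renormalize) out$values <- sweep(out$values, 2, colSums(out$values), "/")
  out
}

#' Split an abundance table by cohort
#' @param table an `abundance_table`
#' @return named list of `abundance_table`s, one per cohort
#' @export
split_by_cohort <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  cohorts <- unique(table$metadata$cohort_id)
  setNames(lapply(cohorts, function(co) {
    subset_table(table, sample_ids = table$metadata$sample_id[table$metadata$cohort_id == co])
  }), cohorts)
}

#' Construct a gene-content network
#'
#' Taxa-by-gene-family incidence (0/1 presence or non-negative copy number)
#' from which pairwise functional distances are computed.
#'
#' @param incidence non-negative numeric matrix with taxon rownames and
#'   gene-family colnames
#' @return object of class `gene_content`
#' @export
gene_content <- function(incidence) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("`incidence` needs taxon rownames and gene-family colnames")
  if (any(incidence < 0)) stop("gene-content entries must be non-negative")
  structure(list(values = incidence), class = "gene_content")
}

#' @export
print.gene_content <- function(x, ...) {
  cat(sprintf("gene_content: %d taxa x %d gene families (density %.2f)\n",
              nrow(x$values), ncol(x$values), mean(x$values > 0)))
  invisible(x)
}

#' Construct recovery labels
#'
#' @param subject_id,cohort_id,label parallel vectors; `label` must be
#'   `"recoverer"` or `"non_recoverer"`
#' @param ... additional per-subject columns (e.g. diagnostics)
#' @return data.frame of class `recovery_labels`
#' @export
recovery_labels <- function(subject_id, cohort_id, label, ...) {
  if (!all(label %in% c("recoverer", "non_recoverer")))
    stop("labels must be 'recoverer' or 'non_recoverer'")
  if (anyDuplicated(subject_id)) stop("duplicated subject_id in labels")
  out <- data.frame(subject_id = as.character(subject_id),
                    cohort_id = as.character(cohort_id),
                    label = as.character(label),
                    ..., stringsAsFactors = FALSE)
  class(out) <- c("recovery_labels", "data.frame")
  out
}

# Map per-subject labels onto the samples of a table (internal).
sample_labels <- function(table, labels) {
  lab <- labels$label[match(table$metadata$subject_id, labels$subject_id)]
  setNames(lab, table$metadata$sample_id)
}
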