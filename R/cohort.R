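#' Read a samples x genera abundance table from TSV
#'
#' Reads a tab-separated abundance table with one header row and row labels in
#' the first column, and returns it in the canonical samples-as-rows layout.
#' Genus-level 16S profiles are distributed both ways round, so the on-disk
#' orientation must be declared rather than guessed.
#'
#' @param path Path to a TSV file. First column holds row labels, remaining
#'   columns are numeric.
#' @param orientation Either \code{"samples-as-rows"} (default) or
#'   \code{"taxa-as-rows"}; the latter is transposed on read.
#' @return A \code{taxon_profile} object: a list with \code{values} (numeric
#'   N x F matrix, samples as rows), \code{sample_ids}, \code{genus_names} and
#'   \code{is_counts} (TRUE when every entry is a whole number).
#' @seealso [read_metadata()], [select_time_series()]
#' @export
read_profile_table <- function(path, orientation = c("samples-as-rows", "taxa-as-rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("profile table needs a label column plus at least one data column")
  labels <- as.character(raw[[1L]])
  num <- raw[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L)
        stop(sprintf("non-numeric cell at row '%s', column '%s'",
                     labels[bad[1L]], names(num)[j]))
      v <- vn
    }
    num[[j]] <- v
  }
  values <- as.matrix(num)
  rownames(values) <- labels
  if (orientation == "taxa-as-rows") values <- t(values)
  taxon_profile(values)
}

#' Construct a validated taxon profile table
#'
#' @param values Numeric matrix, samples as rows, genera as columns, with
#'   sample ids as rownames and genus names as colnames.
#' @return A \code{taxon_profile} object (see [read_profile_table()]).
#' @export
taxon_profile <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample ids (rownames) and genus names (colnames)")
  if (anyNA(values)) stop("abundance table contains missing values")
  if (any(values < 0)) stop("abundance table contains negative values")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate genus names")
  structure(list(values = values,
                 sample_ids = rownames(values),
                 genus_names = colnames(values),
                 is_counts = all(values == round(values))),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("taxon profile: %d samples x %d genera (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_counts) "counts" else "relative abundances"))
  invisible(x)
}

#' @export
dim.taxon_profile <- function(x) dim(x$values)

#' Read per-sample cohort metadata from TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{participant_id},
#'   \code{visit_index} (positive integer giving within-participant collection
#'   order) and \code{class_label}.
#' @param class_labels Allowed labels; default the IBD cohort classes
#'   \code{c("CD", "UC", "nonIBD")}.
#' @return A data.frame of validated metadata, one row per sample.
#' @export
read_metadata <- function(path, class_labels = c("CD", "UC", "nonIBD")) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(md, class_labels)
}

#' @rdname read_metadata
#' @param metadata A data.frame to validate in place of a file.
#' @export
validate_metadata <- function(metadata, class_labels = c("CD", "UC", "nonIBD")) {
  need <- c("sample_id", "participant_id", "visit_index", "class_label")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0L) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$participant_id <- as.character(metadata$participant_id)
  metadata$visit_index <- as.integer(metadata$visit_index)
  metadata$class_label <- as.character(metadata$class_label)
  if (anyNA(metadata$visit_index) || any(metadata$visit_index < 1L))
    stop("visit_index must be a positive integer")
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids in metadata")
  key <- paste(metadata$participant_id, metadata$visit_index, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated (participant_id, visit_index) pair in metadata")
  bad <- setdiff(unique(metadata$class_label), class_labels)
  if (length(bad) > 0L)
    stop(sprintf("unknown class label(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(class_labels, collapse = ", ")))
  per_part <- tapply(metadata$class_label, metadata$participant_id,
                     function(v) length(unique(v)))
  if (any(per_part > 1L))
    stop("class_label must be constant within a participant; offending: ",
         paste(names(per_part)[per_part > 1L], collapse = ", "))
  metadata[c("sample_id", "participant_id", "visit_index", "class_label")]
}

check_profile_metadata <- function(table, metadata) {
  if (!inherits(table, "taxon_profile")) stop("'table' must be a taxon_profile")
  if (!setequal(table$sample_ids, metadata$sample_id) ||
      length(table$sample_ids) != nrow(metadata))
    stop("table and metadata must describe exactly the same samples")
  invisible(TRUE)
}

subset_cohort <- function(table, metadata, keep_ids) {
  metadata <- metadata[match(keep_ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  list(table = taxon_profile(table$values[keep_ids, , drop = FALSE]),
       metadata = metadata)
}

#' Keep each participant's first k time-series samples
#'
#' Participants with fewer than \code{k} samples are dropped entirely; the
#' survivors keep exactly their \code{k} samples of smallest
#' \code{visit_index}. This mirrors a cohort design in which each retained
#' participant contributes the same number of successive stool samples.
#'
#' @param table A \code{taxon_profile}.
#' @param metadata Matching metadata (see [read_metadata()]).
#' @param k Samples to keep per participant (default 10).
#' @return A list with the filtered \code{table} and \code{metadata}, ordered
#'   by participant then visit.
#' @export
select_time_series <- function(table, metadata, k = 10L) {
  check_profile_metadata(table, metadata)
  if (k < 1L) stop("'k' must be >= 1")
  ord <- order(metadata$participant_id, metadata$visit_index)
  md <- metadata[ord, , drop = FALSE]
  keep <- unlist(lapply(split(md$sample_id, md$participant_id), function(ids) {
    if (length(ids) < k) character(0) else ids[seq_len(k)]
  }), use.names = FALSE)
  if (length(keep) == 0L)
    warning("no participant has >= ", k, " samples; result is empty")
  subset_cohort(table, metadata, keep)
}

#' Keep only each participant's first sample
#'
#' Used to build the assemblage-model training set: one (the earliest) sample
#' per participant, avoiding the within-participant homogeneity bias that
#' repeated samples would introduce.
#'
#' @inheritParams select_time_series
#' @return A list with \code{table} and \code{metadata}, one sample per
#'   participant.
#' @export
first_samples <- function(table, metadata) {
  check_profile_metadata(table, metadata)
  ord <- order(metadata$participant_id, metadata$visit_index)
  md <- metadata[ord, , drop = FALSE]
  keep <- vapply(split(md$sample_id, md$participant_id), `[`, character(1L), 1L)
  subset_cohort(table, metadata, unname(keep))
}

#' Draw a class-balanced subset of participants
#'
#' Samples \code{per_class} participants per class without replacement
#' (seeded) and keeps all of their retained samples, giving every class the
#' same number of samples for the downstream per-class maximum-entropy fits.
#'
#' @inheritParams select_time_series
#' @param per_class Participants drawn per class (default 26).
#' @param seed Integer seed controlling the draw.
#' @return A list with \code{table}, \code{metadata} and the \code{seed} used.
#' @export
balanced_subset <- function(table, metadata, per_class = 26L, seed = 1L) {
  check_profile_metadata(table, metadata)
  classes <- sort(unique(metadata$class_label))
  parts <- unique(metadata[c("participant_id", "class_label")])
  chosen <- character(0)
  set.seed(seed)
  for (cl in classes) {
    pool <- sort(parts$participant_id[parts$class_label == cl])
    if (length(pool) < per_class)
      stop(sprintf("class '%s' has only %d eligible participants (< %d requested)",
                   cl, length(pool), per_class))
    chosen <- c(chosen, if (length(pool) == per_class) pool else sample(pool, per_class))
  }
  ord <- order(metadata$participant_id, metadata$visit_index)
  md <- metadata[ord, , drop = FALSE]
  keep <- md$sample_id[md$participant_id %in% chosen]
  out <- subset_cohort(table, metadata, keep)
  out$seed <- seed
  out
}

#' Write a taxon profile or metadata table to TSV
#'
#' @param x A \code{taxon_profile} or a metadata data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_table <- function(x, path) {
  if (inherits(x, "taxon_profile")) {
    df <- data.frame(sample_id = x$sample_ids, x$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
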