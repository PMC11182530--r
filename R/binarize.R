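#' Binarize assemblage abundances into occurrence states
#'
#' Within one disease class, assemblage \eqn{i} is "activated" (\eqn{\sigma_i
#' = +1}) in a sample when its abundance \eqn{\theta_{ni}} is strictly greater
#' than the upper 25th percentile of that assemblage's abundances across all
#' samples of the class, and \eqn{-1} otherwise. The percentile is the order
#' statistic of rank \eqn{\lceil 0.75 N \rceil} (no interpolation), so with
#' distinct values exactly \eqn{\lfloor N/4 \rfloor} samples are activated
#' per assemblage; ties at the threshold fall to \eqn{-1}.
#'
#' @param theta_class An \code{assemblage_abundance} (or plain N x I matrix)
#'   holding samples of exactly one class.
#' @param quantile Activation quantile (default 0.75: the upper 25th
#'   percentile).
#' @return An \code{occurrence_matrix}: \code{states} (N x I with entries
#'   \eqn{\pm 1}), \code{sample_ids}, \code{class_label}, \code{thresholds}
#'   (the per-assemblage cutoffs used).
#' @export
binarize_occurrences <- function(theta_class, quantile = 0.75) {
  class_label <- NA_character_
  sample_ids <- NULL
  if (inherits(theta_class, "assemblage_abundance")) {
    if (!is.null(theta_class$class_labels)) {
      cls <- unique(theta_class$class_labels)
      if (length(cls) > 1L)
        stop("binarization is per class; got labels: ", paste(cls, collapse = ", "))
      class_label <- cls
    }
    sample_ids <- theta_class$sample_ids
    theta_class <- theta_class$theta
  }
  theta_class <- as.matrix(theta_class)
  if (nrow(theta_class) == 0L) stop("empty abundance matrix")
  if (is.null(sample_ids)) sample_ids <- rownames(theta_class)
  N <- nrow(theta_class)
  rank <- ceiling(quantile * N)
  thresholds <- apply(theta_class, 2L, function(col) sort(col)[rank])
  states <- t(ifelse(t(theta_class) > thresholds, 1, -1))
  dimnames(states) <- dimnames(theta_class)
  structure(list(states = states, sample_ids = sample_ids,
                 class_label = class_label, thresholds = thresholds),
            class = "occurrence_matrix")
}

#' Construct an occurrence matrix from +/-1 states directly
#'
#' @param states N x I matrix with entries +1/-1.
#' @param sample_ids Optional sample ids.
#' @param class_label Optional class label.
#' @return An \code{occurrence_matrix}.
#' @export
occurrence_matrix <- function(states, sample_ids = NULL, class_label = NA_character_) {
  states <- as.matrix(states)
  if (!all(states %in% c(-1, 1))) stop("occurrence states must be +1 or -1")
  structure(list(states = states,
                 sample_ids = sample_ids %||% rownames(states),
                 class_label = class_label,
                 thresholds = rep(NA_real_, ncol(states))),
            class = "occurrence_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence matrix: %d samples x %d assemblages (class %s)\n",
              nrow(x$states), ncol(x$states), x$class_label))
  cat("  activated fraction per assemblage:",
      paste(sprintf("%.2f", colMeans(x$states == 1)), collapse = " "), "\n")
  invisible(x)
}

#' Write occurrence states and thresholds to TSV
#'
#' @param occ An \code{occurrence_matrix}.
#' @param path Output TSV for the states; thresholds go to
#'   \code{<path>.thresholds.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(sample_id = occ$sample_ids %||% seq_len(nrow(occ$states)),
                   class_label = occ$class_label, occ$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  thr <- data.frame(assemblage = seq_along(occ$thresholds), threshold = occ$thresholds)
  utils::write.table(thr, paste0(path, ".thresholds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
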