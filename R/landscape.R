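#' Single-flip neighbours of a pattern
#'
#' Neighbour patterns differ in exactly one assemblage state (Hamming
#' distance 1); a pattern of length I has exactly I of them.
#'
#' @param sigma A \eqn{\pm 1} vector.
#' @return An I x I matrix; row \code{i} is \code{sigma} with state \code{i}
#'   flipped.
#' @export
neighbor_patterns <- function(sigma) {
  if (!all(sigma %in% c(-1, 1))) stop("pattern entries must be +1 or -1")
  I <- length(sigma)
  out <- matrix(rep(sigma, each = I), I, I)
  diag(out) <- -sigma
  out
}

# ids (1-based) of the I single-flip neighbours of each pattern id
neighbor_ids <- function(ids, I) {
  vapply(seq_len(I),
         function(i) bitwXor(ids - 1L, bitwShiftL(1L, i - 1L)) + 1L,
         integer(length(ids)))
}

#' Build the energy landscape over all patterns
#'
#' For every pattern, the steepest-descent link points to its lowest-energy
#' single-flip neighbour when that neighbour's energy is strictly below the
#' pattern's own, and to the pattern itself otherwise. Patterns that link to
#' themselves are local minimal patterns (LMPs); following links from any
#' pattern terminates at an LMP (energy strictly decreases along the path),
#' and the set of patterns draining into one LMP is its energy basin. Ties
#' among equally minimal strictly-lower neighbours go to the lowest pattern
#' id, making the landscape deterministic.
#'
#' @param energies Either a numeric vector of length \eqn{2^I} indexed by
#'   pattern id, or \code{maxent_params}/\code{mela_maxent} from which
#'   energies are computed.
#' @param I Pattern length; inferred from \code{energies} when omitted.
#' @return A \code{mela_landscape} object: \code{energies},
#'   \code{descent_link}, \code{lmp_ids}, \code{basin_label} (per pattern,
#'   the id of the LMP its descent path reaches), \code{I}, and
#'   \code{params_ref} when fitted parameters were supplied.
#' @export
build_landscape <- function(energies, I = NULL) {
  params_ref <- NULL
  if (inherits(energies, c("maxent_params", "mela_maxent"))) {
    params_ref <- as_maxent_params(energies)
    I <- params_ref$I
    energies <- pattern_energy(enumerate_patterns(I), params_ref)
  }
  M <- length(energies)
  if (is.null(I)) I <- as.integer(round(log2(M)))
  if (2^I != M) stop("'energies' must cover all 2^I patterns")
  ids <- seq_len(M)
  nb <- neighbor_ids(ids, I)                      # M x I neighbour ids
  nbE <- matrix(energies[nb], M, I)
  bestE <- do.call(pmin, as.data.frame(nbE))
  # lowest-id neighbour achieving the minimum: scan columns in neighbour-id order
  link <- ids
  best_id <- rep(NA_integer_, M)
  for (i in seq_len(I)) {
    hit <- nbE[, i] == bestE & (is.na(best_id) | nb[, i] < best_id)
    best_id[hit] <- nb[hit, i]
  }
  strict <- bestE < energies
  link[strict] <- best_id[strict]
  lmp_ids <- ids[link == ids]
  basin <- link
  repeat {
    nxt <- basin[basin]
    if (identical(nxt, basin)) break
    basin <- nxt
  }
  structure(list(energies = energies, descent_link = link, lmp_ids = lmp_ids,
                 basin_label = basin, I = I, params_ref = params_ref),
            class = "mela_landscape")
}

#' Brute-force local-minimum search (independent oracle)
#'
#' Returns \code{\{p : no single-flip neighbour of p has strictly lower
#' energy\}} by direct comparison, independent of the descent-link
#' construction in [build_landscape()].
#'
#' @inheritParams build_landscape
#' @return Integer vector of LMP pattern ids.
#' @export
find_lmps_bruteforce <- function(energies, I = NULL) {
  M <- length(energies)
  if (is.null(I)) I <- as.integer(round(log2(M)))
  if (2^I != M) stop("'energies' must cover all 2^I patterns")
  ids <- seq_len(M)
  is_lmp <- rep(TRUE, M)
  for (i in seq_len(I)) {
    nb <- bitwXor(ids - 1L, bitwShiftL(1L, i - 1L)) + 1L
    is_lmp <- is_lmp & !(energies[nb] < energies)
  }
  ids[is_lmp]
}

#' @export
print.mela_landscape <- function(x, ...) {
  cat(sprintf("energy landscape: %d patterns (I = %d), %d local minimal pattern(s)\n",
              length(x$energies), x$I, length(x$lmp_ids)))
  print(landscape_summary(x))
  invisible(x)
}

#' @export
summary.mela_landscape <- function(object, ...) landscape_summary(object)

#' Table of local minimal patterns
#'
#' @param landscape A \code{mela_landscape}.
#' @return A data.frame, one row per LMP sorted by energy: \code{pattern_id},
#'   \code{active} (comma-separated activated assemblage indices),
#'   \code{energy}, \code{basin_size}.
#' @export
landscape_summary <- function(landscape) {
  lmp <- landscape$lmp_ids
  sizes <- table(factor(landscape$basin_label, levels = lmp))
  active <- vapply(lmp, function(id) {
    a <- which(decode_pattern(id, landscape$I) == 1)
    if (length(a) == 0L) "none" else paste(a, collapse = ",")
  }, character(1L))
  out <- data.frame(pattern_id = lmp, active = active,
                    energy = landscape$energies[lmp],
                    basin_size = as.integer(sizes),
                    stringsAsFactors = FALSE)
  out <- out[order(out$energy, out$pattern_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample energies grouped by participant and visit
#'
#' Evaluates the fitted energy of every observed sample's occurrence pattern
#' and returns the values both as per-participant time series (ordered by
#' visit) and as the pooled per-class energy distribution.
#'
#' @param occ An \code{occurrence_matrix}.
#' @param params \code{maxent_params} or \code{mela_maxent}.
#' @param metadata Metadata covering \code{occ}'s samples (see
#'   [read_metadata()]).
#' @return A data.frame with columns \code{sample_id}, \code{participant_id},
#'   \code{visit_index}, \code{class_label}, \code{pattern_id},
#'   \code{energy}, ordered by participant then visit.
#' @export
sample_energy_series <- function(occ, params, metadata) {
  S <- occ$states
  ids <- occ$sample_ids %||% rownames(S)
  if (is.null(ids)) stop("occurrence matrix carries no sample ids")
  m <- match(ids, metadata$sample_id)
  if (anyNA(m))
    stop("metadata missing for sample(s): ", paste(ids[is.na(m)], collapse = ", "))
  md <- metadata[m, , drop = FALSE]
  out <- data.frame(sample_id = ids,
                    participant_id = md$participant_id,
                    visit_index = md$visit_index,
                    class_label = md$class_label,
                    pattern_id = pattern_id(S),
                    energy = pattern_energy(S, params),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$visit_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a landscape as TSV, GraphML and an optional plot
#'
#' Writes \code{<prefix>_energy.tsv} (pattern id, \eqn{\pm 1} state string,
#' energy at full precision, descent link, basin label, LMP flag),
#' \code{<prefix>_landscape.graphml} (all patterns as nodes, descent links as
#' directed edges, no self-loops; LMPs flagged by a node attribute) and, when
#' \code{plot = TRUE}, \code{<prefix>_landscape.pdf}.
#'
#' @param landscape A \code{mela_landscape}.
#' @param prefix Output path prefix.
#' @param plot Whether to also write the 2-D energy plot (default FALSE).
#' @return Character vector of the files written, invisibly.
#' @export
export_landscape <- function(landscape, prefix, plot = FALSE) {
  ids <- seq_along(landscape$energies)
  P <- enumerate_patterns(landscape$I)
  state_str <- apply(P, 1L, function(s) paste(ifelse(s > 0, "+", "-"), collapse = ""))
  df <- data.frame(pattern_id = ids, state = state_str,
                   energy = sprintf("%.17g", landscape$energies),
                   descent_link = landscape$descent_link,
                   basin_label = landscape$basin_label,
                   is_lmp = ids %in% landscape$lmp_ids,
                   stringsAsFactors = FALSE)
  tsv <- paste0(prefix, "_energy.tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gr <- igraph::make_empty_graph(n = length(ids), directed = TRUE)
  gr <- igraph::set_vertex_attr(gr, "pattern_id", value = ids)
  gr <- igraph::set_vertex_attr(gr, "state", value = state_str)
  gr <- igraph::set_vertex_attr(gr, "energy", value = landscape$energies)
  gr <- igraph::set_vertex_attr(gr, "basin", value = landscape$basin_label)
  gr <- igraph::set_vertex_attr(gr, "is_lmp", value = as.integer(ids %in% landscape$lmp_ids))
  non_self <- ids[landscape$descent_link != ids]
  if (length(non_self) > 0L)
    gr <- igraph::add_edges(gr, rbind(non_self, landscape$descent_link[non_self]))
  gml <- paste0(prefix, "_landscape.graphml")
  igraph::write_graph(gr, gml, format = "graphml")
  files <- c(tsv, gml)
  if (plot) {
    pdf_file <- paste0(prefix, "_landscape.pdf")
    grDevices::pdf(pdf_file, width = 8, height = 5)
    plot(landscape)
    grDevices::dev.off()
    files <- c(files, pdf_file)
  }
  invisible(files)
}

#' @export
#' @rdname export_landscape
#' @param x A \code{mela_landscape}.
#' @param ... Further arguments passed to \code{plot.default}.
plot.mela_landscape <- function(x, ...) {
  ids <- seq_along(x$energies)
  basin <- match(x$basin_label, x$lmp_ids)
  cols <- grDevices::hcl.colors(max(length(x$lmp_ids), 2L), "Dark 3")
  graphics::plot(ids, x$energies, pch = 16, cex = 0.6, col = cols[basin],
                 xlab = "pattern id", ylab = "energy",
                 main = sprintf("energy landscape (%d basins)", length(x$lmp_ids)), ...)
  graphics::points(x$lmp_ids, x$energies[x$lmp_ids], pch = 8, cex = 1.4)
  invisible(x)
}
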