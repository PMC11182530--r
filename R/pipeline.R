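#' Configuration for a full landscape run
#'
#' Collects the workflow parameters: the default operating point is I = 9
#' assemblages, k = 10 retained visits per participant, 26 participants per
#' class in the balanced subset and the upper-25th-percentile activation
#' rule.
#'
#' @param profile,metadata Input TSV paths (ignored when \code{counts_table}/
#'   \code{metadata_table} are given directly).
#' @param out_dir Output directory.
#' @param orientation Profile table orientation (see [read_profile_table()]).
#' @param I Number of assemblages.
#' @param k Retained visits per participant.
#' @param per_class Participants per class in the balanced subset.
#' @param quantile Binarization quantile (0.75 = upper 25th percentile).
#' @param epsilon,tol,max_iter Maximum-entropy fit controls (see
#'   [fit_maxent()]).
#' @param alpha,beta Assemblage-model priors (see [fit_assemblages()]).
#' @param depth Depth used by [to_counts()] when the profile holds relative
#'   abundances.
#' @param seed_lda,seed_subset Seeds for the assemblage fit and the balanced
#'   draw.
#' @param class_labels Allowed class labels.
#' @return A \code{run_config} list.
#' @export
run_config <- function(profile = NULL, metadata = NULL, out_dir = "mela_out",
                       orientation = "samples-as-rows",
                       I = 9L, k = 10L, per_class = 26L, quantile = 0.75,
                       epsilon = 0.1, tol = 1e-5, max_iter = 200000L,
                       alpha = 1 / I, beta = 1 / I, depth = 10000L,
                       seed_lda = 1L, seed_subset = 1L,
                       class_labels = c("CD", "UC", "nonIBD")) {
  stopifnot(I >= 1L, k >= 1L, per_class >= 1L, quantile > 0, quantile < 1,
            epsilon > 0, tol > 0, max_iter >= 1L, depth >= 1L)
  structure(list(profile = profile, metadata = metadata, out_dir = out_dir,
                 orientation = orientation, I = as.integer(I), k = as.integer(k),
                 per_class = as.integer(per_class), quantile = quantile,
                 epsilon = epsilon, tol = tol, max_iter = as.integer(max_iter),
                 alpha = alpha, beta = beta, depth = as.integer(depth),
                 seed_lda = as.integer(seed_lda), seed_subset = as.integer(seed_subset),
                 class_labels = class_labels),
            class = "run_config")
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full energy-landscape workflow
#'
#' Executes the staged analysis: time-series filtering (first \code{k} visits
#' per participant, short participants dropped), assemblage-model fitting on
#' each participant's first sample, assemblage-abundance inference for a
#' class-balanced participant subset, per-class binarization, per-class
#' pairwise maximum-entropy fitting, and per-class landscape construction.
#' All stage outputs and a JSON run manifest (seeds, parameters, shapes,
#' package version) are written under \code{config$out_dir}.
#'
#' @param config A [run_config()].
#' @param counts_table,metadata_table Optional in-memory inputs (a
#'   \code{taxon_profile} and metadata data.frame) used instead of reading
#'   \code{config$profile}/\code{config$metadata}.
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return Invisibly, a list with the fitted \code{model}, per-class
#'   \code{occurrences}, \code{maxent} fits and \code{landscapes}, the
#'   \code{theta} abundances with metadata, and the manifest.
#' @export
run_pipeline <- function(config = run_config(), counts_table = NULL,
                         metadata_table = NULL, verbose = TRUE) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    table <- counts_table %||% read_profile_table(config$profile, config$orientation)
    metadata <- if (!is.null(metadata_table))
      validate_metadata(metadata_table, config$class_labels)
    else read_metadata(config$metadata, config$class_labels)
    if (!table$is_counts) table <- to_counts(table, config$depth)
    pipeline_log(verbose, stage, "%d samples x %d genera, %d participants",
                 nrow(table$values), ncol(table$values),
                 length(unique(metadata$participant_id)))

    stage <- "select_time_series"
    ts <- select_time_series(table, metadata, config$k)
    pipeline_log(verbose, stage, "kept %d samples from %d participants (k = %d)",
                 nrow(ts$table$values), length(unique(ts$metadata$participant_id)),
                 config$k)

    stage <- "fit_assemblages"
    fs <- first_samples(ts$table, ts$metadata)
    model <- fit_assemblages(fs$table, I = config$I, alpha = config$alpha,
                             beta = config$beta, seed = config$seed_lda)
    pipeline_log(verbose, stage, "fitted I = %d on %d first samples (%d sweeps)",
                 config$I, nrow(fs$table$values), model$fit_diagnostics$iterations)

    stage <- "balanced_subset"
    bs <- balanced_subset(ts$table, ts$metadata, per_class = config$per_class,
                          seed = config$seed_subset)
    pipeline_log(verbose, stage, "balanced subset: %d samples (%d per class)",
                 nrow(bs$table$values), config$per_class * config$k)

    stage <- "infer_abundances"
    theta <- infer_abundances(model, bs$table, class_labels = bs$metadata$class_label)

    stage <- "per_class"
    classes <- sort(unique(bs$metadata$class_label))
    occurrences <- list(); maxent <- list(); landscapes <- list()
    for (cl in classes) {
      sel <- bs$metadata$class_label == cl
      th <- structure(list(theta = theta$theta[sel, , drop = FALSE],
                           sample_ids = theta$sample_ids[sel],
                           class_labels = theta$class_labels[sel]),
                      class = "assemblage_abundance")
      occ <- binarize_occurrences(th, quantile = config$quantile)
      fit <- fit_maxent(occ, epsilon = config$epsilon, tol = config$tol,
                        max_iter = config$max_iter)
      land <- build_landscape(fit)
      pipeline_log(verbose, cl, "N = %d, maxent gap %.1e in %d iters, %d LMP(s)",
                   sum(sel), fit$report$max_moment_gap, fit$report$iterations,
                   length(land$lmp_ids))
      occurrences[[cl]] <- occ; maxent[[cl]] <- fit; landscapes[[cl]] <- land
    }

    stage <- "export"
    utils::write.table(
      data.frame(assemblage = rownames(model$phi), model$phi, check.names = FALSE),
      file.path(config$out_dir, "phi.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = theta$sample_ids, class_label = theta$class_labels,
                 theta$theta, check.names = FALSE),
      file.path(config$out_dir, "theta.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (cl in classes) {
      write_occurrences(occurrences[[cl]],
                        file.path(config$out_dir, sprintf("occurrence_%s.tsv", cl)))
      fit <- maxent[[cl]]
      utils::write.table(data.frame(assemblage = seq_along(fit$params$h), h = fit$params$h),
                         file.path(config$out_dir, sprintf("h_%s.tsv", cl)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fit$params$g,
                         file.path(config$out_dir, sprintf("g_%s.tsv", cl)),
                         sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        fit$report[c("iterations", "max_moment_gap", "epsilon", "tol", "converged")],
        file.path(config$out_dir, sprintf("maxent_%s.json", cl)), auto_unbox = TRUE)
      export_landscape(landscapes[[cl]],
                       file.path(config$out_dir, sprintf("class_%s", cl)))
      series <- sample_energy_series(occurrences[[cl]], fit, bs$metadata)
      utils::write.table(series,
                         file.path(config$out_dir, sprintf("energy_series_%s.tsv", cl)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("mela")),
      parameters = config[setdiff(names(config), c("profile", "metadata"))],
      shapes = list(input_samples = nrow(table$values),
                    genera = ncol(table$values),
                    after_time_series = nrow(ts$table$values),
                    lda_training = nrow(fs$table$values),
                    balanced = nrow(bs$table$values)),
      lmp_counts = lapply(landscapes, function(l) length(l$lmp_ids)),
      complete = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(model = model, theta = theta, metadata = bs$metadata,
         occurrences = occurrences, maxent = maxent, landscapes = landscapes,
         manifest = manifest)
  }, error = function(e) {
    jsonlite::write_json(list(complete = FALSE, failed_stage = stage,
                              error = conditionMessage(e)),
                         file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
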