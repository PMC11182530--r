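#' Draw rows from a Dirichlet distribution
#'
#' @param n Number of draws.
#' @param alpha Concentration vector.
#' @return n x length(alpha) matrix of probability vectors.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / k        # numerical underflow guard (tiny alpha)
  x / rowSums(x)
}

#' A structured planted assemblage composition
#'
#' Builds an I x F row-stochastic matrix in which each assemblage
#' concentrates most of its mass (\code{dominance}) on its own block of
#' genera, decaying geometrically within the block, with the remainder spread
#' uniformly — the kind of dominant-genus structure observed in real gut
#' assemblages (single genera carrying weights up to ~0.9).
#'
#' @param I Number of assemblages.
#' @param F Vocabulary size (must be >= I).
#' @param dominance Mass placed on the assemblage's own genus block
#'   (default 0.9).
#' @return I x F matrix with rows summing to 1; genus names \code{g001}, ...
#' @export
planted_phi <- function(I, F, dominance = 0.9) {
  if (F < I) stop("'F' must be >= I")
  block <- floor(F / I)
  phi <- matrix((1 - dominance) / (F - block), I, F)
  for (i in seq_len(I)) {
    idx <- ((i - 1L) * block + 1L):(i * block)
    w <- 0.5^(seq_along(idx) - 1L)
    phi[i, idx] <- dominance * w / sum(w)
  }
  colnames(phi) <- sprintf("g%03d", seq_len(F))
  rownames(phi) <- paste0("A", seq_len(I))
  phi / rowSums(phi)
}

#' Specification of a synthetic longitudinal cohort
#'
#' Collects the knobs of the cohort generator; the defaults reproduce the
#' structure of an iHMP-style IBD cohort: 65 CD, 38 UC and 27 non-IBD
#' participants with a full series of 10 visits, plus 20 extra short
#' participants (fewer than 10 visits) so the time-series filter is
#' exercised, with Dirichlet-multinomial genus counts generated
#' assemblage-then-genus from a planted composition.
#'
#' @param participants_per_class Named vector, class label -> number of
#'   participants with a full visit series.
#' @param visits Visits per full participant (default 10).
#' @param n_short Extra participants with fewer than \code{visits} samples
#'   (default 20), assigned round-robin to the classes.
#' @param phi Planted I x F assemblage composition (default
#'   \code{planted_phi(9, 40)}).
#' @param theta_prior Symmetric Dirichlet prior for participant-level
#'   assemblage mixtures (default 0.5: strongly imbalanced mixtures, matching
#'   the single-assemblage dominance seen in real data).
#' @param within_concentration Concentration of per-visit mixtures around the
#'   participant-level mixture (default 50: visits from one participant
#'   resemble each other).
#' @param depth Reads per sample (default 10000).
#' @param seed Integer seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(participants_per_class = c(CD = 65, UC = 38, nonIBD = 27),
                        visits = 10L, n_short = 20L,
                        phi = planted_phi(9L, 40L),
                        theta_prior = 0.5, within_concentration = 50,
                        depth = 10000L, seed = 1L) {
  if (any(participants_per_class < 1)) stop("participant counts must be positive")
  if (any(abs(rowSums(phi) - 1) > 1e-9)) stop("'phi' rows must sum to 1")
  if (depth < 1) stop("'depth' must be >= 1")
  structure(list(participants_per_class = participants_per_class,
                 visits = as.integer(visits), n_short = as.integer(n_short),
                 phi = phi, theta_prior = theta_prior,
                 within_concentration = within_concentration,
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a longitudinal cohort of genus count profiles
#'
#' Generates every sample by the assemblage generative process: a
#' participant-level assemblage mixture is drawn from a symmetric Dirichlet,
#' each visit's mixture \eqn{\theta} is drawn from a Dirichlet centred on it,
#' and \code{depth} occurrence events each pick an assemblage from
#' \eqn{\theta} and then a genus from that assemblage's composition
#' \eqn{\phi_i} — so the per-sample genus probabilities are
#' \eqn{\theta \phi}. Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list: \code{table} (a \code{taxon_profile} of counts),
#'   \code{metadata} (sample_id, participant_id, visit_index, class_label),
#'   \code{theta} (the true per-sample mixtures, for tests) and \code{spec}.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  set.seed(spec$seed)
  I <- nrow(spec$phi); F_ <- ncol(spec$phi)
  classes <- names(spec$participants_per_class)
  n_full <- sum(spec$participants_per_class)
  part_class <- rep(classes, times = spec$participants_per_class)
  part_visits <- rep(spec$visits, n_full)
  if (spec$n_short > 0L) {
    short_class <- classes[((seq_len(spec$n_short) - 1L) %% length(classes)) + 1L]
    # deterministic cycle of short lengths so cohort shapes depend only on the spec
    short_visits <- rep_len(seq_len(max(spec$visits - 1L, 1L)), spec$n_short)
    part_class <- c(part_class, short_class)
    part_visits <- c(part_visits, short_visits)
  }
  n_part <- length(part_class)
  part_ids <- sprintf("P%03d", seq_len(n_part))
  n_samples <- sum(part_visits)

  counts <- matrix(0L, n_samples, F_)
  theta_all <- matrix(0, n_samples, I)
  sample_id <- character(n_samples)
  participant_id <- character(n_samples)
  visit_index <- integer(n_samples)
  class_label <- character(n_samples)
  row <- 0L
  for (p in seq_len(n_part)) {
    m <- drop(rdirichlet(1L, rep(spec$theta_prior, I)))
    for (v in seq_len(part_visits[p])) {
      row <- row + 1L
      theta <- drop(rdirichlet(1L, spec$within_concentration * m + 1e-8))
      probs <- drop(theta %*% spec$phi)
      counts[row, ] <- stats::rmultinom(1L, spec$depth, probs)
      theta_all[row, ] <- theta
      sample_id[row] <- sprintf("%s_V%02d", part_ids[p], v)
      participant_id[row] <- part_ids[p]
      visit_index[row] <- v
      class_label[row] <- part_class[p]
    }
  }
  rownames(counts) <- sample_id
  colnames(counts) <- colnames(spec$phi)
  rownames(theta_all) <- sample_id
  metadata <- data.frame(sample_id = sample_id, participant_id = participant_id,
                         visit_index = visit_index, class_label = class_label,
                         stringsAsFactors = FALSE)
  list(table = taxon_profile(counts), metadata = metadata,
       theta = theta_all, spec = spec)
}

#' Draw occurrence patterns exactly from a Boltzmann distribution
#'
#' Enumerates all \eqn{2^I} patterns, computes their exact probabilities
#' under the pairwise maximum-entropy model, and draws \code{n} independent
#' patterns by categorical sampling. Used as the independent sampler in
#' parameter-recovery tests and as the \code{simulate} method of fitted
#' models.
#'
#' @param params \code{maxent_params} or \code{mela_maxent}.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return An \code{occurrence_matrix} of n patterns.
#' @export
sample_boltzmann_patterns <- function(params, n, seed = 1L) {
  p <- as_maxent_params(params)
  if (n < 1L) stop("'n' must be >= 1")
  patterns <- enumerate_patterns(p$I)
  prob <- pattern_distribution(p, patterns)
  set.seed(seed)
  draws <- sample.int(length(prob), n, replace = TRUE, prob = prob)
  occurrence_matrix(patterns[draws, , drop = FALSE],
                    sample_ids = sprintf("s%06d", seq_len(n)))
}

#' Write a small self-contained demo dataset
#'
#' Generates a miniature cohort (3 classes x 26 participants x 10 visits,
#' F = 40 genera, 9 planted assemblages by default), writes the abundance and
#' metadata TSVs plus their md5 checksums under \code{dir}, and returns the
#' file paths.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param depth Reads per sample (default 2000 to keep the fixture small).
#' @return Named character vector of the files written, invisibly.
#' @export
make_demo_fixture <- function(dir = tempfile("mela_demo_"), seed = 1L, depth = 2000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(participants_per_class = c(CD = 26, UC = 26, nonIBD = 26),
                      n_short = 6L, depth = depth, seed = seed)
  sim <- simulate_cohort(spec)
  profile <- file.path(dir, "genus_counts.tsv")
  meta <- file.path(dir, "metadata.tsv")
  write_profile_table(sim$table, profile)
  write_profile_table(sim$metadata, meta)
  sums <- tools::md5sum(c(profile, meta))
  checks <- file.path(dir, "md5sums.txt")
  writeLines(sprintf("%s  %s", sums, basename(names(sums))), checks)
  invisible(c(profile = profile, metadata = meta, checksums = checks))
}
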