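#' Convert relative abundances to pseudo-counts
#'
#' The assemblage model is a generative model of discrete occurrence events,
#' so it needs count input. Tables shipped as relative abundances are rescaled
#' to a common depth: each row is multiplied by \code{depth}, rounded
#' half-to-even, and repaired by a largest-remainder step so the row total is
#' preserved exactly.
#'
#' @param table A \code{taxon_profile} with entries in \eqn{[0, 1]}.
#' @param depth Target row total (reads per sample), default 10000.
#' @return A \code{taxon_profile} of integer counts.
#' @export
to_counts <- function(table, depth = 10000L) {
  if (!inherits(table, "taxon_profile")) stop("'table' must be a taxon_profile")
  if (depth < 1) stop("'depth' must be >= 1")
  if (any(table$values > 1))
    stop("to_counts expects relative abundances in [0, 1]")
  values <- t(apply(table$values, 1L, round_preserving_total, depth = depth))
  dimnames(values) <- dimnames(table$values)
  taxon_profile(values)
}

# Round depth * x to integers whose sum equals round(depth * sum(x)):
# half-even rounding first, then move single units into/out of the entries
# whose fractional parts make the adjustment cheapest.
round_preserving_total <- function(x, depth) {
  if (all(x == 0)) return(x)
  scaled <- x * depth
  r <- round(scaled)
  target <- round(sum(scaled))
  d <- target - sum(r)
  frac <- scaled - floor(scaled)
  while (d != 0) {
    if (d > 0) {
      cand <- which(r == floor(scaled))            # rounded down; bump the largest remainder
      i <- cand[order(-frac[cand], cand)][1L]
      r[i] <- r[i] + 1
      d <- d - 1
    } else {
      cand <- which(r > floor(scaled) & r > 0)     # rounded up; drop the smallest remainder
      i <- cand[order(frac[cand], cand)][1L]
      r[i] <- r[i] - 1
      d <- d + 1
    }
  }
  r
}

dirichlet_elog <- function(m) {
  # E[log x] under Dirichlet with parameter rows m
  digamma(m) - digamma(rowSums(m))
}

# One batch of variational document updates with fixed topics.
# Returns gamma (N x I) and the sufficient statistics for the topic update.
lda_e_step <- function(X, exp_elog_beta, doc_prior, inner_iter = 100L, inner_tol = 1e-3) {
  N <- nrow(X); I <- nrow(exp_elog_beta)
  gamma <- matrix(1, N, I)
  exp_elog_theta <- exp(dirichlet_elog(gamma))
  phinorm <- exp_elog_theta %*% exp_elog_beta + 1e-100
  for (it in seq_len(inner_iter)) {
    gamma_new <- doc_prior + exp_elog_theta * ((X / phinorm) %*% t(exp_elog_beta))
    delta <- mean(abs(gamma_new - gamma))
    gamma <- gamma_new
    exp_elog_theta <- exp(dirichlet_elog(gamma))
    phinorm <- exp_elog_theta %*% exp_elog_beta + 1e-100
    if (delta < inner_tol) break
  }
  list(gamma = gamma,
       sstats = t(exp_elog_theta) %*% (X / phinorm))
}

#' Fit the microbial assemblage model (latent Dirichlet allocation)
#'
#' Groups genera into \code{I} assemblages by their co-occurrence across
#' samples, using batch variational Bayes for the standard LDA generative
#' model: each sequencing read ("occurrence event") draws an assemblage from
#' the sample's mixture \eqn{\theta_n} and then a genus from that assemblage's
#' composition \eqn{\phi_i}. Typically fitted on one sample per participant
#' to avoid within-participant redundancy.
#'
#' @param counts A \code{taxon_profile} of integer counts (see [to_counts()]).
#' @param I Number of assemblages (default 9).
#' @param alpha Symmetric Dirichlet prior on each assemblage's genus
#'   composition \eqn{\phi} (default \code{1/I}).
#' @param beta Symmetric Dirichlet prior on each sample's assemblage mixture
#'   \eqn{\theta} (default \code{1/I}).
#' @param seed Integer seed for the variational initialisation.
#' @param max_iter Maximum variational EM sweeps (default 200).
#' @param tol Relative change in the data log-likelihood (under the point
#'   estimates) at which to stop (default 1e-6).
#' @return A \code{mela_lda} object with \code{phi} (I x F row-stochastic
#'   matrix, assemblages ordered by descending dominant-genus weight),
#'   \code{lambda} (variational topic parameters, used for inference),
#'   priors, \code{genus_names}, \code{seed} and \code{fit_diagnostics}.
#' @seealso [infer_abundances()], [dominant_genera()]
#' @export
fit_assemblages <- function(counts, I = 9L, alpha = 1 / I, beta = 1 / I,
                            seed = 1L, max_iter = 200L, tol = 1e-6) {
  if (!inherits(counts, "taxon_profile")) stop("'counts' must be a taxon_profile")
  if (!counts$is_counts)
    stop("assemblage fitting needs integer counts; convert with to_counts()")
  X <- counts$values
  zero <- rowSums(X) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(counts$sample_ids[zero], collapse = ", "))
  if (I < 1L) stop("'I' must be >= 1")
  if (nrow(X) < I) stop("need at least I samples to fit I assemblages")
  F_ <- ncol(X)

  set.seed(seed)
  lambda <- matrix(stats::rgamma(I * F_, shape = 100, rate = 100), I, F_)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    exp_elog_beta <- exp(dirichlet_elog(lambda))
    es <- lda_e_step(X, exp_elog_beta, doc_prior = beta)
    lambda <- alpha + exp_elog_beta * es$sstats
    phi_hat <- lambda / rowSums(lambda)
    theta_hat <- es$gamma / rowSums(es$gamma)
    ll <- sum(X * log(theta_hat %*% phi_hat + 1e-300))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  phi <- lambda / rowSums(lambda)
  # stable human-readable labels: order assemblages by descending top-genus weight
  ord <- order(-apply(phi, 1L, max), seq_len(I))
  phi <- phi[ord, , drop = FALSE]
  lambda <- lambda[ord, , drop = FALSE]
  rownames(phi) <- rownames(lambda) <- paste0("A", seq_len(I))
  colnames(phi) <- colnames(lambda) <- counts$genus_names
  structure(list(phi = phi, lambda = lambda, I = I,
                 alpha = alpha, beta = beta,
                 genus_names = counts$genus_names, seed = seed,
                 fit_diagnostics = list(algorithm = "batch variational Bayes",
                                        iterations = iters,
                                        objective_trace = trace,
                                        converged = converged)),
            class = "mela_lda")
}

#' @export
print.mela_lda <- function(x, ...) {
  cat(sprintf("microbial assemblage model: I = %d assemblages over F = %d genera\n",
              x$I, length(x$genus_names)))
  cat(sprintf("  %s, %d sweeps, %sconverged (seed %d)\n",
              x$fit_diagnostics$algorithm, x$fit_diagnostics$iterations,
              if (x$fit_diagnostics$converged) "" else "NOT ", x$seed))
  top <- dominant_genera(x, top_k = 1L)
  for (i in seq_len(x$I))
    cat(sprintf("  #%d: %s (%.2f)\n", i, top[[i]]$genus[1L], top[[i]]$weight[1L]))
  invisible(x)
}

#' @export
coef.mela_lda <- function(object, ...) object$phi

#' Infer per-sample assemblage abundances with a fitted model
#'
#' Runs the variational document update with the assemblage compositions held
#' fixed, so the training subset determines \eqn{\phi} and every sample gets
#' an assemblage mixture \eqn{\theta_n} on the same basis.
#'
#' @param model A \code{mela_lda} fit.
#' @param counts A \code{taxon_profile} of integer counts over the same genus
#'   vocabulary (any column order).
#' @param class_labels Optional per-sample class labels carried through to the
#'   result (recycled from metadata by callers).
#' @return An \code{assemblage_abundance} object: \code{theta} (N x I
#'   row-stochastic), \code{sample_ids}, \code{class_labels}.
#' @export
infer_abundances <- function(model, counts, class_labels = NULL) {
  if (!inherits(model, "mela_lda")) stop("'model' must be a mela_lda fit")
  if (!inherits(counts, "taxon_profile")) stop("'counts' must be a taxon_profile")
  if (!counts$is_counts)
    stop("inference needs integer counts; convert with to_counts()")
  missing_g <- setdiff(model$genus_names, counts$genus_names)
  extra_g <- setdiff(counts$genus_names, model$genus_names)
  if (length(missing_g) > 0L || length(extra_g) > 0L)
    stop("vocabulary mismatch; missing: [", paste(missing_g, collapse = ", "),
         "], extra: [", paste(extra_g, collapse = ", "), "]")
  X <- counts$values[, model$genus_names, drop = FALSE]
  exp_elog_beta <- exp(dirichlet_elog(model$lambda))
  es <- lda_e_step(X, exp_elog_beta, doc_prior = model$beta)
  theta <- es$gamma / rowSums(es$gamma)
  rownames(theta) <- counts$sample_ids
  colnames(theta) <- rownames(model$phi)
  if (!is.null(class_labels) && length(class_labels) != nrow(theta))
    stop("'class_labels' must have one entry per sample")
  structure(list(theta = theta, sample_ids = counts$sample_ids,
                 class_labels = class_labels),
            class = "assemblage_abundance")
}

#' @export
#' @rdname infer_abundances
#' @param object,newdata,... \code{predict} method arguments;
#'   \code{newdata} is the count table.
predict.mela_lda <- function(object, newdata, ...) infer_abundances(object, newdata, ...)

#' @export
print.assemblage_abundance <- function(x, ...) {
  cat(sprintf("assemblage abundances: %d samples x %d assemblages\n",
              nrow(x$theta), ncol(x$theta)))
  if (!is.null(x$class_labels)) print(table(x$class_labels))
  invisible(x)
}

#' Rank each assemblage's dominant genera
#'
#' @param model A \code{mela_lda} fit.
#' @param top_k How many genera per assemblage (default 5); ties in weight are
#'   broken alphabetically.
#' @return A list (one element per assemblage) of data.frames with columns
#'   \code{genus} and \code{weight}, sorted by descending weight.
#' @export
dominant_genera <- function(model, top_k = 5L) {
  phi <- model$phi
  if (top_k < 1L || top_k > ncol(phi)) stop("'top_k' must be in 1..F")
  out <- lapply(seq_len(nrow(phi)), function(i) {
    w <- phi[i, ]
    ord <- order(-w, names(w))[seq_len(top_k)]
    data.frame(genus = names(w)[ord], weight = unname(w[ord]),
               stringsAsFactors = FALSE)
  })
  names(out) <- rownames(phi)
  out
}

#' Format the dominant-genera table as text
#'
#' @param model A \code{mela_lda} fit.
#' @param top_k Genera per assemblage.
#' @return Character vector, one line per assemblage, weights to 2 decimals.
#' @export
format_dominant_genera <- function(model, top_k = 2L) {
  dg <- dominant_genera(model, top_k)
  vapply(seq_along(dg), function(i) {
    d <- dg[[i]]
    sprintf("%d | %s", i,
            paste(sprintf("*%s* (%.2f)", d$genus, d$weight), collapse = " and "))
  }, character(1L))
}

#' Shared-dominant-genus network between assemblages
#'
#' Two assemblages are linked when their top-\code{top_k} dominant genus sets
#' intersect; the edge weight is the intersection size. An assemblage whose
#' dominant set is disjoint from all others appears in no edge (an isolated
#' node in the plotted network).
#'
#' @param model A \code{mela_lda} fit.
#' @param top_k Dominant set size (default 5).
#' @return A data.frame with columns \code{from}, \code{to} (assemblage
#'   indices, from < to) and \code{weight}.
#' @export
shared_genus_network <- function(model, top_k = 5L) {
  sets <- lapply(dominant_genera(model, top_k), `[[`, "genus")
  I <- length(sets)
  edges <- list()
  for (i in seq_len(max(I - 1L, 0L))) for (j in seq((i + 1L), I)) {
    w <- length(intersect(sets[[i]], sets[[j]]))
    if (w > 0L) edges[[length(edges) + 1L]] <- data.frame(from = i, to = j, weight = w)
  }
  if (length(edges) == 0L)
    return(data.frame(from = integer(0), to = integer(0), weight = integer(0)))
  do.call(rbind, edges)
}

#' Compare assemblage abundance between classes
#'
#' Per-class mean abundance plus a Kruskal-Wallis rank test per assemblage.
#' No multiplicity correction is applied; with I around 9 the raw p-values
#' are reported as-is.
#'
#' @param theta N x I abundance matrix or an \code{assemblage_abundance}.
#' @param class_labels Length-N class labels (taken from the
#'   \code{assemblage_abundance} if omitted).
#' @return A data.frame with one row per assemblage: per-class means,
#'   the Kruskal-Wallis statistic and its p-value.
#' @export
compare_class_abundance <- function(theta, class_labels = NULL) {
  if (inherits(theta, "assemblage_abundance")) {
    if (is.null(class_labels)) class_labels <- theta$class_labels
    theta <- theta$theta
  }
  if (is.null(class_labels)) stop("class labels are required")
  cl <- factor(class_labels)
  if (nlevels(cl) < 2L) stop("need at least 2 classes")
  if (any(table(cl) < 2L)) stop("every class needs at least 2 samples")
  res <- lapply(seq_len(ncol(theta)), function(i) {
    if (length(unique(theta[, i])) == 1L) {
      # fully tied column: no rank variation, the statistic degenerates to 0
      kw <- list(statistic = 0, p.value = 1)
    } else {
      kw <- stats::kruskal.test(theta[, i], cl)
    }
    means <- tapply(theta[, i], cl, mean)
    out <- data.frame(assemblage = i, statistic = unname(kw$statistic),
                      p_value = unname(kw$p.value))
    for (lv in levels(cl)) out[[paste0("mean_", lv)]] <- unname(means[[lv]])
    out
  })
  do.call(rbind, res)
}
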