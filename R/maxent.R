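#' Enumerate all +/-1 assemblage patterns
#'
#' @param I Number of assemblages (1..20; the landscape is built by exact
#'   enumeration of all \eqn{2^I} patterns, which is exponential in I).
#' @return A \eqn{2^I \times I} matrix of \eqn{\pm 1}; row \code{p} is the
#'   pattern with id \code{p} (see [pattern_id()]); row 1 is all \eqn{-1}.
#' @export
enumerate_patterns <- function(I) {
  if (I < 1L || I > 20L)
    stop("'I' must be in 1..20: enumeration costs 2^I and is refused beyond I = 20")
  ids <- seq_len(2^I) - 1L
  P <- vapply(seq_len(I), function(i) ifelse(bitwAnd(ids, bitwShiftL(1L, i - 1L)) > 0L, 1, -1),
              numeric(length(ids)))
  matrix(P, ncol = I)
}

#' Pattern id of an activity configuration
#'
#' The all-inactive pattern has id 1 and an active assemblage \code{i}
#' contributes \eqn{2^{i-1}}: \code{id = 1 + sum(2^(i-1))} over activated
#' assemblages. Under this convention the pattern with only assemblage #6
#' active is P-#33 and the pattern with assemblages #4 and #8 active is
#' P-#137.
#'
#' @param sigma A \eqn{\pm 1} vector (or matrix with patterns as rows).
#' @return Integer id(s) in \code{1..2^I}.
#' @export
pattern_id <- function(sigma) {
  if (is.matrix(sigma)) return(apply(sigma, 1L, pattern_id))
  if (!all(sigma %in% c(-1, 1))) stop("pattern entries must be +1 or -1")
  1L + sum(bitwShiftL(1L, which(sigma == 1) - 1L))
}

#' @rdname pattern_id
#' @param id Pattern id in \code{1..2^I}.
#' @param I Pattern length.
#' @export
decode_pattern <- function(id, I) {
  if (any(id < 1L) || any(id > 2^I)) stop("pattern id out of range 1..2^I")
  if (length(id) > 1L) return(t(vapply(id, decode_pattern, numeric(I), I = I)))
  ifelse(bitwAnd(id - 1L, bitwShiftL(1L, seq_len(I) - 1L)) > 0L, 1, -1)
}

#' Energy of assemblage patterns
#'
#' \deqn{E(\sigma | h, g) = -\sum_i h_i \sigma_i -
#'   \frac{1}{2} \sum_i \sum_{j \ne i} g_{ij} \sigma_i \sigma_j,}
#' the Ising/Boltzmann energy with kT = 1; low energy means high probability
#' and a stable community configuration.
#'
#' @param sigma A \eqn{\pm 1} vector, or a matrix with patterns as rows.
#' @param params A \code{maxent_params} (or fitted \code{mela_maxent}) with
#'   fields \code{h} and \code{g}.
#' @return Energy value(s).
#' @export
pattern_energy <- function(sigma, params) {
  p <- as_maxent_params(params)
  if (!is.matrix(sigma)) sigma <- matrix(sigma, nrow = 1L)
  if (ncol(sigma) != length(p$h)) stop("pattern length does not match params")
  drop(-(sigma %*% p$h) - 0.5 * rowSums((sigma %*% p$g) * sigma))
}

#' Construct pairwise maximum-entropy parameters
#'
#' @param h Length-I field vector (occurrence tendency; low h, low energy
#'   when inactive).
#' @param g I x I symmetric interaction matrix with zero diagonal (positive =
#'   co-occurrence promoting).
#' @return A \code{maxent_params} object.
#' @export
maxent_params <- function(h, g = matrix(0, length(h), length(h))) {
  h <- as.numeric(h)
  g <- as.matrix(g)
  if (nrow(g) != length(h) || ncol(g) != length(h)) stop("'g' must be I x I")
  if (max(abs(g - t(g))) > 1e-12) stop("'g' must be symmetric")
  if (any(diag(g) != 0)) stop("'g' must have zero diagonal")
  structure(list(h = h, g = (g + t(g)) / 2, I = length(h)), class = "maxent_params")
}

as_maxent_params <- function(x) {
  if (inherits(x, "maxent_params")) return(x)
  if (inherits(x, "mela_maxent")) return(x$params)
  if (is.list(x) && !is.null(x$h) && !is.null(x$g)) return(maxent_params(x$h, x$g))
  stop("cannot interpret 'params'")
}

#' Boltzmann distribution over all patterns
#'
#' \deqn{P(\sigma | h, g) = \exp[-E(\sigma)] / \sum_{\sigma'} \exp[-E(\sigma')]}
#' computed by exact enumeration with a log-sum-exp stable normalisation.
#'
#' @param params \code{maxent_params} or \code{mela_maxent}.
#' @param patterns Optional pre-computed [enumerate_patterns()] matrix.
#' @return Probability vector of length \eqn{2^I}, indexed by pattern id.
#' @export
pattern_distribution <- function(params, patterns = NULL) {
  p <- as_maxent_params(params)
  if (is.null(patterns)) patterns <- enumerate_patterns(p$I)
  logw <- -pattern_energy(patterns, p)
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Empirical first and second moments of occurrence data
#'
#' \eqn{\langle\sigma_i\rangle = \frac{1}{N}\sum_n \sigma_i^n} and
#' \eqn{\langle\sigma_i\sigma_j\rangle = \frac{1}{N}\sum_n \sigma_i^n
#' \sigma_j^n}; these are the constraints the maximum-entropy model matches.
#'
#' @param occ An \code{occurrence_matrix} or plain \eqn{\pm 1} matrix.
#' @return List with \code{first} (length I) and \code{second} (I x I,
#'   unit diagonal).
#' @export
empirical_moments <- function(occ) {
  S <- if (inherits(occ, "occurrence_matrix")) occ$states else as.matrix(occ)
  if (nrow(S) == 0L) stop("empty occurrence matrix")
  if (!all(S %in% c(-1, 1))) stop("occurrence states must be +1 or -1")
  list(first = colMeans(S), second = crossprod(S) / nrow(S))
}

#' Exact model moments under the Boltzmann distribution
#'
#' @param params \code{maxent_params} or \code{mela_maxent}.
#' @param patterns Optional pre-computed pattern matrix.
#' @return List with \code{first} and \code{second} as in
#'   [empirical_moments()], computed by full enumeration (no sampling).
#' @export
model_moments <- function(params, patterns = NULL) {
  p <- as_maxent_params(params)
  if (is.null(patterns)) patterns <- enumerate_patterns(p$I)
  prob <- pattern_distribution(p, patterns)
  list(first = drop(crossprod(patterns, prob)),
       second = crossprod(patterns, patterns * prob))
}

#' Log-likelihood of occurrence data under maximum-entropy parameters
#'
#' @param occ Occurrence data (\code{occurrence_matrix} or \eqn{\pm 1} matrix).
#' @param params \code{maxent_params} or \code{mela_maxent}.
#' @return \eqn{\sum_n \log P(\sigma^n | h, g)} (always \eqn{\le 0}).
#' @export
maxent_log_likelihood <- function(occ, params) {
  S <- if (inherits(occ, "occurrence_matrix")) occ$states else as.matrix(occ)
  p <- as_maxent_params(params)
  prob <- pattern_distribution(p)
  sum(log(prob[pattern_id(S)]))
}

# Core moment-matching loop on precomputed empirical moments.
#
# The mean log-likelihood under the empirical distribution is the exponential
# family dual, h . <s>_emp + sum_{i<j} g_ij <s_i s_j>_emp - log Z, so it can
# be tracked (and used for the monotonicity-preserving step control) from the
# empirical moments alone, without the raw patterns.
fit_maxent_moments <- function(emp, I, epsilon, tol, max_iter,
                               n_samples = NA_integer_, adapt = TRUE) {
  patterns <- enumerate_patterns(I)
  off <- upper.tri(matrix(0, I, I))
  state <- function(h, g) {
    logw <- patterns %*% h + 0.5 * rowSums((patterns %*% g) * patterns)
    m <- max(logw)
    lse <- m + log(sum(exp(logw - m)))
    list(prob = drop(exp(logw - lse)),
         ll = sum(h * emp$first) + sum(g[off] * emp$second[off]) - lse)
  }
  h <- numeric(I)
  g <- matrix(0, I, I)
  st <- state(h, g)
  eps <- epsilon
  ll_trace <- numeric(max_iter)
  gap <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ll_trace[it] <- st$ll
    d1 <- emp$first - drop(crossprod(patterns, st$prob))
    d2 <- emp$second - crossprod(patterns, patterns * st$prob)
    gap <- max(abs(d1), abs(d2[off]))
    if (gap < tol) break
    if (adapt) {
      # keep the moment-gap update direction but backtrack the step until the
      # (concave) likelihood does not decrease, then let it grow again
      repeat {
        h2 <- h + eps * d1
        g2 <- g
        g2[off] <- g[off] + eps * d2[off]
        g2[lower.tri(g2)] <- t(g2)[lower.tri(g2)]
        st2 <- state(h2, g2)
        if (st2$ll >= st$ll || eps < 1e-10) break
        eps <- eps / 2
      }
      h <- h2; g <- g2; st <- st2
      eps <- min(eps * 1.1, 100 * epsilon)
    } else {
      h <- h + eps * d1
      g[off] <- g[off] + eps * d2[off]
      g[lower.tri(g)] <- t(g)[lower.tri(g)]
      st <- state(h, g)
    }
  }
  n_mult <- if (is.na(n_samples)) 1 else n_samples
  list(params = maxent_params(h, g),
       report = list(iterations = it, max_moment_gap = gap,
                     log_likelihood_trace = n_mult * ll_trace[seq_len(it)],
                     epsilon = epsilon, tol = tol,
                     converged = gap < tol, n = n_samples))
}

#' Fit the pairwise maximum-entropy (Ising) model to occurrence data
#'
#' Maximum-likelihood fitting by moment-matching gradient ascent: starting
#' from \code{h = 0, g = 0} (the uniform model), each step moves the
#' parameters by \code{epsilon} times the gap between empirical and exact
#' model moments,
#' \deqn{h_i \leftarrow h_i + \epsilon(\langle\sigma_i\rangle_{emp} -
#'   \langle\sigma_i\rangle_{mod}), \quad
#'   g_{ij} \leftarrow g_{ij} + \epsilon(\langle\sigma_i\sigma_j\rangle_{emp}
#'   - \langle\sigma_i\sigma_j\rangle_{mod}),}
#' with model moments computed by full enumeration of the \eqn{2^I} patterns.
#' The likelihood is concave, so for small enough \code{epsilon} the trace is
#' non-decreasing and the moment gap converges to 0 whenever the empirical
#' moments are realisable in the interior (no assemblage permanently
#' active/inactive and no perfectly locked pair).
#'
#' @param occ An \code{occurrence_matrix} for one class (or plain \eqn{\pm 1}
#'   matrix).
#' @param epsilon Step size (default 0.1).
#' @param tol Convergence tolerance on the largest absolute moment gap
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 50000); non-convergence returns the
#'   fit with \code{converged = FALSE} and a warning.
#' @param adapt Step-size control (default TRUE): the step keeps the
#'   moment-gap direction but is halved whenever it would decrease the
#'   likelihood and allowed to grow again afterwards, which preserves the
#'   monotone likelihood trace while converging much faster than a fixed
#'   step on ill-conditioned fixtures. \code{FALSE} gives the plain fixed-
#'   \code{epsilon} iteration.
#' @return A \code{mela_maxent} object: \code{params} (\code{h}, \code{g}),
#'   \code{moments} (empirical), \code{report} (iterations, final moment gap,
#'   per-iteration log-likelihood trace, converged flag), \code{class_label},
#'   \code{n}.
#' @seealso [pattern_energy()], [build_landscape()],
#'   [sample_boltzmann_patterns()]
#' @export
fit_maxent <- function(occ, epsilon = 0.1, tol = 1e-5, max_iter = 50000L,
                       adapt = TRUE) {
  S <- if (inherits(occ, "occurrence_matrix")) occ$states else as.matrix(occ)
  if (!all(S %in% c(-1, 1))) stop("occurrence states must be +1 or -1")
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  emp <- empirical_moments(S)
  I <- ncol(S)
  fit <- fit_maxent_moments(emp, I, epsilon, tol, max_iter,
                            n_samples = nrow(S), adapt = adapt)
  if (!fit$report$converged)
    warning(sprintf("moment gap %.2e did not reach tol %.2e in %d iterations",
                    fit$report$max_moment_gap, tol, max_iter))
  structure(list(params = fit$params, moments = emp, report = fit$report,
                 class_label = if (inherits(occ, "occurrence_matrix")) occ$class_label else NA_character_,
                 n = nrow(S)),
            class = "mela_maxent")
}

#' @export
print.mela_maxent <- function(x, ...) {
  cat(sprintf("pairwise maximum-entropy model: I = %d assemblages, N = %d samples (class %s)\n",
              x$params$I, x$n, x$class_label))
  cat(sprintf("  %d iterations, max moment gap %.2e (%sconverged)\n",
              x$report$iterations, x$report$max_moment_gap,
              if (x$report$converged) "" else "NOT "))
  cat("  h:", paste(sprintf("% .3f", x$params$h), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mela_maxent <- function(object, ...) {
  ll <- if (length(object$report$log_likelihood_trace) > 0)
    utils::tail(object$report$log_likelihood_trace, 1L) else NA_real_
  structure(list(fit = object, logLik = ll,
                 g_range = range(object$params$g[upper.tri(object$params$g)])),
            class = "summary.mela_maxent")
}

#' @export
print.summary.mela_maxent <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  log-likelihood %.3f; g range [%.3f, %.3f]\n",
              x$logLik, x$g_range[1L], x$g_range[2L]))
  cat("  g (interactions):\n")
  print(round(x$fit$params$g, 3L))
  invisible(x)
}

#' @export
coef.mela_maxent <- function(object, ...) list(h = object$params$h, g = object$params$g)

#' @export
logLik.mela_maxent <- function(object, ...) {
  ll <- utils::tail(object$report$log_likelihood_trace, 1L)
  I <- object$params$I
  structure(ll, df = I + I * (I - 1) / 2, nobs = object$n, class = "logLik")
}

#' @export
#' @rdname sample_boltzmann_patterns
#' @param object A fitted \code{mela_maxent}.
#' @param nsim Number of patterns to draw.
#' @param seed Integer seed.
#' @param ... Unused.
simulate.mela_maxent <- function(object, nsim = 1L, seed = NULL, ...) {
  sample_boltzmann_patterns(object$params, n = nsim, seed = seed %||% 1L)
}
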