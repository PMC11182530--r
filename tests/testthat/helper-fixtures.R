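# Small in-code fixtures shared across test files.

# A miniature longitudinal cohort: 3 classes x 4 participants x 6 visits,
# 2 short participants, I = 3 planted assemblages over 12 genera.
tiny_cohort <- function(seed = 1L, visits = 6L, depth = 300L) {
  simulate_cohort(cohort_spec(
    participants_per_class = c(CD = 4, UC = 4, nonIBD = 4),
    visits = visits, n_short = 2L,
    phi = planted_phi(3L, 12L),
    depth = depth, seed = seed))
}

# A profile + metadata pair written to TSV files in a temp dir.
tiny_cohort_files <- function(seed = 1L) {
  sim <- tiny_cohort(seed)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  profile <- file.path(dir, "profile.tsv")
  meta <- file.path(dir, "metadata.tsv")
  write_profile_table(sim$table, profile)
  write_profile_table(sim$metadata, meta)
  list(profile = profile, metadata = meta, sim = sim)
}

# Count table with named dimensions from a plain matrix.
as_profile <- function(m, samples = sprintf("s%02d", seq_len(nrow(m))),
                       genera = sprintf("g%02d", seq_len(ncol(m)))) {
  rownames(m) <- samples
  colnames(m) <- genera
  taxon_profile(m)
}

# Disjoint-support planted assemblage model used by the recovery tests:
# assemblage 1 lives on genera {A, B}, assemblage 2 on {C, D}.
disjoint_phi2 <- function() {
  phi <- rbind(c(0.6, 0.4, 0, 0), c(0, 0, 0.7, 0.3))
  colnames(phi) <- c("A", "B", "C", "D")
  rownames(phi) <- c("A1", "A2")
  phi
}

# Corpus drawn from a planted phi with Dirichlet(0.5) mixtures.
planted_corpus <- function(phi, n = 200L, depth = 500L, seed = 42L) {
  set.seed(seed)
  theta <- mela:::rdirichlet(n, rep(0.5, nrow(phi)))
  X <- t(vapply(seq_len(n),
                function(i) stats::rmultinom(1L, depth, theta[i, ] %*% phi)[, 1L],
                integer(ncol(phi))))
  colnames(X) <- colnames(phi)
  rownames(X) <- sprintf("d%04d", seq_len(n))
  list(counts = taxon_profile(X), theta = theta)
}

# Total-variation distance between probability vectors.
tv_dist <- function(a, b) 0.5 * sum(abs(a - b))

# Best per-row TV error between fitted and planted phi over row permutations.
matched_tv <- function(phi_fit, phi_star) {
  perms <- function(v) if (length(v) == 1L) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  errs <- vapply(perms(seq_len(nrow(phi_star))), function(p)
    max(vapply(seq_len(nrow(phi_star)),
               function(i) tv_dist(phi_fit[p[i], ], phi_star[i, ]), numeric(1L))),
    numeric(1L))
  min(errs)
}
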