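test_that("to_counts rescales rows and preserves totals", {
  rel <- as_profile(rbind(c(0.25, 0.75), c(1.0, 0.0), c(1 / 3, 2 / 3), c(0, 0)))
  cnt <- to_counts(rel, depth = 100L)
  expect_equal(cnt$values[1, ], c(g01 = 25, g02 = 75))
  expect_true(cnt$is_counts)
  expect_equal(unname(to_counts(rel, depth = 7L)$values[2, ]), c(7, 0))
  # round-half-even then largest-remainder repair: (10/3, 20/3) -> (3, 7)
  expect_equal(unname(to_counts(rel, depth = 10L)$values[3, ]), c(3, 7))
  # all-zero rows stay all-zero
  expect_equal(unname(cnt$values[4, ]), c(0, 0))
  expect_error(to_counts(rel, depth = 0L), ">= 1")
})

test_that("fit_assemblages recovers a planted disjoint-support model", {
  phi_star <- disjoint_phi2()
  corp <- planted_corpus(phi_star, n = 200L, depth = 500L, seed = 42L)
  fit <- fit_assemblages(corp$counts, I = 2L, seed = 7L)
  expect_true(all(abs(rowSums(fit$phi) - 1) < 1e-9))
  expect_true(all(fit$phi >= 0))
  expect_lt(matched_tv(fit$phi, phi_star), 0.05)

  # determinism: identical seed and inputs give bit-identical phi
  fit2 <- fit_assemblages(corp$counts, I = 2L, seed = 7L)
  expect_identical(fit$phi, fit2$phi)

  # I = 1 degenerates to the global genus frequency vector
  fit1 <- fit_assemblages(corp$counts, I = 1L, seed = 1L)
  glob <- colSums(corp$counts$values) / sum(corp$counts$values)
  expect_lt(tv_dist(fit1$phi[1, ], glob), 0.01)
})

test_that("fit_assemblages validates its input", {
  rel <- as_profile(rbind(c(0.3, 0.7), c(0.5, 0.5)))
  expect_error(fit_assemblages(rel, I = 2L), "to_counts")
  cnt <- as_profile(rbind(c(5L, 5L), c(0L, 0L), c(2L, 8L)))
  expect_error(fit_assemblages(cnt, I = 2L), "all-zero sample\\(s\\): s02")
})

test_that("infer_abundances concentrates on the planted assemblage and is row-stochastic", {
  phi_star <- disjoint_phi2()
  corp <- planted_corpus(phi_star, seed = 42L)
  fit <- fit_assemblages(corp$counts, I = 2L, seed = 7L)

  # a sample containing only genera from one support gets theta > 0.9 there
  set.seed(9)
  x <- rbind(q1 = stats::rmultinom(1L, 500L, phi_star[1, ])[, 1L],
             q2 = stats::rmultinom(1L, 500L, phi_star[2, ])[, 1L])
  colnames(x) <- colnames(phi_star)
  ab <- infer_abundances(fit, taxon_profile(x))
  expect_true(all(abs(rowSums(ab$theta) - 1) < 1e-9))
  planted_col <- apply(ab$theta, 1L, which.max)
  expect_false(planted_col[1] == planted_col[2])
  expect_true(all(apply(ab$theta, 1L, max) > 0.9))

  # duplicated samples get identical rows
  dup <- taxon_profile(rbind(a = x[1, ], b = x[1, ]))
  ab2 <- infer_abundances(fit, dup)
  expect_equal(unname(ab2$theta[1, ]), unname(ab2$theta[2, ]))

  # vocabulary mismatch is named
  bad <- x; colnames(bad) <- c("A", "B", "C", "X")
  expect_error(infer_abundances(fit, taxon_profile(bad)),
               "missing: \\[D\\], extra: \\[X\\]")
})

test_that("genus relabeling permutes phi and leaves theta essentially unchanged", {
  phi_star <- disjoint_phi2()
  corp <- planted_corpus(phi_star, seed = 12L)
  fit <- fit_assemblages(corp$counts, I = 2L, seed = 3L)
  perm <- c(3L, 1L, 4L, 2L)
  permuted <- taxon_profile(corp$counts$values[, perm])
  fit_p <- fit_assemblages(permuted, I = 2L, seed = 3L)
  # the optimum is permutation-equivariant; the random initialisation is not,
  # so agreement is statistical rather than bit-exact
  expect_lt(max(abs(fit_p$phi[, colnames(fit$phi)] - fit$phi)), 0.01)
  th <- infer_abundances(fit, corp$counts)$theta
  th_p <- infer_abundances(fit_p, permuted)$theta
  expect_lt(max(abs(th - th_p)), 0.01)
})

test_that("dominant_genera ranks by weight with alphabetical tie-break", {
  phi <- rbind(c(0.89, 0.05, 0.03, 0.03), rep(0.25, 4))
  colnames(phi) <- c("Bacteroides", "Dorea", "Blautia", "Alistipes")
  rownames(phi) <- c("A1", "A2")
  model <- structure(list(phi = phi, I = 2L, genus_names = colnames(phi)),
                     class = "mela_lda")
  top1 <- dominant_genera(model, top_k = 1L)
  expect_equal(top1[[1]]$genus, "Bacteroides")
  expect_equal(top1[[1]]$weight, 0.89)
  expect_equal(format_dominant_genera(model, top_k = 1L)[1],
               "1 | *Bacteroides* (0.89)")
  # uniform row: alphabetical order among ties
  top2 <- dominant_genera(model, top_k = 2L)
  expect_equal(top2[[2]]$genus, c("Alistipes", "Bacteroides"))
  expect_equal(top2[[2]]$weight, c(0.25, 0.25))
  # full ranking sums to 1
  expect_equal(sum(dominant_genera(model, top_k = 4L)[[1]]$weight), 1)
  expect_error(dominant_genera(model, top_k = 5L), "1..F")
})

test_that("shared_genus_network counts common dominant genera", {
  mk <- function(phi, genera) {
    colnames(phi) <- genera
    rownames(phi) <- paste0("A", seq_len(nrow(phi)))
    structure(list(phi = phi, I = nrow(phi), genus_names = genera),
              class = "mela_lda")
  }
  # identical top-5 sets -> single edge of weight 5
  w <- c(0.3, 0.25, 0.2, 0.15, 0.1, 0, 0, 0, 0, 0)
  m1 <- mk(rbind(w, rev(w) * 0 + w), sprintf("g%02d", 1:10))
  e1 <- shared_genus_network(m1, top_k = 5L)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$weight, 5L)

  # disjoint top sets everywhere -> no edges (isolated assemblages)
  m2 <- mk(planted_phi(3L, 12L, dominance = 1 - 1e-9), sprintf("g%03d", 1:12))
  expect_equal(nrow(shared_genus_network(m2, top_k = 4L)), 0L)

  # three assemblages sharing exactly one genus pairwise -> triangle, weights 1
  phi3 <- matrix(1e-6, 3, 7)
  phi3[1, c(1, 4, 5)] <- c(0.5, 0.3, 0.2)
  phi3[2, c(1, 6, 7)] <- c(0.5, 0.3, 0.2)
  phi3[3, c(1, 2, 3)] <- c(0.5, 0.3, 0.2)
  m3 <- mk(phi3 / rowSums(phi3), sprintf("g%02d", 1:7))
  e3 <- shared_genus_network(m3, top_k = 3L)
  expect_equal(nrow(e3), 3L)
  expect_true(all(e3$weight == 1L))
})

test_that("class comparison is calibrated under the null and powered under shift", {
  # null: identical theta distributions in every class
  pvals <- vapply(1:200, function(s) {
    set.seed(s)
    th <- mela:::rdirichlet(60, rep(1, 3))
    compare_class_abundance(th, rep(c("CD", "UC", "nonIBD"), each = 20))$p_value[1]
  }, numeric(1L))
  # p-values are uniform under the null: ~95% of seeds clear 0.05
  expect_gt(mean(pvals > 0.05), 0.88)
  # rank tests on small samples give discrete p-values; jittered KS check
  set.seed(0)
  expect_gt(stats::ks.test(pvals + runif(200, 0, 1e-6), "punif")$p.value, 0.01)

  # power: one assemblage shifted by +0.3 in one class
  set.seed(1)
  th <- mela:::rdirichlet(150, rep(1, 3))
  lab <- rep(c("CD", "UC", "nonIBD"), each = 50)
  th[lab == "CD", 2] <- th[lab == "CD", 2] + 0.3
  res <- compare_class_abundance(th, lab)
  expect_lt(res$p_value[2], 0.01)
  expect_true(all(c("mean_CD", "mean_UC", "mean_nonIBD") %in% names(res)))

  # fully tied columns are handled without error
  tied <- matrix(0.5, 8, 2)
  res_t <- compare_class_abundance(tied, rep(c("a", "b"), each = 4))
  expect_equal(res_t$statistic, c(0, 0))
  expect_error(compare_class_abundance(th, rep("CD", 150)), "at least 2 classes")
  expect_error(compare_class_abundance(th[1:3, ], c("CD", "CD", "UC")),
               "at least 2 samples")
})
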