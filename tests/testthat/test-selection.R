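test_that("bonferroni adjusts and caps", {
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni(0.3), 0.3)
  expect_equal(bonferroni(0.4, m = 3), 1.0)
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("branch-site LRT: nesting, statistic clamp, taxon-order invariance", {
  tr <- ape::read.tree(
    text = "((a:0.3,b:0.3):0.2,(c:0.3,d:0.3):0.2):0;")
  sim <- simulate_codon_alignment(tr, codon_model(kappa = 2), 40, "neutral",
                                  seed = 21)
  fg <- c("a", "b")
  res <- branch_sites_lrt(sim$codons, tr, fg, m_tests = 2, kappa = 2)
  expect_gte(res$lnL_alt, res$lnL_null - 1e-6)
  expect_gte(res$statistic, 0)
  expect_equal(res$p_bonferroni, min(1, 2 * res$p_raw))
  expect_gte(res$omega2, 1)
  expect_equal(res$p0 + res$p1 + res$p2, 1, tolerance = 1e-8)

  # shuffling taxon rows does not change the result
  perm <- c("c", "a", "d", "b")
  res2 <- branch_sites_lrt(sim$codons[perm, ], tr, fg, m_tests = 2, kappa = 2)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-6)
  expect_error(branch_sites_lrt(sim$codons, tr, c("a", "c")), "no branch")
})

test_that("Model A fits match a brute-force grid search on a small instance", {
  tr <- ape::read.tree(
    text = "((a:0.25,b:0.35):0.15,(c:0.2,d:0.3):0.1):0;")
  sim <- simulate_codon_alignment(tr, codon_model(kappa = 2), 30, "sites",
                                  p0 = 0.6, omega0 = 0.2, seed = 33)
  fg_child <- branch_by_leafset(tr, c("a", "b"))
  pi <- empirical_codon_freqs_f3x4(sim$codons)
  kappa <- 2
  res <- branch_sites_lrt(sim$codons, tr, fg_child, codon_freqs = pi,
                          kappa = kappa)

  # grid over (p0, p1, omega0, omega2) at 0.05 resolution, using the
  # package's class likelihoods but an exhaustive search over parameters
  prep <- domevol:::.prep_tree(tr)
  tipi <- domevol:::.tip_indices(sim$codons, "codon")[tr$tip.label, , drop = FALSE]
  mu1 <- domevol:::.neutral_rate(kappa, pi)
  w0_grid <- seq(0.05, 1, by = 0.05)
  w2_grid <- seq(1, 3, by = 0.05)
  pgrid <- expand.grid(p0 = seq(0.05, 0.95, by = 0.05),
                       p1 = seq(0.05, 0.95, by = 0.05))
  pgrid <- pgrid[pgrid$p0 + pgrid$p1 <= 0.999, ]
  best_alt <- -Inf; best_null <- -Inf
  best_pt <- NULL
  for (w0 in w0_grid) for (w2 in w2_grid) {
    cl <- domevol:::.model_a_class_ll(prep, tipi, pi, kappa, w0, w2,
                                      fg_child, mu1)
    for (r in seq_len(nrow(pgrid))) {
      p0 <- pgrid$p0[r]; p1 <- pgrid$p1[r]
      q <- p0 + p1
      w <- c(p0, p1, (1 - q) * p0 / q, (1 - q) * p1 / q)
      lnL <- domevol:::.mix_loglik(cl, w)$total
      if (w2 == 1 && lnL > best_null) best_null <- lnL
      if (lnL > best_alt) { best_alt <- lnL; best_pt <- c(w0, w2, p0, p1) }
    }
  }
  # the coordinate-ascent fit must at least match the grid optimum
  expect_gte(res$lnL_alt, best_alt - 0.05)
  expect_gte(res$lnL_null, best_null - 0.05)

  # and the likelihood at the grid optimum is verified by full enumeration
  cl_best <- domevol:::.model_a_class_ll(prep, tipi, pi, kappa, best_pt[1],
                                         best_pt[2], fg_child, mu1)
  mu <- mu1
  P_of <- function(w) {
    Q <- domevol:::.scaled_codon_q(kappa, w, pi, mu)
    lapply(seq_len(nrow(tr$edge)), function(k)
      transition_matrix(Q, tr$edge.length[k]))
  }
  fg_edge <- which(tr$edge[, 2] == fg_child)
  P0 <- P_of(best_pt[1]); P1 <- P_of(1); P2 <- P_of(best_pt[2])
  P2a <- P0; P2a[fg_edge] <- P2[fg_edge]
  P2b <- P1; P2b[fg_edge] <- P2[fg_edge]
  s <- 1  # one site suffices for the enumeration cross-check
  tip <- setNames(match(sim$codons[, s], sense_codons()), rownames(sim$codons))
  for (ci in 1:4) {
    Pl <- list(P0, P1, P2a, P2b)[[ci]]
    expect_equal(cl_best[ci, s], log(enum_site_lik(tr, tip, Pl, pi)),
                 tolerance = 1e-8)
  }
})

test_that("LRT under the null is conservative across seeds", {
  tr <- random_tree(6, total_length = 1.5, seed = 40)
  ntip <- length(tr$tip.label)
  internal <- setdiff(unique(tr$edge[, 2]), seq_len(ntip))
  fg <- internal[1]
  hits <- 0
  for (r in 1:20) {
    sim <- simulate_codon_alignment(tr, codon_model(kappa = 2), 60, "neutral",
                                    seed = 700 + r)
    res <- branch_sites_lrt(sim$codons, tr, fg, kappa = 2)
    if (res$p_raw <= 0.05) hits <- hits + 1
  }
  # raw p above 0.05 in at least 18 of 20 seeds
  expect_lte(hits, 2)
})

test_that("gene conversion scan: empty input, constructed tract, determinism", {
  m_same <- matrix("A", 3, 30, dimnames = list(paste0("s", 1:3), NULL))
  expect_warning(res0 <- gene_conversion_scan(m_same, n_perm = 10),
                 "polymorphic")
  expect_equal(nrow(res0), 0)

  # mosaic: sequences A and B share a contiguous tract of >= 20 polymorphic
  # sites inside otherwise independently shuffled columns
  set.seed(5)
  nt <- c("A", "C", "G", "T")
  L <- 70
  m <- matrix(sample(nt, 4 * L, replace = TRUE), 4, L,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  m["B", ] <- sample(nt, L, replace = TRUE)
  m["B", 25:46] <- m["A", 25:46]
  res <- gene_conversion_scan(m, n_perm = 1000, seed = 2)
  top <- res[1, ]
  expect_setequal(c(top$seq1, top$seq2), c("A", "B"))
  expect_lte(top$sim_p, 0.01)
  expect_lte(top$begin, 25 + 3)
  expect_gte(top$end, 46 - 3)
  # brute-force verification of the observed fragment score for the pair:
  # maximum over all [i, j] windows of matches - mismatches
  ok <- apply(m, 2, function(col) length(unique(col)) > 1)
  v <- (m["A", ok] == m["B", ok])
  n <- length(v)
  brute <- 0
  for (i in seq_len(n)) for (j in i:n) {
    sc <- sum(v[i:j]) - sum(!v[i:j])
    brute <- max(brute, sc)
  }
  expect_equal(top$score, brute)

  res_b <- gene_conversion_scan(m, n_perm = 1000, seed = 2)
  expect_identical(res, res_b)
})

test_that("permutation p is monotone non-increasing in fragment score", {
  set.seed(11)
  nt <- c("A", "C", "G", "T")
  L <- 60
  base <- matrix(sample(nt, 4 * L, replace = TRUE), 4, L,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  ps <- vapply(c(6, 14, 26), function(tract) {
    m <- base
    m["B", seq_len(tract)] <- m["A", seq_len(tract)]
    res <- gene_conversion_scan(m, n_perm = 400, seed = 3)
    res$sim_p[res$seq1 == "A" & res$seq2 == "B"]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})
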