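test_that("random trees: shape, rescaled length, determinism", {
  tr <- random_tree(3, total_length = 2, seed = 1)
  expect_equal(nrow(tr$edge), 4)
  expect_equal(sum(tr$edge.length), 2, tolerance = 1e-12)
  tr20 <- random_tree(20, total_length = 4, seed = 5)
  expect_equal(sum(tr20$edge.length), 4, tolerance = 1e-9)
  expect_identical(ape::write.tree(random_tree(10, 1, seed = 7)),
                   ape::write.tree(random_tree(10, 1, seed = 7)))
  expect_error(random_tree(2, 1, 1), "n_taxa")
})

test_that("protein simulation: zero branches copy the root, seeds reproduce", {
  tr <- random_tree(5, total_length = 1, seed = 2)
  tr0 <- tr; tr0$edge.length[] <- 0
  mo <- protein_model(alpha = 1, ncat = 2)
  sim <- simulate_protein_alignment(tr0, mo, 40, seed = 3)
  expect_true(all(apply(sim$alignment, 2, function(col) length(unique(col)) == 1)))
  s1 <- simulate_protein_alignment(tr, mo, 50, seed = 9)
  s2 <- simulate_protein_alignment(tr, mo, 50, seed = 9)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$ancestors, s2$ancestors)
})

test_that("two-taxon substitution frequencies match the transition matrix", {
  tr <- ape::read.tree(text = "(a:5,b:0):0;")
  mo <- protein_model(alpha = 1e6, ncat = 1)  # effectively rate-homogeneous
  sim <- simulate_protein_alignment(tr, mo, 20000, seed = 2)
  P <- transition_matrix(build_rate_matrix(mo), 5)
  a <- sim$alignment["a", ]; b <- sim$alignment["b", ]
  viol <- 0; checks <- 0
  for (s in AA_ALPHABET) {
    sel <- b == s
    n <- sum(sel)
    if (n < 300) next
    emp <- table(factor(a[sel], levels = AA_ALPHABET)) / n
    for (t2 in AA_ALPHABET) {
      p <- P[s, t2]
      checks <- checks + 1
      if (abs(emp[[t2]] - p) > 3 * sqrt(p * (1 - p) / n) + 1e-9) viol <- viol + 1
    }
  }
  expect_gt(checks, 100)
  # with ~3-sigma bands a small fraction of violations is expected by chance
  expect_lt(viol / checks, 0.02)
})

test_that("neutral codon simulation matches the syn/nonsyn counting oracle", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05):0;")
  cm <- codon_model(kappa = 2)
  sim <- simulate_codon_alignment(tr, cm, 20000, "neutral", seed = 3)
  a <- sim$codons["a", ]; b <- sim$codons["b", ]
  dif <- which(a != b)
  nd <- mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
               a[dif], b[dif])
  single <- dif[nd == 1]
  obs_nonsyn <- mean(translate_codons(a[single]) != translate_codons(b[single]))
  # expected nonsynonymous fraction of single-nucleotide events at omega = 1,
  # from flux sums over the generator (independent of the pruning machinery)
  Q <- build_rate_matrix(cm)
  pi <- attr(Q, "freq")
  cods <- sense_codons(); aa <- translate_codons(cods)
  nonsyn_flux <- syn_flux <- 0
  for (i in 1:61) for (j in 1:61) {
    if (i == j || Q[i, j] == 0) next
    if (aa[i] == aa[j]) syn_flux <- syn_flux + pi[i] * Q[i, j]
    else nonsyn_flux <- nonsyn_flux + pi[i] * Q[i, j]
  }
  p_exp <- nonsyn_flux / (nonsyn_flux + syn_flux)
  se <- sqrt(p_exp * (1 - p_exp) / length(single))
  expect_lt(abs(obs_nonsyn - p_exp), 4 * se)
})

test_that("sites regime with p0 = 1, omega0 = 0 forbids amino-acid change", {
  tr <- ape::read.tree(text = "(a:1,b:1):0;")
  sim <- simulate_codon_alignment(tr, codon_model(kappa = 2), 400, "sites",
                                  p0 = 1, omega0 = 0, seed = 4)
  expect_identical(translate_codons(sim$codons["a", ]),
                   translate_codons(sim$codons["b", ]))
  s1 <- simulate_codon_alignment(tr, codon_model(), 50, "neutral", seed = 5)
  s2 <- simulate_codon_alignment(tr, codon_model(), 50, "neutral", seed = 5)
  expect_identical(s1$codons, s2$codons)
})

test_that("generating model beats a perturbed model on its own data", {
  tr <- random_tree(6, total_length = 2, seed = 11)
  mo <- protein_model(alpha = 0.6, ncat = 4)
  mo_bad <- protein_model(alpha = 1.2, ncat = 4)
  wins <- 0
  for (r in 1:20) {
    sim <- simulate_protein_alignment(tr, mo, 200, seed = 100 + r)
    if (log_likelihood(sim$alignment, tr, mo)$total >
        log_likelihood(sim$alignment, tr, mo_bad)$total) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("kinetics generator obeys its closed forms", {
  # C = Kd, no noise/drift, long run: plateau = Rmax / 2
  spec <- kinetics_sim_spec(Kd_true = 1e-7, concentrations = c(1e-8, 3e-8, 1e-7),
                            noise_sd = 0, duration = 3600 * 10,
                            sample_interval = 60, n_replicates = 1, Rmax = 2)
  tr <- simulate_kinetics(spec)
  assoc <- tr[tr$phase == "association" & tr$concentration_M == 1e-7, ]
  expect_equal(assoc$signal[nrow(assoc)], 1, tolerance = 1e-4)
  # blank trace with no drift/noise is identically zero
  blank <- tr[tr$concentration_M == 0, ]
  expect_true(all(blank$signal == 0))
  # noiseless steady states lie on the binding hyperbola
  for (C in spec$concentrations) {
    a <- tr[tr$phase == "association" & tr$concentration_M == C, ]
    expect_equal(steady_state(a), 2 * C / (C + 1e-7), tolerance = 1e-3)
  }
  # determinism
  spec2 <- kinetics_sim_spec(noise_sd = 0.02, duration = 60, seed = 3)
  expect_identical(simulate_kinetics(spec2), simulate_kinetics(spec2))
  # koff consistency invariant
  expect_equal(spec$koff / spec$kon, spec$Kd_true, tolerance = 1e-12)
})

test_that("the synthetic domain-family fixture has the declared geometry", {
  fx <- card_family_fixture(seed = 2, n_groups = 5, taxa_per_group = 4,
                            n_sites = 60)
  expect_equal(nrow(fx$alignment), 20)
  expect_equal(ncol(fx$alignment), 60)
  expect_setequal(unique(fx$groups), paste0("g", 1:5))
  # groups are clades on the tree
  keys <- node_leafset_keys(fx$tree)
  for (g in paste0("g", 1:5)) {
    tx <- names(fx$groups)[fx$groups == g]
    expect_true(paste(sort(tx), collapse = "|") %in% keys)
  }
})
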