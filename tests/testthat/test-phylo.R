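test_that("pruning equals brute-force enumeration (protein, with gamma and gaps)", {
  tr <- toy_tree3()
  mo <- protein_model(alpha = 0.8, ncat = 3)
  aln <- toy_protein_aln()
  aln[2, 2] <- "-"   # missing data handled as a flat partial
  ll <- log_likelihood(aln, tr, mo)
  Q <- build_rate_matrix(mo)
  rates <- discrete_gamma(0.8, 3)
  P_lists <- lapply(rates, function(r)
    lapply(seq_len(nrow(tr$edge)), function(k)
      transition_matrix(Q, tr$edge.length[k], r)))
  for (s in 1:2) {
    tip <- setNames(match(aln[, s], AA_ALPHABET), rownames(aln))
    oracle <- enum_site_lik_mix(tr, tip, P_lists, mo$frequencies, rep(1 / 3, 3))
    expect_equal(ll$sites[s], log(oracle), tolerance = 1e-10)
  }
  expect_equal(sum(ll$sites), ll$total, tolerance = 1e-8)
})

test_that("pruning equals enumeration for a 4-taxon codon sites model", {
  tr <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.1):0;")
  mo <- codon_model(kappa = 2.5, site_classes = list(p = c(0.7, 0.3),
                                                     omega = c(0.1, 1)))
  sim <- simulate_codon_alignment(tr, mo, 2, "sites", p0 = 0.7, omega0 = 0.1,
                                  seed = 8)
  ll <- log_likelihood(sim$codons, tr, mo)
  P_lists <- lapply(1:2, function(ci) {
    Q <- build_rate_matrix(mo, class = ci)
    lapply(seq_len(nrow(tr$edge)), function(k)
      transition_matrix(Q, tr$edge.length[k]))
  })
  for (s in 1:2) {
    tip <- setNames(match(sim$codons[, s], sense_codons()), rownames(sim$codons))
    oracle <- enum_site_lik_mix(tr, tip, P_lists, mo$codon_freqs, c(0.7, 0.3))
    expect_equal(ll$sites[s], log(oracle), tolerance = 1e-8)
  }
})

test_that("single-taxon likelihood is the log stationary probability", {
  mo <- protein_model(alpha = 1, ncat = 4)
  tr1 <- ape::read.tree(text = "(a:0);")
  aln <- matrix(c("A", "W", "-"), 1, 3, dimnames = list("a", NULL))
  ll <- log_likelihood(aln, tr1, mo)
  pi <- mo$frequencies
  expect_equal(ll$sites, c(log(pi[["A"]]), log(pi[["W"]]), 0), ignore_attr = TRUE)
})

test_that("likelihood is invariant to root placement", {
  tr <- random_tree(6, total_length = 1.5, seed = 4)
  mo <- protein_model(alpha = 1, ncat = 2)
  sim <- simulate_protein_alignment(tr, mo, 30, seed = 5)
  base <- log_likelihood(sim$alignment, tr, mo)$total
  ut <- ape::unroot(tr)
  for (tip in c(1, 3, 5)) {
    rt <- ape::root(ut, outgroup = ut$tip.label[tip], resolve.root = TRUE)
    expect_equal(log_likelihood(sim$alignment, rt, mo)$total, base,
                 tolerance = 1e-8)
  }
})

test_that("optimizer: no-op returns input, trajectory monotone, recovery", {
  tr <- random_tree(6, total_length = 1.5, seed = 5)
  mo <- protein_model(alpha = 1, ncat = 2)
  sim <- simulate_protein_alignment(tr, mo, 1500, seed = 9)
  ll0 <- log_likelihood(sim$alignment, tr, mo)$total
  noop <- optimize_model(sim$alignment, tr, mo, free = character())
  expect_identical(noop$lnL, ll0)

  tr0 <- tr; tr0$edge.length[] <- 0.1
  fit <- optimize_model(sim$alignment, tr0, mo, free = "branch_lengths",
                        control = list(tol = 1e-3, brent_tol = 1e-3))
  expect_true(all(diff(fit$trajectory) >= -1e-9))
  expect_gt(fit$lnL, log_likelihood(sim$alignment, tr0, mo)$total)
  # compare on the unrooted tree: the split of length across the two
  # root-adjacent edges is not identifiable under a reversible model
  ut_fit <- ape::unroot(fit$tree); ut_true <- ape::unroot(tr)
  est <- setNames(ut_fit$edge.length, node_leafset_keys(ut_fit)[ut_fit$edge[, 2]])
  tru <- setNames(ut_true$edge.length, node_leafset_keys(ut_true)[ut_true$edge[, 2]])
  expect_lt(max(abs(est[names(tru)] - tru) / pmax(tru, 0.05)), 0.15)
})

test_that("neighbor joining: three-point formulas and additive recovery", {
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- neighbor_joining(d3)
  b <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(b[["a"]], 1)   # (3 + 5 - 6) / 2
  expect_equal(b[["b"]], 2)
  expect_equal(b[["c"]], 4)

  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2,e:4);")
  d <- stats::cophenetic(tr)
  nj <- neighbor_joining(d)
  expect_equal(ape::dist.topo(nj, tr), 0, ignore_attr = TRUE)
  expect_equal(stats::cophenetic(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
  # agreement with the classical implementation on additive input
  nj_ape <- ape::nj(d)
  expect_equal(ape::dist.topo(nj, nj_ape), 0, ignore_attr = TRUE)

  # invariance to input taxon order
  perm <- c("d", "a", "e", "c", "b")
  nj2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(nj, nj2), 0, ignore_attr = TRUE)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "asymmetric|3 taxa")
})

test_that("SH test: self-comparison and duplicates get p = 1, power on wrong topology", {
  # generating tree with substantial internal branches, so the heavily
  # perturbed topology is genuinely distinguishable
  tr <- ape::read.tree(
    text = "(((a:0.2,b:0.2):0.3,c:0.4):0.3,(d:0.2,e:0.3):0.2):0;")
  mo <- protein_model(alpha = 1, ncat = 1)
  trB <- ape::read.tree(
    text = "(((d:0.2,b:0.2):0.3,c:0.4):0.3,(a:0.2,e:0.3):0.2):0;")
  expect_gt(ape::dist.topo(ape::unroot(tr), ape::unroot(trB)), 0)

  sim <- simulate_protein_alignment(tr, mo, 300, seed = 2)
  sh <- sh_test(sim$alignment, list(tr, trB, tr), mo, n_rell = 300, seed = 1,
                optimize = FALSE)
  expect_equal(sh$p_sh[1], 1)           # best tree
  expect_equal(sh$p_sh[3], 1)           # duplicate of the best tree
  expect_true(all(sh$p_sh >= 0 & sh$p_sh <= 1))
  # reproducible under a fixed seed
  sh2 <- sh_test(sim$alignment, list(tr, trB, tr), mo, n_rell = 300, seed = 1,
                 optimize = FALSE)
  expect_identical(sh$p_sh, sh2$p_sh)

  rejections <- 0
  for (r in 1:10) {
    sim_r <- simulate_protein_alignment(tr, mo, 400, seed = 500 + r)
    sh_r <- sh_test(sim_r$alignment, list(tr, trB), mo, n_rell = 200,
                    seed = r, optimize = TRUE)
    if (sh_r$p_sh[2] < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections, 9)
})

test_that("duplication/loss rooting: congruent trees cost zero, oracle equality", {
  sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  gt <- ape::unroot(ape::read.tree(text = "((A_x:1,B_x:1):1,(C_x:1,D_x:1):1);"))
  r <- root_by_duplication_loss(gt, sp)
  expect_equal(r$best_edges$duplications, 0)
  expect_equal(r$best_edges$losses, 0)

  # every candidate edge's cost equals the independent reconciliation oracle
  leaf_map <- setNames(sub("_.*$", "", gt$tip.label), gt$tip.label)
  keys <- node_leafset_keys(gt)
  ntip <- length(gt$tip.label)
  for (k in seq_len(nrow(gt$edge))) {
    ch <- gt$edge[k, 2]
    og <- strsplit(keys[ch], "|", fixed = TRUE)[[1]]
    if (length(og) >= ntip) next
    rt <- ape::root(gt, outgroup = og, resolve.root = TRUE)
    oracle <- reconcile_oracle(rt, sp, leaf_map)
    row <- r$all_edges[r$all_edges$edge_leafset == keys[ch], ]
    expect_equal(row$duplications, unname(oracle["duplications"]))
    expect_equal(row$losses, unname(oracle["losses"]))
  }

  # two tandem copies of the whole species tree: one duplication at the root
  gt2 <- ape::unroot(ape::read.tree(
    text = "(((A_1,B_1),(C_1,D_1)),((A_2,B_2),(C_2,D_2)));"))
  r2 <- root_by_duplication_loss(gt2, sp)
  expect_equal(r2$best_edges$duplications, 1)
  expect_equal(r2$best_edges$losses, 0)
  expect_error(root_by_duplication_loss(gt, ape::read.tree(text = "((A,B),(C,E));")),
               "unmappable")
})

test_that("dup/loss costs on a 6-leaf incongruent case match the oracle everywhere", {
  sp <- ape::read.tree(text = "(((A,B),C),(D,E));")
  gt <- ape::unroot(ape::read.tree(
    text = "((A_1,(C_1,D_1)),(B_1,(E_1,E_2)));"))
  leaf_map <- setNames(sub("_.*$", "", gt$tip.label), gt$tip.label)
  r <- root_by_duplication_loss(gt, sp, leaf_map)
  keys <- node_leafset_keys(gt)
  ntip <- length(gt$tip.label)
  for (k in seq_len(nrow(gt$edge))) {
    ch <- gt$edge[k, 2]
    og <- strsplit(keys[ch], "|", fixed = TRUE)[[1]]
    if (length(og) >= ntip) next
    rt <- ape::root(gt, outgroup = og, resolve.root = TRUE)
    oracle <- reconcile_oracle(rt, sp, leaf_map)
    row <- r$all_edges[r$all_edges$edge_leafset == keys[ch], ]
    expect_equal(row$total, unname(sum(oracle)))
  }
})
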