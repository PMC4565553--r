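test_that("marginal posteriors equal brute-force Bayes and sum to one", {
  tr <- toy_tree3()
  mo <- protein_model(alpha = 0.8, ncat = 3)
  aln <- toy_protein_aln()
  rec <- marginal_reconstruct(aln, tr, mo)
  Q <- build_rate_matrix(mo)
  rates <- discrete_gamma(0.8, 3)
  P_lists <- lapply(rates, function(r)
    lapply(seq_len(nrow(tr$edge)), function(k)
      transition_matrix(Q, tr$edge.length[k], r)))
  for (node_key in names(rec$nodes)) {
    node_id <- which(node_leafset_keys(tr) == node_key)
    for (s in 1:2) {
      tip <- setNames(match(aln[, s], AA_ALPHABET), rownames(aln))
      oracle <- enum_node_posterior(tr, tip, P_lists, mo$frequencies,
                                    rep(1 / 3, 3), node_id)
      expect_equal(rec$nodes[[node_key]]$posterior[s, ], oracle,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
    expect_equal(rowSums(rec$nodes[[node_key]]$posterior), c(1, 1),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(rec$nodes[[node_key]]$map_p >=
                      rec$nodes[[node_key]]$alt_p))
  }
})

test_that("a zero-length branch to a leaf pins the adjacent ancestor", {
  tr <- ape::read.tree(text = "((a:0,b:0.5):0.2,c:0.7):0;")
  rec <- marginal_reconstruct(toy_protein_aln(), tr, protein_model(alpha = 1))
  expect_equal(unname(rec$nodes[["a|b"]]$posterior[1, "A"]), 1,
               tolerance = 1e-12)
  expect_equal(rec$nodes[["a|b"]]$map[1], "A")
})

test_that("integration over trees: identity, averaging, partial support", {
  mo <- protein_model(alpha = 1, ncat = 2)
  aln <- matrix(c("A", "A", "R", "C", "C", "C"), 3, 2,
                dimnames = list(c("a", "b", "c"), NULL))
  trA <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.2):0;")
  trB <- ape::read.tree(text = "((a:0.1,c:0.1):0.1,b:0.2):0;")
  recA <- marginal_reconstruct(aln, trA, mo)
  recB <- marginal_reconstruct(aln, trB, mo)

  one <- integrate_over_trees(list(recA), 1, c("a", "b"))
  expect_identical(one$posterior, recA$nodes[["a|b"]]$posterior)
  expect_equal(one$support, 1)

  # both trees contain the root clade {a,b,c}: equal weights average
  both <- integrate_over_trees(list(recA, recB), c(0.5, 0.5), c("a", "b", "c"))
  expect_equal(both$posterior,
               (recA$nodes[["a|b|c"]]$posterior +
                  recB$nodes[["a|b|c"]]$posterior) / 2)
  expect_equal(both$support, 1)

  # clade {a,b} exists only in tree A: its reconstruction, support 0.5
  half <- integrate_over_trees(list(recA, recB), c(0.5, 0.5), c("a", "b"))
  expect_equal(half$posterior, recA$nodes[["a|b"]]$posterior)
  expect_equal(half$support, 0.5)
  expect_error(integrate_over_trees(list(recA), 1, c("b", "c")), "no tree")
})

test_that("Fitch indel labelings are minimal-change and follow the tie rules", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1):0;")
  # all present: every ancestor present
  aln_all <- matrix("A", 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  pres <- parsimony_indels(aln_all, tr)
  expect_true(all(pres$presence))

  # exhaustive check over all 16 tip patterns at one site
  for (pat in 0:15) {
    tips <- as.integer(intToBits(pat))[1:4]
    aln <- matrix(ifelse(tips == 1, "A", "-"), 4, 1,
                  dimnames = list(c("a", "b", "c", "d"), NULL))
    p <- parsimony_indels(aln, tr)
    oracle <- enum_min_changes(tr, tips)
    # the package labeling must attain the minimal number of changes
    keys <- node_leafset_keys(tr)
    nn <- 4 + tr$Nnode
    lab <- integer(nn)
    lab[1:4] <- tips
    for (n in 5:nn) lab[n] <- as.integer(p$presence[keys[n], 1])
    changes <- sum(lab[tr$edge[, 1]] != lab[tr$edge[, 2]])
    expect_equal(changes, oracle$min_changes)
  }

  # ambiguity at the root resolves toward presence
  aln_amb <- matrix(c("A", "-", "A", "-"), 4, 1,
                    dimnames = list(c("a", "b", "c", "d"), NULL))
  p_amb <- parsimony_indels(aln_amb, tr)
  expect_true(p_amb$presence["a|b|c|d", 1])

  # equally weighted disagreeing trees: probability 0.5 calls presence
  trB <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1):0;")
  p2 <- parsimony_indels(aln_amb, weighted_tree_set(list(tr, trB)))
  shared <- "a|b|c|d"
  if (any(p2$probability[shared, ] == 0.5))
    expect_true(all(p2$presence[shared, p2$probability[shared, ] == 0.5]))
})

test_that("confidence summaries count thresholds and ambiguity correctly", {
  # crafted 10-site node: 3 sites at (0.6 MAP / 0.35 alt)
  post <- matrix(0, 10, 20, dimnames = list(NULL, AA_ALPHABET))
  post[1:7, "A"] <- 1
  post[8:10, "A"] <- 0.6; post[8:10, "V"] <- 0.35; post[8:10, "R"] <- 0.05
  rec <- list(n1 = list(posterior = post,
                        map = rep("A", 10), map_p = post[, "A"],
                        alt = c(rep("R", 7), rep("V", 3)),
                        alt_p = c(rep(0, 7), rep(0.35, 3)),
                        presence = rep(TRUE, 10)))
  cs <- confidence_summary(rec)
  expect_equal(cs$pooled$n_ambiguous, 3)
  expect_equal(cs$pooled$frac_above_0.95, 0.7)
  expect_equal(cs$pooled$frac_above_0.8, 0.7)
  # V is in the same (aliphatic) class as A
  expect_equal(cs$pooled$frac_same_class, 1)
  # threshold fractions are monotone non-increasing in the threshold
  fr <- unlist(cs$pooled[paste0("frac_above_", c("0.95", "0.9", "0.8"))])
  expect_true(all(diff(fr) >= 0))

  # all MAP posteriors 1: everything above every threshold, nothing ambiguous
  rec1 <- list(n1 = list(posterior = NULL, map = rep("A", 5),
                         map_p = rep(1, 5), alt = rep("R", 5),
                         alt_p = rep(0, 5), presence = rep(TRUE, 5)))
  cs1 <- confidence_summary(rec1)
  expect_equal(cs1$pooled$frac_above_0.95, 1)
  expect_equal(cs1$pooled$n_ambiguous, 0)
  expect_error(confidence_summary(list()), "empty")
})

test_that("stationarity chi-square matches hand computation and is monotone", {
  # identical composition: statistic 0, p = 1
  g_same <- list(g1 = matrix(rep(c("A", "R"), 10), 1),
                 g2 = matrix(rep(c("A", "R"), 10), 1))
  st <- stationarity_test(g_same)
  expect_equal(st$statistic, c(0, 0))
  expect_equal(st$p, c(1, 1))

  # two-residue toy: counts (30,10) vs pooled (0.5,0.5) gives 10.0
  g <- list(g1 = matrix(c(rep("A", 30), rep("R", 10)), 1),
            g2 = matrix(c(rep("A", 10), rep("R", 30)), 1))
  st2 <- stationarity_test(g)
  expect_equal(st2$statistic[1], 10)
  expect_equal(st2$df[1], 1)

  # p decreases as the skew grows
  skew_p <- function(k) {
    g <- list(g1 = matrix(c(rep("A", 20 + k), rep("R", 20 - k)), 1),
              g2 = matrix(c(rep("A", 20), rep("R", 20)), 1))
    stationarity_test(g)$p[1]
  }
  ps <- vapply(c(2, 6, 12), skew_p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(stationarity_test(list(g1 = matrix("A", 1))), "2 groups")
})

test_that("a masked deletion block is reconstructed as absent in its clade", {
  fx <- card_family_fixture(seed = 4, n_groups = 3, taxa_per_group = 4,
                            n_sites = 40)
  g1 <- names(fx$groups)[fx$groups == "g1"]
  masked <- mask_indel_block(fx$alignment, g1, start = 10, width = 6)
  p <- parsimony_indels(masked, fx$tree)
  key <- paste(sort(g1), collapse = "|")
  expect_true(all(!p$presence[key, 10:15]))
  expect_true(all(p$presence[key, c(1:9, 16:40)]))
  root_key <- paste(sort(rownames(fx$alignment)), collapse = "|")
  expect_true(all(p$presence[root_key, ]))  # deletion stays inside the clade
})
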