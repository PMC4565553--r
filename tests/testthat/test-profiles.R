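test_that("profile HMM construction follows the pseudocount formulas", {
  # one gap-free sequence duplicated: match length = alignment length
  aln <- matrix(rep(c("A", "C", "D", "E"), each = 2), 2, 4,
                dimnames = list(c("s1", "s2"), NULL))
  h <- build_hmm(aln)
  expect_equal(h$length, 4)
  expect_equal(unname(h$emissions[1, "A"]), 2.2 / 6)  # (2+0.2)/(2+4)

  # column with counts (A:3, V:1) and pseudocount 0.2
  aln2 <- matrix(c("A", "A", "A", "V"), 4, 1,
                 dimnames = list(paste0("s", 1:4), NULL))
  h2 <- build_hmm(aln2)
  expect_equal(unname(h2$emissions[1, "A"]), 3.2 / 8)
  expect_equal(unname(h2$emissions[1, "V"]), 1.2 / 8)
  expect_equal(unname(h2$emissions[1, "R"]), 0.2 / 8)
  expect_equal(rowSums(h2$emissions), 1, ignore_attr = TRUE)

  # all-gap and minority columns are excluded from match states
  aln3 <- matrix(c("A", "A",
                   "-", "-",
                   "C", "-",
                   "D", "D"), 2, 4,
                 dimnames = list(c("s1", "s2"), NULL))
  h3 <- build_hmm(aln3)
  expect_equal(h3$match_columns, c(1, 3, 4))
  expect_error(build_hmm(matrix("-", 2, 3)), "zero match columns")
  # transition distributions are proper
  expect_true(all(abs(apply(h3$transitions, c(1, 2), sum) - 1) < 1e-12))
})

test_that("HMM distance: zero on self, symmetric, closed form", {
  aln <- matrix(c("A", "A", "V", "V"), 2, 2,
                dimnames = list(c("s1", "s2"), NULL))
  h <- build_hmm(aln)
  expect_equal(hmm_distance(h, h), 0)

  # single-position emissions (0.9, 0.1) vs (0.1, 0.9): 0.8 ln 9
  mk <- function(pA) {
    h <- build_hmm(matrix(c("A", "A"), 2, 1, dimnames = list(c("x", "y"), NULL)))
    h$emissions[1, ] <- c(pA, 1 - pA, rep(0, 18))
    # move mass onto a two-residue support (A, R)
    h
  }
  h1 <- mk(0.9); h2 <- mk(0.1)
  expect_equal(hmm_distance(h1, h2), 0.8 * log(9), tolerance = 1e-12)
  expect_equal(hmm_distance(h1, h2), hmm_distance(h2, h1))
  h3 <- build_hmm(matrix("A", 2, 2, dimnames = list(c("x", "y"), NULL)))
  expect_error(hmm_distance(h1, h3), "length")
})

test_that("HMM NJ tree joins tight clusters first and is deterministic", {
  fx <- card_family_fixture(seed = 3, n_groups = 4, taxa_per_group = 6,
                            n_sites = 80, within_depth = 0.2, stem = 1.2)
  hmms <- lapply(split(names(fx$groups), fx$groups), function(tx)
    build_hmm(fx$alignment[tx, , drop = FALSE]))
  tr <- hmm_tree(hmms)
  expect_setequal(tr$tip.label, paste0("g", 1:4))
  expect_identical(ape::write.tree(hmm_tree(hmms)), ape::write.tree(tr))
  d <- attr(tr, "distances")
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # two pairs of near-identical groups must be joined as cherries
  a1 <- fx$alignment[names(fx$groups)[fx$groups == "g1"], ]
  g5 <- a1; rownames(g5) <- paste0("x", seq_len(nrow(g5)))
  a2 <- fx$alignment[names(fx$groups)[fx$groups == "g2"], ]
  g6 <- a2; rownames(g6) <- paste0("y", seq_len(nrow(g6)))
  hmms2 <- list(g1 = build_hmm(a1), g1b = build_hmm(g5),
                g2 = build_hmm(a2), g2b = build_hmm(g6))
  tr2 <- hmm_tree(hmms2)
  key <- node_leafset_keys(tr2)
  expect_true("g1|g1b" %in% key || "g2|g2b" %in% key)
})

test_that("similarity network: SW scores match the DP oracle, e-values behave", {
  seqs <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            p2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            p3 = "GSHMWELRVDGGSWTEYQDSAGNVYAVNT",
            p4 = "MKTWYIGKQRQISFVKSHISRQLEERLGA")
  net <- similarity_network(seqs, evalue_cutoff = Inf)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B62 <- get("BLOSUM62", envir = data_env)
  for (r in seq_len(nrow(net$edges))) {
    e <- net$edges[r, ]
    expect_equal(e$score, sw_score_dp(seqs[[e$id1]], seqs[[e$id2]], B62))
  }
  # identical pair attains the minimal e-value among pairs involving either
  e12 <- net$edges$evalue[net$edges$id1 == "p1" & net$edges$id2 == "p2"]
  involving <- net$edges$evalue[net$edges$id1 %in% c("p1", "p2") |
                                  net$edges$id2 %in% c("p1", "p2")]
  expect_equal(e12, min(involving))
  # e-value strictly decreasing in score at fixed lengths
  ord <- order(net$edges$score)
  same_len <- net$edges[nchar(seqs[net$edges$id1]) == nchar(seqs[net$edges$id2]), ]
  if (nrow(same_len) > 1) {
    ord2 <- order(same_len$score)
    expect_true(all(diff(same_len$evalue[ord2]) <= 0))
  }
  # the edge set is monotone in the cutoff
  net_tight <- similarity_network(seqs, evalue_cutoff = 1e-6)
  expect_true(all(paste(net_tight$edges$id1, net_tight$edges$id2) %in%
                    paste(net$edges$id1, net$edges$id2)))
  expect_error(similarity_network(c(a = "MK", b = "")), "empty")
})

test_that("within-group similarity exceeds between-group on the family fixture", {
  fx <- card_family_fixture(seed = 1, n_groups = 3, taxa_per_group = 4,
                            n_sites = 70)
  seqs <- apply(fx$alignment, 1, paste, collapse = "")
  net <- similarity_network(seqs, groups = fx$groups, evalue_cutoff = Inf)
  g1 <- fx$groups[net$edges$id1]; g2 <- fx$groups[net$edges$id2]
  expect_lt(mean(net$edges$evalue[g1 == g2]),
            mean(net$edges$evalue[g1 != g2]))
  # GraphML and edge-list export round-trip
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  g <- export_network(net, gml, tsv)
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_true(file.exists(gml))
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
})
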