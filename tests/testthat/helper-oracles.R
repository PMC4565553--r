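# Independent brute-force oracles used across the test files.  These stay
# deliberately naive (explicit enumeration / plain DP) and never share code
# with the package's own algorithms.

# Likelihood of one site pattern by summing over every assignment of states
# to the internal nodes.  `P_edge` is indexed like tree$edge rows;
# `tip_state` is a named integer vector (NA = missing).
enum_site_lik <- function(tree, tip_state, P_edge, freq) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1):nn
  nstates <- length(freq)
  root <- ntip + 1
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(nstates)), length(internal))))
  for (g in seq_len(nrow(grid))) {
    assign_all <- integer(nn)
    assign_all[internal] <- grid[g, ]
    term <- freq[assign_all[root]]
    ok <- TRUE
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      s_p <- assign_all[p]
      if (ch <= ntip) {
        s_c <- tip_state[tree$tip.label[ch]]
        if (is.na(s_c)) next  # missing: sums to 1 over child states
        term <- term * P_edge[[k]][s_p, s_c]
      } else {
        term <- term * P_edge[[k]][s_p, assign_all[ch]]
      }
      if (term == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + term
  }
  unname(total)
}

# mixture (e.g. gamma categories) version: average over per-class P lists
enum_site_lik_mix <- function(tree, tip_state, P_lists, freq, weights) {
  sum(vapply(seq_along(P_lists), function(i)
    weights[i] * enum_site_lik(tree, tip_state, P_lists[[i]], freq),
    numeric(1)))
}

# marginal posterior at one internal node by brute-force Bayes over the same
# enumeration (joint likelihood with that node clamped to each state)
enum_node_posterior <- function(tree, tip_state, P_lists, freq, weights, node) {
  ntip <- length(tree$tip.label)
  nstates <- length(freq)
  out <- numeric(nstates)
  for (s in seq_len(nstates)) {
    tot <- 0
    for (i in seq_along(P_lists)) {
      P_edge <- P_lists[[i]]
      nn <- ntip + tree$Nnode
      internal <- setdiff((ntip + 1):nn, node)
      grid <- as.matrix(expand.grid(rep(list(seq_len(nstates)), length(internal))))
      if (!length(internal)) grid <- matrix(0, 1, 0)
      for (g in seq_len(nrow(grid))) {
        assign_all <- integer(nn)
        if (length(internal)) assign_all[internal] <- grid[g, ]
        assign_all[node] <- s
        term <- freq[assign_all[ntip + 1]]
        for (k in seq_len(nrow(tree$edge))) {
          p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
          s_p <- assign_all[p]
          if (ch <= ntip) {
            s_c <- tip_state[tree$tip.label[ch]]
            if (is.na(s_c)) next
            term <- term * P_edge[[k]][s_p, s_c]
          } else term <- term * P_edge[[k]][s_p, assign_all[ch]]
          if (term == 0) break
        }
        tot <- tot + weights[i] * term
      }
    }
    out[s] <- tot
  }
  unname(out / sum(out))
}

# minimal number of presence/absence changes over all internal labelings
enum_min_changes <- function(tree, tip_state) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  best <- Inf
  best_labelings <- list()
  for (g in seq_len(nrow(grid))) {
    lab <- integer(nn)
    lab[seq_len(ntip)] <- tip_state
    lab[internal] <- grid[g, ]
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (ch < best) { best <- ch; best_labelings <- list(lab) }
    else if (ch == best) best_labelings <- c(best_labelings, list(lab))
  }
  list(min_changes = best, labelings = best_labelings)
}

# affine-gap Smith-Waterman score (gap of length L costs open + L * ext)
sw_score_dp <- function(a, b, S, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
                     S[a[i - 1], b[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

# independent duplication/loss count for a rooted gene tree: LCA mapping via
# ape::getMRCA, losses by walking species-tree node paths
reconcile_oracle <- function(gene_tree, species_tree, leaf_map) {
  st_depth <- function(node) {
    length(ape::nodepath(species_tree, length(species_tree$tip.label) + 1, node)) - 1
  }
  map_of <- function(tips) {
    sp <- unique(unname(leaf_map[tips]))
    ids <- match(sp, species_tree$tip.label)
    if (length(ids) == 1) ids else ape::getMRCA(species_tree, ids)
  }
  ntip <- length(gene_tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(gene_tree$tip.label[node])
    unlist(lapply(gene_tree$edge[gene_tree$edge[, 1] == node, 2], desc))
  }
  dups <- 0; losses <- 0
  for (v in (ntip + 1):(ntip + gene_tree$Nnode)) {
    kids <- gene_tree$edge[gene_tree$edge[, 1] == v, 2]
    mv <- map_of(desc(v))
    mk <- vapply(kids, function(k) map_of(desc(k)), numeric(1))
    is_dup <- any(mk == mv)
    if (is_dup) dups <- dups + 1
    for (m in mk)
      losses <- losses + (st_depth(m) - st_depth(mv)) - 1 + as.integer(is_dup)
  }
  c(duplications = dups, losses = losses)
}

# small shared fixtures --------------------------------------------------

toy_protein_aln <- function() {
  matrix(c("A", "R", "N",
           "C", "C", "W"), nrow = 3,
         dimnames = list(c("a", "b", "c"), NULL))
}

toy_tree3 <- function() ape::read.tree(text = "((a:0.3,b:0.5):0.2,c:0.7):0;")
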