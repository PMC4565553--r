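# Distance trees, topology testing and duplication/loss rooting.

#' Neighbor joining
#'
#' Standard Saitou-Nei agglomeration.  Negative branch lengths arising at a
#' join are clamped to zero and the deficit moved onto the sibling edge, so
#' the sum of the two joined edges is preserved.
#'
#' @param d symmetric distance matrix with zero diagonal and dimnames.
#' @return an unrooted `phylo` (trifurcating root).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stop("asymmetric distance matrix")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  sub <- labels  # newick fragment per active cluster
  while (n > 3) {
    r <- rowSums(d)
    Qm <- (n - 2) * d - outer(r, r, "+")
    diag(Qm) <- Inf
    ij <- which(Qm == min(Qm), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], bi, sub[j], bj)
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    sub <- c(sub[keep], merged)
    n <- n - 1
  }
  # final trifurcation by the three-point formulas
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(ba, bb, bc), 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[1], b[1], sub[2], b[2], sub[3], b[3])
  ape::read.tree(text = txt)
}

#' Shimodaira-Hasegawa topology test with RELL bootstrap
#'
#' Branch lengths of every candidate topology are optimised under the model
#' (other parameters fixed), per-site log-likelihoods collected, and the SH
#' procedure applied with resampling-estimated log-likelihoods: sites are
#' resampled, per-tree sums are recentred on their bootstrap means, and the
#' p-value of tree k is the fraction of replicates whose recentred deficit
#' reaches the observed deficit to the best tree.
#'
#' @param alignment alignment (matrix or records).
#' @param candidate_trees list of `phylo` objects on the same taxa.
#' @param model substitution model.
#' @param n_rell number of RELL bootstrap replicates.
#' @param seed RNG seed.
#' @param optimize whether to optimise branch lengths per topology first.
#' @param control optimiser control list (see [optimize_model()]).
#' @return data.frame with per-tree `lnL`, `delta` and `p_sh`.
#' @export
sh_test <- function(alignment, candidate_trees, model, n_rell = 1000, seed = 1,
                    optimize = TRUE, control = list()) {
  if (length(candidate_trees) < 2) stop("need at least 2 candidate topologies")
  site_ll <- lapply(candidate_trees, function(tr) {
    if (optimize)
      tr <- optimize_model(alignment, tr, model, free = "branch_lengths",
                           control = control)$tree
    log_likelihood(alignment, tr, model)$sites
  })
  ns <- unique(vapply(site_ll, length, integer(1)))
  if (length(ns) != 1) stop("site counts differ across trees")
  S <- do.call(rbind, site_ll)         # trees x sites
  tot <- rowSums(S)
  delta <- max(tot) - tot
  set.seed(seed)
  idx <- matrix(sample.int(ns, ns * n_rell, replace = TRUE), ns, n_rell)
  boot <- matrix(NA_real_, length(tot), n_rell)
  for (b in seq_len(n_rell)) boot[, b] <- rowSums(S[, idx[, b], drop = FALSE])
  cent <- boot - rowMeans(boot)
  colmax <- apply(cent, 2, max)
  dstar <- matrix(colmax, nrow(cent), n_rell, byrow = TRUE) - cent  # deficits
  p <- vapply(seq_along(tot), function(k) mean(dstar[k, ] >= delta[k]), numeric(1))
  data.frame(tree = seq_along(tot), lnL = tot, delta = delta, p_sh = p)
}

# species-tree bookkeeping for reconciliation: per-node depth and ancestry
.species_index <- function(species_tree) {
  st <- species_tree
  ntip <- length(st$tip.label)
  nn <- ntip + st$Nnode
  root <- ntip + 1L
  parent <- integer(nn)
  for (k in seq_len(nrow(st$edge))) parent[st$edge[k, 2]] <- st$edge[k, 1]
  depth <- integer(nn)
  po <- rev(unique(stats::reorder(st, "postorder")$edge[, 1]))
  depth[root] <- 0L
  for (nd in po) {
    kids <- st$edge[st$edge[, 1] == nd, 2]
    depth[kids] <- depth[nd] + 1L
  }
  anc <- lapply(seq_len(nn), function(v) {
    path <- v
    while (v != root) { v <- parent[v]; path <- c(path, v) }
    path
  })
  list(tree = st, ntip = ntip, depth = depth, anc = anc)
}

.species_lca <- function(si, a, b) {
  common <- intersect(si$anc[[a]], si$anc[[b]])
  common[which.max(si$depth[common])]
}

# reconcile one rooted gene tree: LCA mapping, duplication and loss counts
.reconcile <- function(gene_tree, si, leaf_map) {
  gt <- gene_tree
  ntip <- length(gt$tip.label)
  nn <- ntip + gt$Nnode
  M <- integer(nn)
  sp_of <- match(leaf_map[gt$tip.label], si$tree$tip.label)
  if (anyNA(sp_of))
    stop("unmappable gene-tree leaf label(s): ",
         paste(gt$tip.label[is.na(sp_of)], collapse = ", "))
  M[seq_len(ntip)] <- sp_of
  po <- stats::reorder(gt, "postorder")
  dups <- 0L; losses <- 0L
  for (nd in unique(po$edge[, 1])) {
    kids <- po$edge[po$edge[, 1] == nd, 2]
    m <- M[kids[1]]
    for (k in kids[-1]) m <- .species_lca(si, m, M[k])
    M[nd] <- m
    is_dup <- any(M[kids] == m)
    if (is_dup) dups <- dups + 1L
    for (k in kids) {
      dd <- si$depth[M[k]] - si$depth[m]
      losses <- losses + dd - 1L + as.integer(is_dup)
    }
  }
  c(duplications = dups, losses = losses)
}

#' Root a gene tree by duplication/loss parsimony
#'
#' Every edge of the unrooted gene tree is tried as a root position; the
#' rooted tree is LCA-mapped onto the species tree, duplications and losses
#' are counted with unit costs, and all edges minimising duplications +
#' losses are returned.
#'
#' @param gene_tree unrooted `phylo`.
#' @param species_tree rooted `phylo` of the species.
#' @param leaf_map named character vector mapping gene-tree leaf labels to
#'   species-tree leaf labels; by default the part of the gene leaf label
#'   before the first underscore is used.
#' @return list with `best_edges` (data.frame of optimal root edges described
#'   by the leaf set on one side, with duplication and loss counts) and
#'   `all_edges` (costs for every candidate root).
#' @export
root_by_duplication_loss <- function(gene_tree, species_tree, leaf_map = NULL) {
  if (is.null(leaf_map)) {
    leaf_map <- sub("_.*$", "", gene_tree$tip.label)
    names(leaf_map) <- gene_tree$tip.label
  }
  si <- .species_index(species_tree)
  ut <- ape::unroot(gene_tree)
  keys <- node_leafset_keys(ut)
  ntip <- length(ut$tip.label)
  res <- lapply(seq_len(nrow(ut$edge)), function(k) {
    ch <- ut$edge[k, 2]
    og <- strsplit(keys[ch], "|", fixed = TRUE)[[1]]
    if (length(og) >= ntip) return(NULL)
    rt <- tryCatch(ape::root(ut, outgroup = og, resolve.root = TRUE),
                   error = function(e) NULL)
    if (is.null(rt)) return(NULL)
    cost <- .reconcile(rt, si, leaf_map)
    data.frame(edge_leafset = keys[ch], duplications = cost[1], losses = cost[2],
               total = sum(cost))
  })
  all_edges <- do.call(rbind, res)
  all_edges <- all_edges[!duplicated(all_edges$edge_leafset), , drop = FALSE]
  rownames(all_edges) <- NULL
  best <- all_edges[all_edges$total == min(all_edges$total), , drop = FALSE]
  list(best_edges = best, all_edges = all_edges)
}
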