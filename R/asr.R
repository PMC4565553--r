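# Marginal ancestral sequence reconstruction (empirical Bayes), integration
# across a weighted set of topologies, parsimony reconstruction of indels,
# confidence summaries and the amino-acid stationarity check.

#' Marginal ancestral reconstruction
#'
#' Empirical-Bayes marginal posteriors: for each internal node and site,
#' `P(state | tip data)` integrating over all other nodes and the
#' discrete-gamma rate categories.  MAP ties are broken by the fixed residue
#' order `ARNDCQEGHILKMFPSTWYV`.
#'
#' @param alignment alignment matrix or FASTA records.
#' @param tree rooted `phylo`.
#' @param model fitted `protein_model` (parameters are taken as given).
#' @return object of class `marginal_reconstruction`: a list of per-node
#'   records keyed by leaf-set key, each with `posterior` (sites x 20), `map`
#'   (residues), `map_p`, `alt` (second-best residues), `alt_p`, and
#'   `presence` (defaults to all-present; see [parsimony_indels()]).
#' @export
marginal_reconstruct <- function(alignment, tree, model) {
  aln <- .aln_for_model(alignment, model)
  if (!setequal(rownames(aln), tree$tip.label))
    stop("alignment taxa do not match tree tips")
  tip_idx <- .tip_indices(aln, "protein")[tree$tip.label, , drop = FALSE]
  prep <- .prep_tree(tree)
  classes <- .model_classes(model, tree)
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  post <- .node_posteriors(prep, tip_idx, 20L, classes, nodes)
  keys <- node_leafset_keys(tree)
  recs <- list()
  for (n in nodes) {
    pp <- post[[n]]
    colnames(pp) <- AA_ALPHABET
    map_i <- max.col(pp, ties.method = "first")
    map_p <- pp[cbind(seq_len(nrow(pp)), map_i)]
    pp2 <- pp
    pp2[cbind(seq_len(nrow(pp)), map_i)] <- -Inf
    alt_i <- max.col(pp2, ties.method = "first")
    alt_p <- pp[cbind(seq_len(nrow(pp)), alt_i)]
    recs[[keys[n]]] <- list(posterior = pp,
                            map = AA_ALPHABET[map_i], map_p = map_p,
                            alt = AA_ALPHABET[alt_i], alt_p = alt_p,
                            presence = rep(TRUE, nrow(pp)))
  }
  structure(list(nodes = recs, tree = tree, model = model),
            class = "marginal_reconstruction")
}

#' Integrate reconstructions across a weighted tree set
#'
#' The posterior of the target clade at each site is the weight-averaged
#' posterior over the trees that contain the clade, renormalised by the
#' total weight of those trees; the fraction of tree-set weight supporting
#' the clade is reported.
#'
#' @param reconstructions list of `marginal_reconstruction`, one per tree.
#' @param weights tree weights (normalised internally).
#' @param target_clade character vector of leaf labels defining the clade.
#' @return list with `posterior`, `map`, `map_p`, `alt`, `alt_p`,
#'   `support` (weight fraction of trees containing the clade) and
#'   `clade_key`.
#' @export
integrate_over_trees <- function(reconstructions, weights, target_clade) {
  weights <- weights / sum(weights)
  key <- paste(sort(target_clade), collapse = "|")
  have <- vapply(reconstructions, function(r) key %in% names(r$nodes), logical(1))
  if (!any(have)) stop("clade {", key, "} present in no tree")
  wsum <- sum(weights[have])
  post <- NULL
  for (i in which(have)) {
    p_i <- reconstructions[[i]]$nodes[[key]]$posterior * weights[i]
    post <- if (is.null(post)) p_i else post + p_i
  }
  post <- post / wsum
  map_i <- max.col(post, ties.method = "first")
  map_p <- post[cbind(seq_len(nrow(post)), map_i)]
  post2 <- post
  post2[cbind(seq_len(nrow(post)), map_i)] <- -Inf
  alt_i <- max.col(post2, ties.method = "first")
  list(posterior = post, map = AA_ALPHABET[map_i], map_p = map_p,
       alt = AA_ALPHABET[alt_i], alt_p = post[cbind(seq_len(nrow(post)), alt_i)],
       support = wsum, clade_key = key)
}

# Fitch parsimony for one presence/absence site pattern on one tree.
# State sets encoded as integers: 1 = {absent}, 2 = {present}, 3 = both.
.fitch_site <- function(prep, x) {
  edge <- prep$edge; ntip <- prep$ntip
  nn <- ntip + prep$tree$Nnode
  setv <- integer(nn)
  setv[seq_len(ntip)] <- ifelse(x, 2L, 1L)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    setv[p] <- if (setv[p] == 0L) setv[ch] else {
      inter <- bitwAnd(setv[p], setv[ch])
      if (inter > 0L) inter else bitwOr(setv[p], setv[ch])
    }
  }
  state <- integer(nn)
  state[seq_len(ntip)] <- as.integer(x)
  root <- prep$root
  state[root] <- if (setv[root] == 1L) 0L else 1L  # ambiguity -> presence
  for (k in rev(seq_len(nrow(edge)))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    if (ch <= ntip) next
    ps <- state[p] + 1L  # 1 = absent, 2 = present
    state[ch] <- if (bitwAnd(setv[ch], bitwShiftL(1L, ps - 1L)) > 0L) ps - 1L
      else if (setv[ch] == 1L) 0L else 1L
  }
  state
}

#' Parsimony reconstruction of indel presence/absence
#'
#' Sites are coded present (residue) / absent (gap) at the tips; Fitch
#' parsimony labels each internal node per site and per tree (ambiguous root
#' states resolved toward presence); the per-node presence probability is
#' the weight-averaged presence over the trees containing the node, and the
#' final call is presence iff that probability is >= 0.5.
#'
#' @param alignment alignment matrix or FASTA records (gaps = `-`).
#' @param tree_set `weighted_tree_set` (or a single `phylo`).
#' @param weights optional weights when `tree_set` is a plain list of trees.
#' @return list with per-node-key `probability` (matrix nodes x sites) and
#'   `presence` (logical matrix, the >= 0.5 calls).
#' @export
parsimony_indels <- function(alignment, tree_set, weights = NULL) {
  if (is.data.frame(alignment)) alignment <- alignment_matrix(alignment)
  if (inherits(tree_set, "phylo")) tree_set <- weighted_tree_set(list(tree_set))
  if (is.list(tree_set) && !inherits(tree_set, "weighted_tree_set"))
    tree_set <- weighted_tree_set(tree_set, weights)
  trees <- tree_set$trees
  w <- tree_set$weights
  nsites <- ncol(alignment)
  acc <- list()   # key -> c(weighted presence sum, weight sum)
  wsum <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    prep <- .prep_tree(tr)
    ntip <- length(tr$tip.label)
    pres <- alignment[tr$tip.label, , drop = FALSE] != "-"
    keys <- node_leafset_keys(tr)
    nodes <- (ntip + 1L):(ntip + tr$Nnode)
    lab <- matrix(NA_integer_, length(nodes), nsites)
    for (s in seq_len(nsites))
      lab[, s] <- .fitch_site(prep, pres[, s])[nodes]
    for (j in seq_along(nodes)) {
      key <- keys[nodes[j]]
      if (is.null(acc[[key]])) { acc[[key]] <- numeric(nsites); wsum[[key]] <- 0 }
      acc[[key]] <- acc[[key]] + w[i] * lab[j, ]
      wsum[[key]] <- wsum[[key]] + w[i]
    }
  }
  prob <- do.call(rbind, lapply(names(acc), function(k) acc[[k]] / wsum[[k]]))
  rownames(prob) <- names(acc)
  list(probability = prob, presence = prob >= 0.5)
}

#' Confidence summary of an ancestral reconstruction
#'
#' Reports, per node and pooled over nodes, the fraction of present sites
#' whose MAP posterior exceeds each threshold; the count and fraction of
#' sites whose second-best posterior exceeds `alt_threshold`; and, among
#' those ambiguous sites, the fraction whose alternative residue falls in
#' the same biochemical class as the MAP residue.
#'
#' @param reconstruction `marginal_reconstruction` (or a list of per-node
#'   records in the same shape).
#' @param thresholds MAP posterior thresholds.
#' @param alt_threshold second-best posterior threshold for "ambiguous".
#' @param classes biochemical classes ([biochemical_classes()] by default).
#' @return list with `per_node` (data.frame) and `pooled` (one-row
#'   data.frame).
#' @export
confidence_summary <- function(reconstruction, thresholds = c(0.95, 0.90, 0.80),
                               alt_threshold = 0.3,
                               classes = biochemical_classes()) {
  nodes <- if (inherits(reconstruction, "marginal_reconstruction"))
    reconstruction$nodes else reconstruction
  if (!length(nodes)) stop("empty reconstruction")
  lk <- .class_lookup(classes)
  per <- lapply(names(nodes), function(key) {
    r <- nodes[[key]]
    keep <- r$presence
    map_p <- r$map_p[keep]; alt_p <- r$alt_p[keep]
    map <- r$map[keep]; alt <- r$alt[keep]
    amb <- alt_p > alt_threshold
    row <- data.frame(node = key, n_sites = sum(keep))
    for (th in thresholds)
      row[[sprintf("frac_above_%g", th)]] <- mean(map_p > th)
    row$n_ambiguous <- sum(amb)
    row$frac_ambiguous <- mean(amb)
    row$frac_same_class <- if (any(amb)) mean(lk[map[amb]] == lk[alt[amb]]) else NA_real_
    row
  })
  per_node <- do.call(rbind, per)
  all_map_p <- unlist(lapply(nodes, function(r) r$map_p[r$presence]))
  all_alt_p <- unlist(lapply(nodes, function(r) r$alt_p[r$presence]))
  all_map <- unlist(lapply(nodes, function(r) r$map[r$presence]))
  all_alt <- unlist(lapply(nodes, function(r) r$alt[r$presence]))
  amb <- all_alt_p > alt_threshold
  pooled <- data.frame(n_sites = length(all_map_p))
  for (th in thresholds)
    pooled[[sprintf("frac_above_%g", th)]] <- mean(all_map_p > th)
  pooled$n_ambiguous <- sum(amb)
  pooled$frac_ambiguous <- mean(amb)
  pooled$frac_same_class <- if (any(amb)) mean(lk[all_map[amb]] == lk[all_alt[amb]]) else NA_real_
  list(per_node = per_node, pooled = pooled)
}

#' Amino-acid stationarity check
#'
#' Each group's residue composition is compared to the composition pooled
#' across all groups by a chi-square goodness-of-fit test (df = number of
#' observed states minus 1); gaps are excluded from all counts.
#'
#' @param groups named list of character matrices or sequence vectors.
#' @return data.frame with per-group `statistic`, `df` and `p`.
#' @export
stationarity_test <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  count1 <- function(x) {
    ch <- unlist(strsplit(paste(as.vector(x), collapse = ""), ""))
    table(factor(ch[ch %in% AA_ALPHABET], levels = AA_ALPHABET))
  }
  counts <- lapply(groups, count1)
  for (g in names(counts))
    if (sum(counts[[g]]) == 0) stop("group with zero residues: ", g)
  pool <- Reduce(`+`, counts)
  pfreq <- pool / sum(pool)
  used <- pool > 0
  out <- lapply(names(counts), function(g) {
    o <- as.numeric(counts[[g]])[used]
    e <- as.numeric(pfreq)[used] * sum(o)
    stat <- sum((o - e)^2 / e)
    df <- sum(used) - 1
    data.frame(group = g, statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Write MAP ancestral sequences to FASTA
#'
#' Absent sites (per the presence calls) are written as gaps.
#'
#' @param reconstruction `marginal_reconstruction`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_ancestral_fasta <- function(reconstruction, path) {
  recs <- do.call(rbind, lapply(names(reconstruction$nodes), function(key) {
    r <- reconstruction$nodes[[key]]
    s <- ifelse(r$presence, r$map, "-")
    data.frame(id = gsub("\\|", ",", key), seq = paste(s, collapse = ""))
  }))
  write_fasta(recs, path)
}
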