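# Felsenstein pruning over rate/site-class mixtures, with per-site scaling,
# plus the up-down pass that yields marginal ancestral posteriors.
#
# Internally a "class" is one component of the site mixture: a generator
# eigendecomposition (optionally a second one for a foreground branch set),
# a rate multiplier and a mixture weight.  A gamma category, a sites-model
# class and a branch-site Model A class are all the same object here.

# integer state indices for tips; NA = missing (gap/X/ambiguous)
.tip_indices <- function(aln, type = c("protein", "codon")) {
  type <- match.arg(type)
  states <- if (type == "protein") AA_ALPHABET else sense_codons()
  idx <- matrix(match(aln, states), nrow = nrow(aln),
                dimnames = dimnames(aln))
  idx
}

# postorder bookkeeping for one rooted (or trifurcating-root) tree
.prep_tree <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nodes_po <- unique(po$edge[, 1])  # internal nodes in postorder
  list(tree = po, edge = po$edge, elen = po$edge.length, ntip = ntip,
       root = ntip + 1L, nodes_po = nodes_po)
}

#' Leaf-set keys for every node of a tree
#'
#' Nodes are identified throughout the package by the sorted set of their
#' descendant leaves, joined with `|`; this is stable across topologies.
#'
#' @param tree a `phylo`.
#' @return character vector indexed by node number (tips first).
#' @export
node_leafset_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  po <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
}

#' Find the branch whose descendant leaf set equals a given set
#'
#' @param tree a `phylo`.
#' @param leaves character vector of leaf labels (the bipartition side below
#'   the branch).
#' @return the child node id of the matching branch.
#' @export
branch_by_leafset <- function(tree, leaves) {
  key <- paste(sort(leaves), collapse = "|")
  keys <- node_leafset_keys(tree)
  hit <- which(keys == key)
  if (!length(hit)) stop("no branch with leaf set {", key, "} in tree")
  hit[1]
}

# fast column maxima (pmax over rows); apply() is too slow in hot loops
.colmax <- function(m) do.call(pmax, asplit(m, 1))

# One class's pruning pass.  Edge rows are visited in postorder, so a child's
# (rescaled) partial is complete before the edge above it is processed.
# Returns internal-node partials, per-node log scaling factors, and per-child
# contributions (P %*% D_child) for reuse in the up pass.
.prune_class <- function(prep, tip_idx, nstates, class) {
  edge <- prep$edge; elen <- prep$elen; ntip <- prep$ntip
  nsites <- ncol(tip_idx)
  nn <- ntip + prep$tree$Nnode
  P_edge <- vector("list", nrow(edge))
  for (k in seq_len(nrow(edge))) {
    eig <- if (edge[k, 2] %in% class$fg_child) class$eig_fg else class$eig
    t_eff <- elen[k] * class$rate
    P_edge[[k]] <- if (t_eff <= 0) diag(nstates) else .p_matrix(eig, t_eff)
  }
  partial <- vector("list", nn)
  lognorm <- rep(list(numeric(nsites)), nn)
  contrib <- vector("list", nn)  # indexed by child node
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    P <- P_edge[[k]]
    if (ch <= ntip) {
      idx <- tip_idx[ch, ]
      cp <- matrix(1, nstates, nsites)
      obs <- !is.na(idx)
      if (any(obs)) cp[, obs] <- P[, idx[obs]]
      ln_ch <- numeric(nsites)
    } else {
      # rescale the now-complete child partial before use; a cheap global
      # guard skips per-column maxima on shallow trees, where no column can
      # underflow
      pc <- partial[[ch]]
      if (max(pc) < 1e-80) {
        cm <- .colmax(pc)
        cm[cm <= 0] <- 1
        pc <- pc / rep(cm, each = nstates)
        partial[[ch]] <- pc
        lognorm[[ch]] <- lognorm[[ch]] + log(cm)
      }
      ln_ch <- lognorm[[ch]]
      cp <- P %*% pc
    }
    contrib[[ch]] <- cp
    if (is.null(partial[[p]])) {
      partial[[p]] <- cp
      lognorm[[p]] <- ln_ch
    } else {
      partial[[p]] <- partial[[p]] * cp
      lognorm[[p]] <- lognorm[[p]] + ln_ch
    }
  }
  list(partial = partial, lognorm = lognorm, contrib = contrib,
       P_edge = P_edge)
}

# per-class per-site log-likelihoods: matrix n_class x n_sites
.class_site_loglik <- function(prep, tip_idx, nstates, classes,
                               keep_prune = FALSE) {
  nsites <- ncol(tip_idx)
  out <- matrix(NA_real_, length(classes), nsites)
  prunes <- if (keep_prune) vector("list", length(classes)) else NULL
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    if (prep$ntip == 1L) {  # degenerate single-taxon case
      idx <- tip_idx[1, ]
      lik <- ifelse(is.na(idx), 1, cl$freq[idx])
      out[i, ] <- log(lik)
      next
    }
    pr <- .prune_class(prep, tip_idx, nstates, cl)
    rootp <- pr$partial[[prep$root]]
    lik <- colSums(rootp * cl$freq)
    out[i, ] <- log(lik) + pr$lognorm[[prep$root]]
    if (keep_prune) prunes[[i]] <- pr
  }
  list(class_ll = out, prunes = prunes)
}

# mixture of per-class site log-likelihoods with weights w
.mix_loglik <- function(class_ll, w) {
  if (is.null(dim(class_ll))) class_ll <- matrix(class_ll, nrow = 1)
  m <- .colmax(class_ll)
  site <- m + log(colSums(exp(sweep(class_ll, 2, m)) * w))
  list(total = sum(site), sites = site)
}

# build the class list for a model on a given tree
.model_classes <- function(model, tree) {
  if (inherits(model, "protein_model")) {
    Q <- build_rate_matrix(model)
    eig <- .q_eigen(Q)
    rates <- discrete_gamma(model$alpha, model$ncat)
    lapply(seq_len(model$ncat), function(k)
      list(eig = eig, eig_fg = NULL, fg_child = integer(0), rate = rates[k],
           weight = 1 / model$ncat, freq = model$frequencies))
  } else if (inherits(model, "codon_model")) {
    fg_child <- integer(0)
    eig_fg <- NULL
    if (!is.null(model$foreground) && !is.null(model$omega2)) {
      fg_child <- if (is.character(model$foreground))
        branch_by_leafset(tree, model$foreground) else as.integer(model$foreground)
      eig_fg <- .q_eigen(build_rate_matrix(model, foreground = TRUE))
    }
    lapply(seq_along(model$site_classes$p), function(k) {
      eig <- .q_eigen(build_rate_matrix(model, class = k))
      list(eig = eig, eig_fg = eig_fg, fg_child = fg_child, rate = 1,
           weight = model$site_classes$p[k], freq = model$codon_freqs)
    })
  } else stop("unknown model class")
}

.aln_for_model <- function(alignment, model) {
  if (is.data.frame(alignment)) {
    alignment <- if (inherits(model, "codon_model")) codon_matrix(alignment)
    else alignment_matrix(alignment)
  }
  alignment
}

#' Phylogenetic log-likelihood by pruning
#'
#' Computes the log-likelihood of an alignment on a fixed tree under an
#' LG(+F)+Gamma protein model or a codon site-class model, by Felsenstein
#' pruning over the mixture of rate/site classes.  Gaps and ambiguous states
#' are treated as missing data.
#'
#' @param alignment character matrix ([alignment_matrix()] /
#'   [codon_matrix()]) or a FASTA record data.frame.
#' @param tree a `phylo` with branch lengths (substitutions per site/codon).
#' @param model `protein_model` or `codon_model`.
#' @return list with `total` (log-likelihood), `sites` (per-site
#'   log-likelihoods) and `class_ll` (per-class per-site matrix).
#' @export
log_likelihood <- function(alignment, tree, model) {
  aln <- .aln_for_model(alignment, model)
  type <- if (inherits(model, "codon_model")) "codon" else "protein"
  if (!setequal(rownames(aln), tree$tip.label))
    stop("alignment taxa do not match tree tips")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  tip_idx <- .tip_indices(aln, type)[tree$tip.label, , drop = FALSE]
  nstates <- if (type == "codon") 61L else 20L
  prep <- .prep_tree(tree)
  classes <- .model_classes(model, tree)
  cs <- .class_site_loglik(prep, tip_idx, nstates, classes)
  w <- vapply(classes, `[[`, numeric(1), "weight")
  mix <- .mix_loglik(cs$class_ll, w)
  list(total = mix$total, sites = mix$sites, class_ll = cs$class_ll)
}

# Up-down pass: marginal posteriors over states at internal nodes.
# For each mixture class, the "up" partial U_n carries the likelihood of all
# data outside the subtree of n conditional on the state at n; the marginal
# posterior at n mixes U_n * D_n across classes with the class weights and
# the accumulated log scaling factors.
.node_posteriors <- function(prep, tip_idx, nstates, classes, nodes = NULL) {
  ntip <- prep$ntip
  nn <- ntip + prep$tree$Nnode
  nsites <- ncol(tip_idx)
  if (is.null(nodes)) nodes <- (ntip + 1L):nn
  edge <- prep$edge
  nclass <- length(classes)
  w <- vapply(classes, `[[`, numeric(1), "weight")

  joint <- vector("list", nclass)     # per class: list over nodes of U*D
  logw <- vector("list", nclass)      # per class: per node log scale vectors
  for (ci in seq_len(nclass)) {
    cl <- classes[[ci]]
    pr <- .prune_class(prep, tip_idx, nstates, cl)
    U <- vector("list", nn)
    lnU <- rep(list(numeric(nsites)), nn)
    U[[prep$root]] <- matrix(cl$freq, nstates, nsites)
    children <- split(seq_len(nrow(edge)), edge[, 1])
    for (k in rev(seq_len(nrow(edge)))) {   # preorder
      p <- edge[k, 1]; ch <- edge[k, 2]
      if (ch <= ntip) next
      prod_other <- U[[p]]
      ln <- lnU[[p]]
      for (k2 in children[[as.character(p)]]) {
        c2 <- edge[k2, 2]
        if (c2 == ch) next
        prod_other <- prod_other * pr$contrib[[c2]]
        ln <- ln + pr$lognorm[[c2]]
      }
      u <- crossprod(pr$P_edge[[k]], prod_other)
      cm <- .colmax(u)
      if (min(cm) < 1e-120) {
        cm[cm <= 0] <- 1
        U[[ch]] <- u / rep(cm, each = nstates)
        lnU[[ch]] <- ln + log(cm)
      } else {
        U[[ch]] <- u
        lnU[[ch]] <- ln
      }
    }
    jl <- vector("list", nn)
    lw <- vector("list", nn)
    for (n in nodes) {
      jl[[n]] <- U[[n]] * pr$partial[[n]]
      lw[[n]] <- lnU[[n]] + pr$lognorm[[n]]
    }
    joint[[ci]] <- jl
    logw[[ci]] <- lw
  }

  out <- vector("list", nn)
  for (n in nodes) {
    lw_n <- do.call(rbind, lapply(seq_len(nclass), function(ci) logw[[ci]][[n]]))
    m <- apply(lw_n, 2, max)
    post <- matrix(0, nstates, nsites)
    for (ci in seq_len(nclass))
      post <- post + joint[[ci]][[n]] *
        rep(w[ci] * exp(lw_n[ci, ] - m), each = nstates)
    tot <- colSums(post)
    out[[n]] <- t(post / rep(tot, each = nstates))
  }
  out
}

# fast path: per-site log-likelihood for one class given precomputed
# per-edge transition matrices (shared across Model A classes)
.build_P_list <- function(prep, eig, rate = 1) {
  nstates <- length(eig$freq)
  lapply(seq_len(nrow(prep$edge)), function(k) {
    t_eff <- prep$elen[k] * rate
    if (t_eff <= 0) diag(nstates) else .p_matrix(eig, t_eff)
  })
}

.site_ll_P <- function(prep, tip_idx, nstates, P_edge, freq) {
  edge <- prep$edge; ntip <- prep$ntip
  nsites <- ncol(tip_idx)
  nn <- ntip + prep$tree$Nnode
  partial <- vector("list", nn)
  lognorm <- rep(list(numeric(nsites)), nn)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    P <- P_edge[[k]]
    if (ch <= ntip) {
      idx <- tip_idx[ch, ]
      cp <- matrix(1, nstates, nsites)
      obs <- !is.na(idx)
      if (any(obs)) cp[, obs] <- P[, idx[obs]]
      ln_ch <- numeric(nsites)
    } else {
      pc <- partial[[ch]]
      if (max(pc) < 1e-80) {
        cm <- .colmax(pc)
        cm[cm <= 0] <- 1
        pc <- pc / rep(cm, each = nstates)
        lognorm[[ch]] <- lognorm[[ch]] + log(cm)
      }
      ln_ch <- lognorm[[ch]]
      cp <- P %*% pc
    }
    if (is.null(partial[[p]])) {
      partial[[p]] <- cp
      lognorm[[p]] <- ln_ch
    } else {
      partial[[p]] <- partial[[p]] * cp
      lognorm[[p]] <- lognorm[[p]] + ln_ch
    }
  }
  log(colSums(partial[[prep$root]] * freq)) + lognorm[[prep$root]]
}
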