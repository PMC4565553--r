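# Synthetic-data generators: random trees, protein alignments under
# LG(+F)+Gamma with true ancestral states recorded, codon alignments under
# neutral / sites / branch-site-released regimes, and biolayer-
# interferometry-like binding traces under a 1:1 Langmuir model.
# All generators are deterministic under a fixed seed.

#' Random rooted binary tree
#'
#' Branch lengths are drawn uniformly and rescaled so their sum equals
#' `total_length`.
#'
#' @param n_taxa number of tips (>= 3).
#' @param total_length target sum of branch lengths.
#' @param seed RNG seed.
#' @return rooted binary `phylo`.
#' @export
random_tree <- function(n_taxa, total_length = 1, seed = 1) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- tr$edge.length * total_length / sum(tr$edge.length)
  tr
}

# walk states down the tree: root draw from freq, then per-edge transitions;
# eig_for_edge(k) supplies the decomposition, rate_site the per-site rate
.evolve_states <- function(tree, nstates, freq, n_sites, eig_for_edge,
                           rate_site) {
  prep <- .prep_tree(tree)
  edge <- prep$edge; elen <- prep$elen
  ntip <- prep$ntip
  nn <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nn, n_sites)
  states[prep$root, ] <- sample.int(nstates, n_sites, replace = TRUE, prob = freq)
  rate_levels <- sort(unique(rate_site))
  for (k in rev(seq_len(nrow(edge)))) {  # preorder: parent before child
    p <- edge[k, 1]; ch <- edge[k, 2]
    st <- integer(n_sites)
    for (r in rate_levels) {
      sel <- which(rate_site == r)
      if (!length(sel)) next
      t_eff <- elen[k] * r
      if (t_eff <= 0) { st[sel] <- states[p, sel]; next }
      P <- .p_matrix(eig_for_edge(k), t_eff)
      for (s in unique(states[p, sel])) {
        at <- sel[states[p, sel] == s]
        st[at] <- sample.int(nstates, length(at), replace = TRUE, prob = P[s, ])
      }
    }
    states[ch, ] <- st
  }
  states
}

#' Simulate a protein alignment along a tree
#'
#' Each site is assigned one discrete-gamma rate category; the root state is
#' drawn from the model's stationary frequencies; true internal-node states
#' are recorded for error scoring.
#'
#' @param tree rooted `phylo` with nonnegative branch lengths.
#' @param model `protein_model`.
#' @param n_sites number of alignment columns.
#' @param seed RNG seed.
#' @return list with `alignment` (tips x sites character matrix),
#'   `ancestors` (internal nodes x sites, rownames = leaf-set keys),
#'   `site_categories`, `tree`, `model`.
#' @export
simulate_protein_alignment <- function(tree, model, n_sites, seed = 1) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  set.seed(seed)
  rates <- discrete_gamma(model$alpha, model$ncat)
  cat_site <- sample.int(model$ncat, n_sites, replace = TRUE)
  eig <- .q_eigen(build_rate_matrix(model))
  states <- .evolve_states(tree, 20L, model$frequencies, n_sites,
                           function(k) eig, rates[cat_site])
  ntip <- length(tree$tip.label)
  aln <- matrix(AA_ALPHABET[states[seq_len(ntip), ]], ntip, n_sites,
                dimnames = list(tree$tip.label, NULL))
  keys <- node_leafset_keys(tree)
  anc_rows <- (ntip + 1L):(ntip + tree$Nnode)
  anc <- matrix(AA_ALPHABET[states[anc_rows, ]], length(anc_rows), n_sites,
                dimnames = list(keys[anc_rows], NULL))
  list(alignment = aln, ancestors = anc, site_categories = cat_site,
       tree = tree, model = model)
}

#' Simulate an in-frame codon alignment
#'
#' Regimes: `neutral` (omega = 1 at all sites and branches), `sites` (a
#' proportion `p0` of sites evolves with `omega0`, the rest neutrally) and
#' `branch_sites_released` (sites regime on the background, but every site
#' neutral on the foreground branch).
#'
#' @param tree rooted `phylo`; branch lengths in expected substitutions per
#'   codon under the regime's site-class mixture.
#' @param model `codon_model` carrying `kappa` and `codon_freqs` (its own
#'   site classes are ignored; the regime defines them).
#' @param n_codons number of codon sites.
#' @param regime one of `"neutral"`, `"sites"`, `"branch_sites_released"`.
#' @param foreground foreground branch (leaf set or child-node id), required
#'   for `branch_sites_released`.
#' @param p0,omega0 sites-regime parameters.
#' @param seed RNG seed.
#' @return list with `codons` (tips x sites codon matrix), `site_class`
#'   (1 = constrained, 2 = neutral), `tree`, `regime`.
#' @export
simulate_codon_alignment <- function(tree, model, n_codons,
                                     regime = c("neutral", "sites",
                                                "branch_sites_released"),
                                     foreground = NULL, p0 = 0.8, omega0 = 0.1,
                                     seed = 1) {
  regime <- match.arg(regime)
  set.seed(seed)
  classes <- switch(regime,
    neutral = list(p = 1, omega = 1),
    sites = ,
    branch_sites_released = list(p = c(p0, 1 - p0), omega = c(omega0, 1)))
  mo <- codon_model(kappa = model$kappa, codon_freqs = model$codon_freqs,
                    site_classes = classes)
  fg_child <- integer(0)
  if (regime == "branch_sites_released") {
    if (is.null(foreground)) stop("foreground branch required for this regime")
    fg_child <- if (is.character(foreground)) branch_by_leafset(tree, foreground)
      else as.integer(foreground)
  }
  site_class <- sample.int(length(classes$p), n_codons, replace = TRUE,
                           prob = classes$p)
  eigs <- lapply(seq_along(classes$p), function(ci)
    .q_eigen(build_rate_matrix(mo, class = ci)))
  # foreground releases all sites: neutral generator, same mixture scaling
  eig_fg <- if (length(fg_child)) {
    Qn <- .codon_q_raw(mo$kappa, 1, mo$codon_freqs) / attr(
      build_rate_matrix(mo, class = 1), "scale")
    attr(Qn, "freq") <- mo$codon_freqs
    .q_eigen(Qn)
  } else NULL
  prep <- .prep_tree(tree)
  ntip <- length(tree$tip.label)
  states <- matrix(NA_integer_, ntip + tree$Nnode, n_codons)
  for (ci in seq_along(classes$p)) {
    sel <- which(site_class == ci)
    if (!length(sel)) next
    sub <- .evolve_states(tree, 61L, mo$codon_freqs, length(sel),
                          function(k) {
                            if (prep$edge[k, 2] %in% fg_child) eig_fg
                            else eigs[[ci]]
                          },
                          rep(1, length(sel)))
    states[, sel] <- sub
  }
  cods <- sense_codons()
  m <- matrix(cods[states[seq_len(ntip), ]], ntip, n_codons,
              dimnames = list(tree$tip.label, NULL))
  list(codons = m, site_class = site_class, tree = tree, regime = regime)
}

#' Specification for a synthetic binding-kinetics experiment
#'
#' Defaults emulate a biolayer-interferometry assay at 7 log-spaced analyte
#' concentrations with 3 replicates under 1:1 Langmuir binding.
#'
#' @param Kd_true equilibrium dissociation constant (molar).
#' @param kon association rate constant (1/(M s)); `koff = kon * Kd_true`.
#' @param Rmax maximal response (nm).
#' @param concentrations analyte concentrations (molar, sorted).
#' @param noise_sd Gaussian noise sd (nm).
#' @param drift linear baseline drift during association (nm/s).
#' @param n_replicates number of replicates.
#' @param sample_interval sampling interval (s).
#' @param duration duration of each phase (s).
#' @param seed RNG seed.
#' @return object of class `kinetics_sim_spec`.
#' @export
kinetics_sim_spec <- function(Kd_true = 3e-8, kon = 1e5, Rmax = 1,
                              concentrations = 10^seq(-9, -4, length.out = 7),
                              noise_sd = 0.01, drift = 0, n_replicates = 3,
                              sample_interval = 1, duration = 1800, seed = 1) {
  concentrations <- sort(concentrations)
  stopifnot(all(concentrations > 0), Kd_true > 0, kon > 0, Rmax > 0,
            noise_sd >= 0, n_replicates >= 1)
  structure(list(Kd_true = Kd_true, kon = kon, koff = kon * Kd_true,
                 Rmax = Rmax, concentrations = concentrations,
                 noise_sd = noise_sd, drift = drift,
                 n_replicates = n_replicates,
                 sample_interval = sample_interval, duration = duration,
                 seed = seed),
            class = "kinetics_sim_spec")
}

#' Simulate association-dissociation traces
#'
#' Association follows `R(t) = Rmax C/(C+Kd) (1 - exp(-(kon C + koff) t)) +
#' drift t + e`; dissociation decays from the deterministic association end
#' value as `R_end exp(-koff t) + e`, with `e ~ N(0, noise_sd^2)`.  A blank
#' trace at concentration 0 (drift plus noise during association, noise only
#' during dissociation) is included.
#'
#' @param spec a [kinetics_sim_spec()].
#' @return trace data.frame in the [read_traces()] layout.
#' @export
simulate_kinetics <- function(spec) {
  stopifnot(inherits(spec, "kinetics_sim_spec"))
  set.seed(spec$seed)
  tt <- seq(spec$sample_interval, spec$duration, by = spec$sample_interval)
  rows <- list()
  for (rep_i in seq_len(spec$n_replicates)) {
    for (C in c(0, spec$concentrations)) {
      if (C > 0) {
        kobs <- spec$kon * C + spec$koff
        req <- spec$Rmax * C / (C + spec$Kd_true)
        assoc <- req * (1 - exp(-kobs * tt)) + spec$drift * tt
        r_end <- req * (1 - exp(-kobs * spec$duration))
        dissoc <- r_end * exp(-spec$koff * tt)
      } else {
        assoc <- spec$drift * tt
        dissoc <- rep(0, length(tt))
      }
      assoc <- assoc + stats::rnorm(length(tt), 0, spec$noise_sd)
      dissoc <- dissoc + stats::rnorm(length(tt), 0, spec$noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        time = c(tt, tt),
        signal = c(assoc, dissoc),
        concentration_M = C,
        replicate = rep_i,
        phase = rep(c("association", "dissociation"), each = length(tt)))
    }
  }
  validate_traces(do.call(rbind, rows))
}

#' Synthetic five-group domain-family fixture
#'
#' A stand-in for a small family of ~95-residue interaction domains: five
#' subfamily groups of `taxa_per_group` taxa on one shared tree (within-group
#' depth `within_depth`, group stems `stem` substitutions/site), evolved
#' under LG+Gamma.  Used as the demonstration dataset for every
#' sequence-based stage.
#'
#' @param seed RNG seed.
#' @param n_groups number of subfamily groups.
#' @param taxa_per_group taxa per group.
#' @param n_sites alignment columns.
#' @param within_depth root-to-tip depth inside each group.
#' @param stem stem branch length leading to each group.
#' @param alpha gamma shape of the generating model.
#' @param ncat gamma categories.
#' @return list with `tree`, `alignment`, `ancestors`, `groups` (named
#'   vector taxon -> group), `model`.
#' @export
card_family_fixture <- function(seed = 1, n_groups = 5, taxa_per_group = 10,
                                n_sites = 95, within_depth = 0.5, stem = 0.8,
                                alpha = 0.8, ncat = 4) {
  set.seed(seed)
  subtrees <- lapply(seq_len(n_groups), function(g) {
    tr <- ape::rcoal(taxa_per_group,
                     tip.label = sprintf("g%d_t%02d", g, seq_len(taxa_per_group)))
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * within_depth / depth
    tr
  })
  # caterpillar backbone with one stem per group
  txt <- paste0("G", n_groups, ":", stem)
  for (g in rev(seq_len(n_groups - 1)))
    txt <- sprintf("(G%d:%g,%s):%g", g, stem, txt, if (g > 1) 0.1 else 0)
  backbone <- ape::read.tree(text = paste0(txt, ";"))
  tree <- backbone
  for (g in seq_len(n_groups))
    tree <- ape::bind.tree(tree, subtrees[[g]], where = which(tree$tip.label == paste0("G", g)))
  model <- protein_model(alpha = alpha, ncat = ncat)
  sim <- simulate_protein_alignment(tree, model, n_sites, seed = seed + 1)
  groups <- sub("_.*$", "", rownames(sim$alignment))
  names(groups) <- rownames(sim$alignment)
  list(tree = tree, alignment = sim$alignment, ancestors = sim$ancestors,
       groups = groups, model = model)
}

#' Delete a contiguous block in one clade of an alignment
#'
#' Introduces a synthetic deletion (gap block) into every sequence of a
#' clade, to exercise indel parsimony on simulated data.
#'
#' @param alignment character matrix (taxa x sites).
#' @param taxa taxa carrying the deletion.
#' @param start first deleted column (1-based).
#' @param width number of deleted columns.
#' @return the masked alignment matrix.
#' @export
mask_indel_block <- function(alignment, taxa, start, width) {
  stopifnot(all(taxa %in% rownames(alignment)),
            start >= 1, start + width - 1 <= ncol(alignment))
  alignment[taxa, start:(start + width - 1)] <- "-"
  alignment
}
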