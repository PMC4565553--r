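# Simulation-based calibration experiments: ancestral-reconstruction error
# rates under the fitted model, and false-positive rates of the branch-site
# test under neutral / sites / branch-site-released generating regimes.

#' Ancestral-reconstruction error experiment
#'
#' Per replicate: simulate a protein alignment along the tree (true
#' ancestral states recorded), reconstruct ancestors by marginal
#' reconstruction with the generating model (no re-estimation), and score
#' per-node strict errors (MAP != truth) and biochemical-class errors
#' (class(MAP) != class(truth)).
#'
#' @param tree rooted `phylo`.
#' @param model fitted `protein_model` used both to simulate and reconstruct.
#' @param n_sites alignment columns per replicate.
#' @param n_reps replicates.
#' @param classes biochemical classes.
#' @param seed base RNG seed (replicate r uses `seed + r`).
#' @return list with `per_node` (data.frame: node, mean/SE strict and class
#'   error, mean MAP posterior), `replicates` (per-replicate per-node
#'   matrix), and `calibration` (pooled mean MAP posterior vs accuracy).
#' @export
asr_error_experiment <- function(tree, model, n_sites, n_reps = 10,
                                 classes = biochemical_classes(), seed = 1) {
  lk <- .class_lookup(classes)
  keys <- NULL
  strict <- class_err <- map_mean <- NULL
  post_sum <- 0; acc_sum <- 0; n_tot <- 0
  for (r in seq_len(n_reps)) {
    sim <- simulate_protein_alignment(tree, model, n_sites, seed = seed + r)
    rec <- marginal_reconstruct(sim$alignment, tree, model)
    if (is.null(keys)) {
      keys <- rownames(sim$ancestors)
      strict <- class_err <- map_mean <- matrix(NA_real_, n_reps, length(keys),
                                                dimnames = list(NULL, keys))
    }
    for (key in keys) {
      truth <- sim$ancestors[key, ]
      map <- rec$nodes[[key]]$map
      strict[r, key] <- mean(map != truth)
      class_err[r, key] <- mean(lk[map] != lk[truth])
      map_mean[r, key] <- mean(rec$nodes[[key]]$map_p)
      post_sum <- post_sum + sum(rec$nodes[[key]]$map_p)
      acc_sum <- acc_sum + sum(map == truth)
      n_tot <- n_tot + length(map)
    }
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  per_node <- data.frame(
    node = keys,
    strict_error = colMeans(strict), strict_se = apply(strict, 2, se),
    class_error = colMeans(class_err), class_se = apply(class_err, 2, se),
    mean_map_posterior = colMeans(map_mean), row.names = NULL)
  list(per_node = per_node,
       replicates = list(strict = strict, class = class_err),
       calibration = data.frame(mean_map_posterior = post_sum / n_tot,
                                empirical_accuracy = acc_sum / n_tot,
                                n_residues = n_tot))
}

#' Branch-site false-positive-rate experiment
#'
#' Per replicate: simulate a codon alignment under the chosen regime (none
#' of which contains positive selection), run the branch-site LRT on each
#' tested branch with Bonferroni correction over those branches, and count
#' the fraction of (replicate x branch) tests declared significant.
#'
#' @param tree rooted `phylo` (branch lengths in expected substitutions per
#'   codon under the regime mixture).
#' @param base_model `codon_model` carrying kappa and codon frequencies for
#'   simulation.
#' @param regime `"neutral"`, `"sites"` or `"branch_sites_released"`.
#' @param n_reps replicates (the study-scale default is 100; desk-scale runs
#'   use fewer).
#' @param alpha family-wise significance level after Bonferroni.
#' @param tested_branches list of foreground branches (leaf sets or child
#'   ids); all are tested in every replicate.
#' @param n_codons codon sites per replicate.
#' @param p0,omega0 sites-regime parameters (defaults 0.8 / 0.1, used when
#'   no empirically fitted values are supplied).
#' @param seed base RNG seed.
#' @return list with `fpr` (pooled over replicate x branch), `per_replicate`
#'   (fraction significant per replicate), `mean`, `se`, `alpha`,
#'   `n_reps`, `tested_branches`, and the raw p-value matrix.
#' @export
branch_site_fpr_experiment <- function(tree, base_model,
                                       regime = c("neutral", "sites",
                                                  "branch_sites_released"),
                                       n_reps = 100, alpha = 0.05,
                                       tested_branches, n_codons = 90,
                                       p0 = 0.8, omega0 = 0.1, seed = 1) {
  regime <- match.arg(regime)
  if (!length(tested_branches)) stop("zero tested branches")
  m <- length(tested_branches)
  fg_children <- vapply(tested_branches, function(b)
    if (is.character(b)) branch_by_leafset(tree, b) else as.integer(b),
    integer(1))
  p_raw <- p_adj <- matrix(NA_real_, n_reps, m)
  for (r in seq_len(n_reps)) {
    fg_sim <- if (regime == "branch_sites_released") fg_children[1] else NULL
    sim <- simulate_codon_alignment(tree, base_model, n_codons, regime,
                                    foreground = fg_sim, p0 = p0,
                                    omega0 = omega0, seed = seed + r)
    prep <- .prep_tree(tree)
    tip_idx <- .tip_indices(sim$codons, "codon")[tree$tip.label, , drop = FALSE]
    pi <- empirical_codon_freqs_f3x4(sim$codons)
    kappa <- .estimate_kappa(prep, tip_idx, pi)
    for (bi in seq_len(m)) {
      res <- branch_sites_lrt(sim$codons, tree, fg_children[bi], m_tests = m,
                              codon_freqs = pi, kappa = kappa)
      p_raw[r, bi] <- res$p_raw
      p_adj[r, bi] <- res$p_bonferroni
    }
  }
  sig <- p_adj < alpha
  per_rep <- rowMeans(sig)
  list(fpr = mean(sig), per_replicate = per_rep,
       mean = mean(per_rep), se = stats::sd(per_rep) / sqrt(n_reps),
       alpha = alpha, n_reps = n_reps, regime = regime,
       tested_branches = tested_branches,
       p_raw = p_raw, p_bonferroni = p_adj)
}
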