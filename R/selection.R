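# Branch-site test of positive selection (codon Model A vs its null) and a
# GENECONV-style permutation screen for gene conversion.
#
# Model A mixes four site classes on a foreground branch b:
#   class 0:  omega0 (<1) on all branches          weight p0
#   class 1:  omega = 1 on all branches            weight p1
#   class 2a: omega0 background, omega2 on b       weight p2 * p0/(p0+p1)
#   class 2b: 1 background, omega2 on b            weight p2 * p1/(p0+p1)
# The null fixes omega2 = 1.  The likelihood is maximised by coordinate
# ascent over (omega0, omega2) with the class proportions profiled out at
# every omega evaluation; kappa is estimated once per alignment under a
# single-class model and then held fixed (see the methods vignette).

# generator scaled to expected substitutions per codon under neutrality
.scaled_codon_q <- function(kappa, omega, pi, mu1) {
  Q <- .codon_q_raw(kappa, omega, pi) / mu1
  attr(Q, "freq") <- pi
  Q
}

.neutral_rate <- function(kappa, pi) -sum(pi * diag(.codon_q_raw(kappa, 1, pi)))

# class site log-likelihood matrix (4 x sites) for Model A at given params;
# per-edge P matrices are shared between the background classes and patched
# on the foreground edge only, which dominates the fit's cost profile
.model_a_class_ll <- function(prep, tip_idx, pi, kappa, w0, w2, fg_child, mu1,
                              P1 = NULL) {
  fg_k <- which(prep$edge[, 2] %in% fg_child)
  eig0 <- .q_eigen(.scaled_codon_q(kappa, w0, pi, mu1))
  P0 <- .build_P_list(prep, eig0)
  if (is.null(P1))
    P1 <- .build_P_list(prep, .q_eigen(.scaled_codon_q(kappa, 1, pi, mu1)))
  P2fg <- if (w2 == 1) P1[fg_k] else {
    eig2 <- .q_eigen(.scaled_codon_q(kappa, w2, pi, mu1))
    lapply(fg_k, function(k) if (prep$elen[k] <= 0) diag(61L)
           else .p_matrix(eig2, prep$elen[k]))
  }
  P2a <- P0; P2a[fg_k] <- P2fg
  P2b <- P1; P2b[fg_k] <- P2fg
  rbind(.site_ll_P(prep, tip_idx, 61L, P0, pi),
        .site_ll_P(prep, tip_idx, 61L, P1, pi),
        .site_ll_P(prep, tip_idx, 61L, P2a, pi),
        .site_ll_P(prep, tip_idx, 61L, P2b, pi))
}

# profile the Model A proportions: maximise the mixture lnL over (p0, p1).
# The per-class site likelihoods are fixed here, so shift/exponentiate once
# and optimise over the (cheap) mixture weights only.
.profile_proportions <- function(class_ll, p_init) {
  m <- .colmax(class_ll)
  E <- exp(sweep(class_ll, 2, m))   # 4 x sites, safe scale
  mix <- function(p) {
    q <- p[1] + p[2]
    w <- c(p[1], p[2], (1 - q) * p[1] / q, (1 - q) * p[2] / q)
    sum(m + log(colSums(E * w)))
  }
  xf <- log(pmax(p_init[1:2], 1e-6) / pmax(1 - sum(p_init[1:2]), 1e-6))
  op <- stats::optim(xf, function(x) {
    e <- exp(c(x, 0)); pp <- e / sum(e)
    -mix(pp[1:2])
  }, method = "Nelder-Mead", control = list(maxit = 200, reltol = 1e-9))
  e <- exp(c(op$par, 0)); pp <- e / sum(e)
  list(p = pp[1:2], lnL = -op$value)
}

# Fit Model A (alternative) or its null on a fixed topology.  Background
# branch lengths stay at their input values, but the foreground branch
# length is re-estimated under each model: it is partially confounded with
# omega2, and holding it fixed would let realised substitution-count noise
# on that one branch masquerade as positive selection.  The omega = 1 class
# machinery is cached; an omega0 move recomputes class rows 0/2a, an omega2
# move rows 2a/2b, a foreground-length move all four rows (foreground-edge
# transition matrices only); class proportions are profiled out at every
# evaluation.
.fit_model_a <- function(prep, tip_idx, pi, fg_child, kappa, null = FALSE,
                         init = NULL, brent_tol = 2e-3, max_sweeps = 6,
                         tol = 1e-3) {
  mu1 <- .neutral_rate(kappa, pi)
  fg_k <- which(prep$edge[, 2] %in% fg_child)
  w0 <- init$w0 %||% 0.5
  w2 <- if (null) 1 else max(init$w2 %||% 1.5, 1)
  p <- init$p %||% c(0.5, 0.4)
  t_fg <- init$t_fg %||% prep$elen[fg_k[1]]

  eig1 <- .q_eigen(.scaled_codon_q(kappa, 1, pi, mu1))
  P1_base <- .build_P_list(prep, eig1)
  eig_cache <- new.env(parent = emptyenv())
  eig_of <- function(w) {
    key <- sprintf("e%.12g", w)
    if (is.null(eig_cache[[key]]))
      eig_cache[[key]] <- .q_eigen(.scaled_codon_q(kappa, w, pi, mu1))
    eig_cache[[key]]
  }
  pbase_of <- function(w) {
    # background P list for one omega, cached (rebuilt only when omega moves)
    key <- sprintf("p%.12g", w)
    if (is.null(eig_cache[[key]]))
      eig_cache[[key]] <- .build_P_list(prep, eig_of(w))
    eig_cache[[key]]
  }
  fg_P <- function(eig, t) replicate(length(fg_k), {
    if (t <= 0) diag(61L) else .p_matrix(eig, t)
  }, simplify = FALSE)

  rows_for <- function(w0_, w2_, t_) {
    eig0 <- eig_of(w0_)
    P0 <- pbase_of(w0_)
    P0[fg_k] <- fg_P(eig0, t_)
    P1 <- P1_base
    P1[fg_k] <- fg_P(eig1, t_)
    P2fg <- if (w2_ == 1) P1[fg_k] else fg_P(eig_of(w2_), t_)
    P2a <- P0; P2a[fg_k] <- P2fg
    P2b <- P1; P2b[fg_k] <- P2fg
    rbind(.site_ll_P(prep, tip_idx, 61L, P0, pi),
          .site_ll_P(prep, tip_idx, 61L, P1, pi),
          .site_ll_P(prep, tip_idx, 61L, P2a, pi),
          .site_ll_P(prep, tip_idx, 61L, P2b, pi))
  }
  eval_at <- function(w0_, w2_, t_) {
    cl <- rows_for(w0_, w2_, t_)
    pr <- .profile_proportions(cl, p)
    list(class_ll = cl, p = pr$p, lnL = pr$lnL)
  }
  cur <- eval_at(w0, w2, t_fg)
  p <- cur$p
  for (sweep in seq_len(max_sweeps)) {
    prev_lnL <- cur$lnL
    op <- stats::optimize(function(x) eval_at(x, w2, t_fg)$lnL,
                          interval = .OPT_BOUNDS$omega0, maximum = TRUE,
                          tol = brent_tol)
    if (op$objective > cur$lnL) {
      w0 <- op$maximum; cur <- eval_at(w0, w2, t_fg); p <- cur$p
    }
    if (!null) {
      op <- stats::optimize(function(x) eval_at(w0, x, t_fg)$lnL,
                            interval = .OPT_BOUNDS$omega2, maximum = TRUE,
                            tol = brent_tol)
      if (op$objective > cur$lnL) {
        w2 <- op$maximum; cur <- eval_at(w0, w2, t_fg); p <- cur$p
      }
    }
    op <- stats::optimize(function(x) eval_at(w0, w2, x)$lnL,
                          interval = c(1e-8, max(1, 10 * t_fg)),
                          maximum = TRUE, tol = brent_tol * max(t_fg, 0.1))
    if (op$objective > cur$lnL) {
      t_fg <- op$maximum; cur <- eval_at(w0, w2, t_fg); p <- cur$p
    }
    if (cur$lnL - prev_lnL < tol) break
  }
  q <- p[1] + p[2]
  list(lnL = cur$lnL, omega0 = w0, omega2 = w2, kappa = kappa,
       p0 = p[1], p1 = p[2], p2 = 1 - q, t_fg = t_fg)
}

# single-class (M0-like) kappa estimate with omega free, used as the shared
# kappa for all branch-site fits on one alignment
.estimate_kappa <- function(prep, tip_idx, pi, brent_tol = 5e-3) {
  fit1 <- function(kappa) {
    mu1 <- .neutral_rate(kappa, pi)
    op <- stats::optimize(function(w) {
      eig <- .q_eigen(.scaled_codon_q(kappa, w, pi, mu1))
      cl <- list(list(eig = eig, eig_fg = NULL, fg_child = integer(0),
                      rate = 1, freq = pi))
      sum(.class_site_loglik(prep, tip_idx, 61L, cl)$class_ll)
    }, interval = c(1e-3, 5), maximum = TRUE, tol = 0.01)
    op$objective
  }
  op <- stats::optimize(fit1, interval = c(0.5, 10), maximum = TRUE,
                        tol = brent_tol * 20)
  op$maximum
}

#' Branch-site likelihood-ratio test of positive selection
#'
#' Fits branch-site Model A and its null (foreground omega2 fixed at 1) on a
#' fixed tree, compares twice the log-likelihood difference to a chi-square
#' with 1 df, and applies a Bonferroni correction over `m_tests` tested
#' branches.
#'
#' @param codon_alignment codon matrix ([codon_matrix()]) or FASTA records
#'   of in-frame DNA.
#' @param tree `phylo` with branch lengths (expected substitutions per codon
#'   under neutrality); held fixed during fitting.
#' @param foreground_branch the foreground branch: child-node id or leaf-set
#'   character vector.
#' @param m_tests number of branches tested in the family (Bonferroni m).
#' @param codon_freqs stationary codon frequencies; default empirical F3x4
#'   from the alignment.
#' @param kappa transition/transversion ratio; `NULL` (default) estimates it
#'   once under a single-class model and holds it fixed for both fits.
#' @param boundary_mixture if TRUE, p-values use the 50:50 mixture of 0 and
#'   chi-square(1) appropriate for the boundary null (default FALSE: plain
#'   chi-square df = 1).
#' @return list of class `lrt_result`: branch key, `lnL_alt`, `lnL_null`,
#'   `statistic`, `df`, `p_raw`, `p_bonferroni`, and the alternative-model
#'   estimates (`p0`, `p1`, `p2`, `omega0`, `omega2`, `kappa`).
#' @export
branch_sites_lrt <- function(codon_alignment, tree, foreground_branch,
                             m_tests = 1, codon_freqs = NULL, kappa = NULL,
                             boundary_mixture = FALSE) {
  aln <- if (is.data.frame(codon_alignment)) codon_matrix(codon_alignment)
    else codon_alignment
  if (!setequal(rownames(aln), tree$tip.label))
    stop("alignment taxa do not match tree tips")
  fg_child <- if (is.character(foreground_branch))
    branch_by_leafset(tree, foreground_branch) else as.integer(foreground_branch)
  if (is.null(codon_freqs)) codon_freqs <- empirical_codon_freqs_f3x4(aln)
  tip_idx <- .tip_indices(aln, "codon")[tree$tip.label, , drop = FALSE]
  prep <- .prep_tree(tree)
  if (!fg_child %in% prep$edge[, 2]) stop("foreground branch absent from tree")
  if (is.null(kappa)) kappa <- .estimate_kappa(prep, tip_idx, codon_freqs)
  # fit the alternative first, then the null from the alternative's optimum:
  # starting both fits from one optimum keeps optimisation noise out of the
  # statistic (if the null still lands above the alternative, the models are
  # equivalent at the optimum and the statistic is zero)
  fit1 <- .fit_model_a(prep, tip_idx, codon_freqs, fg_child, kappa,
                       null = FALSE)
  fit0 <- .fit_model_a(prep, tip_idx, codon_freqs, fg_child, kappa,
                       null = TRUE,
                       init = list(w0 = fit1$omega0,
                                   p = c(fit1$p0, fit1$p1),
                                   t_fg = fit1$t_fg))
  if (fit0$lnL > fit1$lnL) {
    fit1 <- fit0
    fit1$omega2 <- 1
  }
  stat <- 2 * (fit1$lnL - fit0$lnL)
  stat <- max(stat, 0)
  p_raw <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary_mixture) p_raw <- p_raw / 2
  keys <- node_leafset_keys(tree)
  structure(list(branch = keys[fg_child], lnL_alt = fit1$lnL,
                 lnL_null = fit0$lnL, statistic = stat, df = 1,
                 p_raw = p_raw, p_bonferroni = min(1, m_tests * p_raw),
                 p0 = fit1$p0, p1 = fit1$p1, p2 = fit1$p2,
                 omega0 = fit1$omega0, omega2 = fit1$omega2,
                 kappa = kappa),
            class = "lrt_result")
}

#' Bonferroni adjustment
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m number of tests (default `length(p_values)`).
#' @return adjusted p-values `min(1, m p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

# maximal-scoring segment (match = +1, mismatch = -penalty) of a logical
# vector; returns score and the first/last index of the best segment
.max_fragment <- function(match, penalty = 1) {
  x <- ifelse(match, 1, -penalty)
  n <- length(x)
  S <- cumsum(x)
  Smin_prev <- cummin(c(0, S[-n]))
  gains <- S - Smin_prev
  best <- max(gains)
  if (best <= 0) return(list(score = 0, begin = NA, end = NA))
  end <- which.max(gains)
  start_base <- which(c(0, S[-n]) == Smin_prev[end])
  begin <- max(start_base[start_base <= end])
  list(score = best, begin = begin, end = end)
}

# vectorised best-segment score only (for permutation replicates)
.max_fragment_score <- function(x) {
  S <- cumsum(x)
  max(0, max(S - cummin(c(0, S[-length(S)]))))
}

#' Permutation screen for gene conversion
#'
#' Restricting the alignment to polymorphic columns (no gaps, at least two
#' states), each unordered sequence pair is scanned for its maximal-scoring
#' fragment of agreement (match +1, mismatch penalty `g`, interruptions
#' allowed).  Significance is assessed by permuting the polymorphic-column
#' order: `sim_p = (1 + #{permutation max score >= observed}) / (n_perm +
#' 1)`, Bonferroni-corrected over pairs.
#'
#' @param dna_alignment character matrix of aligned DNA (or FASTA records).
#' @param n_perm number of column-order permutations.
#' @param seed RNG seed.
#' @param g mismatch penalty inside a fragment.
#' @return data.frame with one row per pair that has a positive-score
#'   fragment: `seq1`, `seq2`, `sim_p`, `p_bonferroni`, `begin`, `end`
#'   (1-based alignment coordinates), `poly`, `len`, `diff`, `total_diff`,
#'   `score`.
#' @export
gene_conversion_scan <- function(dna_alignment, n_perm = 10000, seed = 1, g = 1) {
  m <- if (is.data.frame(dna_alignment)) alignment_matrix(dna_alignment)
    else dna_alignment
  if (nrow(m) < 3) stop("need at least 3 aligned sequences")
  m <- toupper(m)
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  poly <- ok & apply(m, 2, function(col) length(unique(col)) > 1)
  cols <- which(poly)
  if (length(cols) < 2) {
    warning("fewer than 2 polymorphic columns; empty result")
    return(data.frame(seq1 = character(), seq2 = character(), sim_p = numeric(),
                      p_bonferroni = numeric(), begin = integer(), end = integer(),
                      poly = integer(), len = integer(), diff = integer(),
                      total_diff = integer(), score = numeric()))
  }
  ids <- rownames(m)
  pairs <- utils::combn(seq_len(nrow(m)), 2)
  match_mat <- apply(pairs, 2, function(ij) m[ij[1], cols] == m[ij[2], cols])
  match_mat <- matrix(match_mat, nrow = length(cols))
  obs <- lapply(seq_len(ncol(pairs)), function(k)
    .max_fragment(match_mat[, k], penalty = g))
  set.seed(seed)
  n_ge <- numeric(ncol(pairs))
  xs <- ifelse(match_mat, 1, -g)
  for (b in seq_len(n_perm)) {
    ord <- sample.int(length(cols))
    for (k in seq_len(ncol(pairs)))
      if (.max_fragment_score(xs[ord, k]) >= obs[[k]]$score)
        n_ge[k] <- n_ge[k] + 1
  }
  sim_p <- (1 + n_ge) / (n_perm + 1)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    o <- obs[[k]]
    if (o$score <= 0) return(NULL)
    b_col <- cols[o$begin]; e_col <- cols[o$end]
    frag <- m[pairs[1, k], cols[o$begin:o$end]] != m[pairs[2, k], cols[o$begin:o$end]]
    data.frame(seq1 = ids[pairs[1, k]], seq2 = ids[pairs[2, k]],
               sim_p = sim_p[k], p_bonferroni = min(1, ncol(pairs) * sim_p[k]),
               begin = b_col, end = e_col,
               poly = o$end - o$begin + 1L, len = e_col - b_col + 1L,
               diff = sum(frag), total_diff = sum(!match_mat[, k]),
               score = o$score)
  })
  out <- do.call(rbind, rows)
  out[order(out$sim_p, -out$score), , drop = FALSE]
}
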