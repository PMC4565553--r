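# Coordinate-ascent fitting of model parameters and branch lengths on a
# fixed topology: Brent line searches per parameter, sweeps repeated until
# the log-likelihood gain falls below tolerance.  The log-likelihood
# trajectory is non-decreasing by construction (a proposed update is only
# accepted if it improves the current value).

.OPT_BOUNDS <- list(branch = c(1e-8, 50), alpha = c(0.05, 20),
                    kappa = c(0.01, 30), omega0 = c(1e-4, 1),
                    omega2 = c(1, 50))

#' Fit model parameters and branch lengths on a fixed topology
#'
#' @param alignment alignment matrix or FASTA records.
#' @param tree `phylo` with starting branch lengths.
#' @param model starting `protein_model` or `codon_model`.
#' @param free character vector naming the free parameters, a subset of
#'   `"branch_lengths"`, `"alpha"` (protein), `"kappa"`, `"omegas"`,
#'   `"proportions"` (codon).  Empty means: evaluate only.
#' @param control list: `tol` (lnL convergence, default 1e-6), `max_sweeps`
#'   (default 200), `brent_tol` (default 1e-4).
#' @return list with `model`, `tree`, `lnL` and the per-sweep `trajectory`.
#' @export
optimize_model <- function(alignment, tree, model,
                           free = c("branch_lengths", "alpha"),
                           control = list()) {
  tol <- control$tol %||% 1e-6
  max_sweeps <- control$max_sweeps %||% 200L
  btol <- control$brent_tol %||% 1e-4
  aln <- .aln_for_model(alignment, model)

  eval_ll <- function(tr, mo) log_likelihood(aln, tr, mo)$total
  cur <- eval_ll(tree, model)
  if (!is.finite(cur))
    stop("non-finite log-likelihood at initial parameters (lnL = ", cur, ")")
  if (!length(free))
    return(list(model = model, tree = tree, lnL = cur, trajectory = cur))

  brent_update <- function(f, bounds, x0) {
    # maximise f over [bounds]; keep x0 unless improvement found
    opt <- stats::optimize(f, interval = bounds, maximum = TRUE, tol = btol)
    if (opt$objective > cur) list(x = opt$maximum, val = opt$objective)
    else list(x = x0, val = cur)
  }

  traj <- cur
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    if ("branch_lengths" %in% free) {
      for (k in seq_along(tree$edge.length)) {
        up <- brent_update(function(x) {
          tr2 <- tree; tr2$edge.length[k] <- x; eval_ll(tr2, model)
        }, .OPT_BOUNDS$branch, tree$edge.length[k])
        tree$edge.length[k] <- up$x; cur <- up$val
      }
    }
    if ("alpha" %in% free && inherits(model, "protein_model")) {
      up <- brent_update(function(x) {
        mo2 <- model; mo2$alpha <- x; eval_ll(tree, mo2)
      }, .OPT_BOUNDS$alpha, model$alpha)
      model$alpha <- up$x; cur <- up$val
    }
    if ("kappa" %in% free && inherits(model, "codon_model")) {
      up <- brent_update(function(x) {
        mo2 <- model; mo2$kappa <- x; eval_ll(tree, mo2)
      }, .OPT_BOUNDS$kappa, model$kappa)
      model$kappa <- up$x; cur <- up$val
    }
    if ("omegas" %in% free && inherits(model, "codon_model")) {
      for (ci in seq_along(model$site_classes$omega)) {
        bounds <- if (model$site_classes$omega[ci] > 1) .OPT_BOUNDS$omega2
          else .OPT_BOUNDS$omega0
        up <- brent_update(function(x) {
          mo2 <- model; mo2$site_classes$omega[ci] <- x; eval_ll(tree, mo2)
        }, bounds, model$site_classes$omega[ci])
        model$site_classes$omega[ci] <- up$x; cur <- up$val
      }
      if (!is.null(model$omega2) && !is.null(model$foreground)) {
        up <- brent_update(function(x) {
          mo2 <- model; mo2$omega2 <- x; eval_ll(tree, mo2)
        }, .OPT_BOUNDS$omega2, model$omega2)
        model$omega2 <- up$x; cur <- up$val
      }
    }
    if ("proportions" %in% free && inherits(model, "codon_model") &&
        length(model$site_classes$p) > 1) {
      p <- model$site_classes$p
      xf <- log(pmax(p[-length(p)], 1e-8) / pmax(p[length(p)], 1e-8))
      obj <- function(x) {
        e <- exp(c(x, 0)); pp <- e / sum(e)
        mo2 <- model; mo2$site_classes$p <- pp
        -eval_ll(tree, mo2)
      }
      op <- stats::optim(xf, obj, method = "Nelder-Mead",
                         control = list(maxit = 200))
      if (-op$value > cur) {
        e <- exp(c(op$par, 0))
        model$site_classes$p <- e / sum(e)
        cur <- -op$value
      }
    }
    traj <- c(traj, cur)
    if (cur - prev < tol) break
  }
  list(model = model, tree = tree, lnL = cur, trajectory = traj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
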