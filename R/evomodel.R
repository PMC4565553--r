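# Substitution-model machinery: LG(+F)+Gamma for proteins and a
# Goldman-Yang-style codon model family (sites models, branch-site Model A
# and its null).

#' Construct an LG(+F)+Gamma protein model
#'
#' @param frequencies stationary residue frequencies (20-vector, sums to 1);
#'   default the LG frequencies.  Use [empirical_frequencies()] for "+F".
#' @param alpha gamma shape for among-site rate variation (> 0).
#' @param ncat number of discrete gamma categories (default 8).
#' @param exchangeabilities symmetric 20x20 exchangeability matrix.
#' @return object of class `protein_model`.
#' @export
protein_model <- function(frequencies = lg_frequencies(), alpha = 1, ncat = 8,
                          exchangeabilities = lg_exchangeabilities()) {
  stopifnot(alpha > 0, ncat >= 1)
  frequencies <- frequencies / sum(frequencies)
  if (abs(sum(frequencies) - 1) > 1e-12) stop("frequencies must sum to 1")
  structure(list(exchangeabilities = exchangeabilities,
                 frequencies = frequencies, alpha = alpha, ncat = as.integer(ncat)),
            class = "protein_model")
}

#' Empirical residue frequencies from an alignment (+F)
#'
#' Counts residues over the alignment with a pseudocount of 1 per residue;
#' gaps and `X` are ignored.
#'
#' @param aln character matrix from [alignment_matrix()].
#' @return named 20-vector summing to 1.
#' @export
empirical_frequencies <- function(aln) {
  counts <- table(factor(aln[aln %in% AA_ALPHABET], levels = AA_ALPHABET))
  f <- (as.numeric(counts) + 1) / (sum(counts) + 20)
  names(f) <- AA_ALPHABET
  f
}

#' Construct a codon model
#'
#' Site classes are given as proportions `p` and ratios `omega`; a
#' branch-site model additionally names a foreground branch and a foreground
#' ratio `omega2` applying there (Model A semantics are assembled by
#' [branch_sites_lrt()]).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param codon_freqs stationary codon frequencies (61-vector); default F3x4
#'   from uniform nucleotide frequencies.
#' @param site_classes list with numeric vectors `p` (proportions, sum 1) and
#'   `omega` (nonnegative, same length).
#' @param foreground optional foreground branch (child-node id or leaf set).
#' @param omega2 optional foreground omega (>= 1 in the alternative model).
#' @return object of class `codon_model`.
#' @export
codon_model <- function(kappa = 2, codon_freqs = codon_freqs_f3x4(),
                        site_classes = list(p = 1, omega = 1),
                        foreground = NULL, omega2 = NULL) {
  stopifnot(kappa > 0, length(codon_freqs) == 61,
            length(site_classes$p) == length(site_classes$omega),
            all(site_classes$omega >= 0))
  if (abs(sum(site_classes$p) - 1) > 1e-9) stop("class proportions must sum to 1")
  codon_freqs <- codon_freqs / sum(codon_freqs)
  structure(list(kappa = kappa, codon_freqs = codon_freqs,
                 site_classes = site_classes, foreground = foreground,
                 omega2 = omega2),
            class = "codon_model")
}

#' F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies multiplied across the three codon
#' positions, restricted to sense codons and renormalised.
#'
#' @param nuc_freqs 4x3 matrix of nucleotide frequencies (rows TCAG order
#'   irrelevant as long as rownames are A,C,G,T) or NULL for uniform.
#' @return named 61-vector summing to 1.
#' @export
codon_freqs_f3x4 <- function(nuc_freqs = NULL) {
  if (is.null(nuc_freqs)) {
    nuc_freqs <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  }
  stopifnot(nrow(nuc_freqs) == 4, ncol(nuc_freqs) == 3,
            !is.null(rownames(nuc_freqs)))
  nuc_freqs <- sweep(nuc_freqs, 2, colSums(nuc_freqs), "/")
  cods <- sense_codons()
  f <- vapply(cods, function(cd) {
    b <- strsplit(cd, "")[[1]]
    nuc_freqs[b[1], 1] * nuc_freqs[b[2], 2] * nuc_freqs[b[3], 3]
  }, numeric(1))
  f / sum(f)
}

#' Empirical F3x4 frequencies from a codon alignment
#'
#' @param cmat codon matrix from [codon_matrix()].
#' @return named 61-vector.
#' @export
empirical_codon_freqs_f3x4 <- function(cmat) {
  cods <- cmat[!is.na(cmat)]
  nf <- sapply(1:3, function(p) {
    b <- substring(cods, p, p)
    tab <- table(factor(b, levels = c("A", "C", "G", "T")))
    (as.numeric(tab) + 1) / (sum(tab) + 4)
  })
  rownames(nf) <- c("A", "C", "G", "T")
  codon_freqs_f3x4(nf)
}

# Structural constants of the codon state space: for each single-nucleotide
# codon pair, whether the change is a transition and whether it is
# synonymous.  Computed once per session.
.codon_struct <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cods <- sense_codons()
    aa <- translate_codons(cods)
    n <- length(cods)
    b <- do.call(rbind, strsplit(cods, ""))
    ts_pair <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
    single <- matrix(FALSE, n, n)
    is_ts <- matrix(FALSE, n, n)
    for (p in 1:3) {
      same_other <- Reduce(`&`, lapply(setdiff(1:3, p), function(q)
        outer(b[, q], b[, q], "==")))
      diff_p <- outer(b[, p], b[, p], "!=")
      hit <- same_other & diff_p
      single <- single | hit
      is_ts <- is_ts | (hit & outer(b[, p], b[, p], ts_pair))
    }
    syn <- outer(aa, aa, "==")
    cache <<- list(codons = cods, single = single, is_ts = is_ts, syn = syn)
    cache
  }
})

#' Build a scaled generator matrix
#'
#' For a protein model, returns the reversible LG(+F) generator scaled so the
#' expected substitution rate at relative rate 1 is one substitution per
#' site.  For a codon model, returns the generator of one site class scaled
#' so branch lengths are expected substitutions per codon under the model's
#' class mixture.
#'
#' @param model `protein_model` or `codon_model`.
#' @param class site-class index (codon models; default 1).
#' @param foreground for branch-site use, build the foreground generator
#'   (omega2) instead of the background one.
#' @return generator matrix with attributes `freq` (stationary distribution)
#'   and, for codon models, `scale` (the mixture scaling factor applied).
#' @export
build_rate_matrix <- function(model, class = 1L, foreground = FALSE) {
  UseMethod("build_rate_matrix")
}

#' @export
build_rate_matrix.protein_model <- function(model, class = 1L, foreground = FALSE) {
  s <- model$exchangeabilities
  pi <- model$frequencies
  if (any(pi == 0 & colSums(s) > 0))
    stop("zero frequency with positive exchangeability: scaling unidentifiable")
  Q <- s * rep(pi, each = nrow(s))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  attr(Q, "freq") <- pi
  Q
}

# unscaled codon generator for one omega
.codon_q_raw <- function(kappa, omega, pi) {
  st <- .codon_struct()
  Q <- matrix(0, 61, 61, dimnames = list(st$codons, st$codons))
  rate <- ifelse(st$is_ts, kappa, 1)
  rate[!st$single] <- 0
  rate[st$single & !st$syn] <- rate[st$single & !st$syn] * omega
  Q <- rate * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(st$codons, st$codons)
  Q
}

#' @export
build_rate_matrix.codon_model <- function(model, class = 1L, foreground = FALSE) {
  pi <- model$codon_freqs
  omega <- if (foreground) {
    if (is.null(model$omega2)) stop("model has no foreground omega2")
    model$omega2
  } else model$site_classes$omega[class]
  Q <- .codon_q_raw(model$kappa, omega, pi)
  # mixture scaling: expected substitutions per codon = 1 per unit branch
  # length under the background class mixture
  mus <- vapply(model$site_classes$omega, function(w)
    -sum(pi * diag(.codon_q_raw(model$kappa, w, pi))), numeric(1))
  mu <- sum(model$site_classes$p * mus)
  Q <- Q / mu
  attr(Q, "freq") <- pi
  attr(Q, "scale") <- mu
  Q
}

#' Discrete-gamma rate multipliers
#'
#' Category means over equiprobable quantile bins of a Gamma(alpha, alpha)
#' density (mean 1), the convention of PAML's discrete-gamma approximation.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories (>= 1).
#' @return numeric vector of `ncat` rates with mean 1.
#' @export
discrete_gamma <- function(alpha, ncat) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (ncat < 1) stop("ncat must be >= 1")
  if (ncat == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  # E[X ; a<X<b] for X~Gamma(alpha, alpha) equals F(b; alpha+1) - F(a; alpha+1)
  cdf1 <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- diff(cdf1) * ncat
  r / mean(r)
}

# eigendecomposition of a reversible generator via its symmetrised form
.q_eigen <- function(Q) {
  pi <- attr(Q, "freq")
  sq <- sqrt(pi)
  B <- Q * (sq / rep(sq, each = nrow(Q)))  # diag(sq) Q diag(1/sq), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values,
       U = e$vectors / sq,          # diag(1/sq) V
       Uinv = t(e$vectors * sq),    # t(V) diag(sq)
       freq = pi)
}

.p_matrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$vals * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix
#'
#' `expm(Q * t * rate)` via eigendecomposition of the symmetrised reversible
#' generator.
#'
#' @param Q generator from [build_rate_matrix()] (carries its stationary
#'   distribution as attribute `freq`).
#' @param t branch length (>= 0).
#' @param rate rate multiplier (>= 0), e.g. a discrete-gamma category rate.
#' @return stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  if (rate < 0) stop("negative rate")
  if (t * rate == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- .p_matrix(.q_eigen(Q), t * rate)
  dimnames(P) <- dimnames(Q)
  P
}

#' Serialize a model to JSON
#'
#' @param model `protein_model` or `codon_model`.
#' @param path optional output path; otherwise the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  kind <- class(model)[1]
  payload <- c(list(kind = kind), unclass(model))
  payload$exchangeabilities <- NULL  # LG constants are implied for proteins
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a model from JSON
#'
#' @param json JSON string or path produced by [model_to_json()].
#' @return `protein_model` or `codon_model`.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (identical(x$kind, "protein_model")) {
    protein_model(frequencies = stats::setNames(unlist(x$frequencies),
                                                AA_ALPHABET),
                  alpha = x$alpha, ncat = x$ncat)
  } else if (identical(x$kind, "codon_model")) {
    codon_model(kappa = x$kappa,
                codon_freqs = stats::setNames(unlist(x$codon_freqs),
                                              sense_codons()),
                site_classes = list(p = x$site_classes$p,
                                    omega = x$site_classes$omega),
                foreground = x$foreground, omega2 = x$omega2)
  } else stop("unknown model kind in JSON")
}
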