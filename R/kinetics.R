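# Binding-kinetics estimation from association-dissociation traces: blank
# correction, steady-state and initial-rate extraction, one-site
# concentration-response fits under two averaging schemes, pKd/pKm
# transforms and Welch comparisons.

#' Blank-correct traces
#'
#' Subtracts the 0-concentration blank trace pointwise (per replicate and
#' phase); blank time grids are linearly interpolated when they differ.
#'
#' @param traces trace data.frame ([read_traces()] layout); rows with
#'   `concentration_M == 0` are used as blanks if `blank` is NULL.
#' @param blank optional separate blank trace data.frame.
#' @return corrected traces (blank rows removed).
#' @export
blank_correct <- function(traces, blank = NULL) {
  if (is.null(blank)) {
    blank <- traces[traces$concentration_M == 0, , drop = FALSE]
    traces <- traces[traces$concentration_M > 0, , drop = FALSE]
  }
  if (!nrow(blank)) return(traces)
  out <- traces
  for (rep_i in unique(traces$replicate)) {
    for (ph in unique(traces$phase)) {
      b <- blank[blank$replicate == rep_i & blank$phase == ph, , drop = FALSE]
      if (!nrow(b)) next
      sel <- out$replicate == rep_i & out$phase == ph
      tt <- out$time[sel]
      if (max(tt) < min(b$time) || min(tt) > max(b$time))
        stop("blank and trace time ranges do not overlap")
      bs <- stats::approx(b$time, b$signal, xout = tt, rule = 2)$y
      out$signal[sel] <- out$signal[sel] - bs
    }
  }
  out
}

#' Steady-state response of one association trace
#'
#' Arithmetic mean of the signal over the last `n_last` samples of the
#' association phase; traces with fewer samples are averaged whole, with a
#' warning.
#'
#' @param trace data.frame of one association series (columns time, signal).
#' @param n_last number of final samples to average (default 500).
#' @return mean response (nm).
#' @export
steady_state <- function(trace, n_last = 500) {
  sig <- trace$signal[order(trace$time)]
  if (!length(sig)) stop("empty trace")
  if (length(sig) < n_last) {
    warning("trace has ", length(sig), " < ", n_last,
            " samples; averaging all of them")
    return(mean(sig))
  }
  mean(sig[(length(sig) - n_last + 1):length(sig)])
}

#' Initial binding rate of one association trace
#'
#' Fits `R(t) = A (1 - exp(-k t))` by nonlinear least squares and returns the
#' derivative at t = 0, `A k`.  A windowed linear-slope alternative is
#' available via `method = "linear"`.
#'
#' @param trace data.frame of one association series.
#' @param method `"exponential"` (default) or `"linear"` (regression slope
#'   over the first `window` samples).
#' @param window sample count for the linear method.
#' @return initial rate (nm/s).
#' @export
initial_rate <- function(trace, method = c("exponential", "linear"),
                         window = 50) {
  method <- match.arg(method)
  ord <- order(trace$time)
  tt <- trace$time[ord]; sig <- trace$signal[ord]
  if (!length(tt)) stop("empty trace")
  if (method == "linear") {
    n <- min(window, length(tt))
    return(unname(stats::coef(stats::lm(sig[1:n] ~ tt[1:n]))[2]))
  }
  A0 <- max(sig[length(sig)], max(sig) * 0.9, 1e-8)
  below <- which(sig < 0.63 * A0)
  k0 <- max(1 / tt[if (length(below)) max(below) else 1], 1e-6)
  # rates faster than the sampling resolution are not identifiable; cap k at
  # the fastest resolvable exponential so saturated traces yield the maximal
  # resolvable initial slope instead of a divergent A*k
  k_max <- 2 / min(diff(tt))
  fit <- NULL
  for (ks in unique(pmin(c(k0, 0.1 * k_max, k_max), k_max))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(sig ~ A * (1 - exp(-k * tt)),
                        start = list(A = A0, k = ks),
                        lower = c(0, 1e-10), upper = c(Inf, k_max),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("initial-rate fit failed (singular or non-positive k); ",
         "n = ", length(tt), ", max signal = ", signif(max(sig), 4))
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0) stop("initial-rate fit returned k <= 0")
  unname(cf[["A"]] * cf[["k"]])
}

#' Fit a one-site binding curve
#'
#' Least-squares fit of `R = Rmax C / (K + C)` to concentration-response
#' points, multistarted from K at the minimum, geometric mean and maximum of
#' the concentrations.  Fits with r^2 <= 0.91 are flagged (not rejected).
#'
#' @param concentration molar concentrations (>= 4 distinct).
#' @param response responses (nm or nm/s).
#' @return list of class `binding_fit`: `K` (molar), `Rmax`, `r_squared`,
#'   `pK` (= -log10 K), `flagged` (logical).
#' @export
fit_one_site <- function(concentration, response) {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 4) stop("need >= 4 distinct concentrations")
  if (stats::sd(response) == 0) stop("all responses equal: K unidentifiable")
  starts <- c(min(concentration), exp(mean(log(concentration))), max(concentration))
  best <- NULL
  for (K0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(response ~ Rmax * concentration / (K + concentration),
                        start = list(Rmax = max(response), K = K0),
                        lower = c(1e-12, 1e-15),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("one-site fit failed at all starts")
  cf <- stats::coef(best$fit)
  sstot <- sum((response - mean(response))^2)
  r2 <- 1 - best$rss / sstot
  structure(list(K = unname(cf[["K"]]), Rmax = unname(cf[["Rmax"]]),
                 r_squared = r2, pK = -log10(unname(cf[["K"]])),
                 flagged = r2 <= 0.91),
            class = "binding_fit")
}

# split a trace table into per-(concentration, replicate) association series
.assoc_series <- function(traces) {
  a <- traces[traces$phase == "association" & traces$concentration_M > 0, ]
  split(a, list(a$concentration_M, a$replicate), drop = TRUE)
}

#' Estimate Kd and Km from a kinetics dataset
#'
#' Blank-corrects the traces, extracts per-(concentration, replicate)
#' steady-state responses and initial rates, and fits one-site curves under
#' one of two schemes: `per_replicate` fits each replicate separately and
#' averages the estimates; `averaged` averages the concentration-response
#' points across replicates (with standard errors) and fits once.
#'
#' @param traces trace data.frame including a 0-concentration blank.
#' @param scheme `"per_replicate"` or `"averaged"`.
#' @param n_last samples averaged for steady state.
#' @param measures which responses to fit: `"steady"` (Kd), `"rate"` (Km) or
#'   both (default).
#' @return list with `Kd` and `Km` entries (as requested); each carries the
#'   fitted values, `pK`, `r_squared`, per-replicate estimates and their
#'   `mean`/`se` (for `per_replicate`), and the concentration-response
#'   `points`.
#' @export
estimate_binding <- function(traces, scheme = c("per_replicate", "averaged"),
                             n_last = 500, measures = c("steady", "rate")) {
  scheme <- match.arg(scheme)
  measures <- match.arg(measures, several.ok = TRUE)
  corrected <- blank_correct(traces)
  series <- .assoc_series(corrected)
  info <- do.call(rbind, lapply(series, function(s) data.frame(
    concentration = s$concentration_M[1], replicate = s$replicate[1],
    steady = steady_state(s, n_last = n_last),
    rate = if ("rate" %in% measures) initial_rate(s) else NA_real_)))
  cols <- stats::setNames(measures, c(steady = "steady", rate = "rate")[measures])
  reps <- sort(unique(info$replicate))
  if (scheme == "per_replicate") {
    out <- lapply(cols, function(col) {
      fits <- lapply(reps, function(r) {
        sub <- info[info$replicate == r, ]
        tryCatch(fit_one_site(sub$concentration, sub[[col]]),
                 error = function(e) stop("replicate ", r, ": ",
                                          conditionMessage(e)))
      })
      K <- vapply(fits, `[[`, numeric(1), "K")
      list(K_mean = mean(K), K_se = stats::sd(K) / sqrt(length(K)),
           pK_values = -log10(K), pK_mean = mean(-log10(K)),
           pK_se = stats::sd(-log10(K)) / sqrt(length(K)),
           per_replicate = fits, K_values = K,
           r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
           scheme = "per_replicate")
    })
  } else {
    out <- lapply(cols, function(col) {
      agg_m <- tapply(info[[col]], info$concentration, mean)
      agg_se <- tapply(info[[col]], info$concentration,
                       function(x) stats::sd(x) / sqrt(length(x)))
      conc <- as.numeric(names(agg_m))
      fit <- fit_one_site(conc, as.numeric(agg_m))
      list(K_mean = fit$K, pK_mean = fit$pK, r_squared = fit$r_squared,
           fit = fit,
           points = data.frame(concentration = conc,
                               response = as.numeric(agg_m),
                               se = as.numeric(agg_se)),
           scheme = "averaged")
    })
  }
  list(Kd = out[["steady"]], Km = out[["rate"]], scheme = scheme,
       points = info)
}

#' Welch comparison of affinity estimates
#'
#' Two-tailed two-sample t test assuming unequal variances (Satterthwaite
#' df), run on the -log10 scale values supplied.
#'
#' @param estimates_a,estimates_b numeric vectors (>= 2 values each), e.g.
#'   per-replicate pKd values.
#' @return list with `t`, `df`, `p`.
#' @export
compare_affinities <- function(estimates_a, estimates_b) {
  stopifnot(length(estimates_a) >= 2, length(estimates_b) >= 2)
  if (stats::sd(estimates_a) == 0 && stats::sd(estimates_b) == 0) {
    if (mean(estimates_a) == mean(estimates_b))
      return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(estimates_a) - mean(estimates_b)) * Inf,
                df = NA_real_, p = 0))
  }
  ht <- stats::t.test(estimates_a, estimates_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
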