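# Three-component mixture for continuous-report orientation data:
# target von Mises + non-target (swap) von Mises + uniform guess, with a
# shared concentration kappa, fitted by EM on the doubled circle. Component
# means are fixed at the (doubled) target and interfering-item orientations,
# so only the weights and kappa are free.

log_i0 <- function(kappa) log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa

vm_logdens <- function(x, mu, kappa) kappa * cos(x - mu) - log(2 * pi) - log_i0(kappa)

# inverse of A(kappa) = I1/I0 (Fisher's approximation, refined by uniroot)
a1inv <- function(r, lower = 1e-3, upper = 500) {
  if (r <= 0) return(lower)
  k <- if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
  k <- min(max(k, lower), upper)
  f <- function(kk) besselI(kk, 1, TRUE) / besselI(kk, 0, TRUE) - r
  fl <- f(lower); fu <- f(upper)
  if (fl > 0) return(lower)
  if (fu < 0) return(upper)
  tryCatch(stats::uniroot(f, c(lower, upper), tol = 1e-10)$root,
           error = function(e) k)
}

#' Options controlling the mixture fit
#'
#' @param min_trials minimum trials required to attempt a fit.
#' @param n_restarts number of dispersed EM starting points.
#' @param max_iter maximum EM iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param kappa_bounds allowed range for the concentration.
#' @param seed kept for interface stability; the dispersed starts are a fixed
#'   deterministic set, so fits are reproducible regardless.
#' @return list of class `wm_mixture_opts`.
#' @export
mixture_opts <- function(min_trials = 20L, n_restarts = 10L, max_iter = 500L,
                         tol = 1e-8, kappa_bounds = c(1e-3, 500), seed = 1L) {
  structure(list(min_trials = min_trials, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol, kappa_bounds = kappa_bounds,
                 seed = seed),
            class = "wm_mixture_opts")
}

#' Mixture density of an orientation report on the doubled circle
#'
#' Density of the doubled report angle (radians) under the three-component
#' model: `p_target * vM(2r | 2t, kappa) + p_nontarget * vM(2r | 2nt, kappa)
#' + p_uniform / (2 pi)`. Integrates to 1 over the circle.
#'
#' @param report,target,nontarget orientations in degrees, in (-90, 90];
#'   `nontarget` may be `NA` where no interfering item exists (its component
#'   then contributes nothing and `p_nontarget` must be 0 for the density to
#'   normalise).
#' @param params list with `p_target`, `p_nontarget`, `p_uniform` (summing to
#'   1) and `kappa` (> 0).
#' @return density values (per radian on the doubled circle).
#' @export
mixture_density <- function(report, target, nontarget, params) {
  w <- c(params$p_target, params$p_nontarget, params$p_uniform)
  if (any(!is.finite(w)) || any(w < -1e-12) || abs(sum(w) - 1) > 1e-9)
    stop_invalid_input("mixture_density: proportions must be in [0,1] and sum to 1")
  if (!is.finite(params$kappa) || params$kappa < 0)
    stop_invalid_input("mixture_density: kappa must be non-negative")
  x <- to_full_circle(report)
  m1 <- to_full_circle(target)
  d <- w[1] * exp(vm_logdens(x, m1, params$kappa)) + w[3] / (2 * pi)
  has_nt <- !is.na(nontarget)
  if (any(has_nt)) {
    m2 <- to_full_circle(nontarget[has_nt])
    d[has_nt] <- d[has_nt] +
      w[2] * exp(vm_logdens(x[has_nt], m2, params$kappa))
  }
  d
}

# fixed dispersed starting grid (weights as (p_uniform, p_nontarget), kappa)
mixture_starts <- function(n, with_nontarget) {
  grid <- expand.grid(pu = c(0.05, 0.25, 0.60),
                      pnt = if (with_nontarget) c(0.02, 0.15, 0.40) else 0,
                      kappa = c(2, 8, 32))
  grid <- grid[grid$pu + grid$pnt < 1, ]
  grid[seq_len(min(n, nrow(grid))), , drop = FALSE]
}

#' Fit the swap mixture model by expectation-maximization
#'
#' Maximum-likelihood fit of the target / non-target / uniform mixture with
#' shared concentration, via EM from several dispersed starting points; the
#' best run is returned. Component means are fixed at the known stimulus
#' orientations, so the M-step updates only the weights and (in closed form
#' via the Bessel-ratio inverse) the concentration. The observed-data
#' log-likelihood is non-decreasing across iterations; the per-iteration
#' trace of the winning run is attached for inspection.
#'
#' @param reports,targets orientations in degrees.
#' @param nontargets interfering-item orientations, or `NULL` / all-`NA` for
#'   a two-component (target + uniform) fit.
#' @param opts a [mixture_opts()].
#' @return list of class `wm_mixture_fit`: `p_target`, `p_nontarget`,
#'   `p_uniform`, `kappa` (doubled-circle scale), `loglik`, `n_trials`,
#'   `converged`, `n_restarts_used`, and `trace` (loglik per iteration).
#' @export
fit_mixture <- function(reports, targets, nontargets = NULL,
                        opts = mixture_opts()) {
  n <- length(reports)
  if (n < opts$min_trials)
    stop_insufficient_data(sprintf("fit_mixture: %d trials < minimum %d",
                                   n, opts$min_trials))
  if (is.null(nontargets)) nontargets <- rep(NA_real_, n)
  x <- to_full_circle(reports)
  m1 <- to_full_circle(targets)
  has_nt <- !is.na(nontargets)
  with_nt <- any(has_nt)
  m2 <- ifelse(has_nt, nontargets * 2 * pi / 180, 0)
  c1 <- cos(x - m1)
  c2 <- ifelse(has_nt, cos(x - m2), 0)
  lo <- opts$kappa_bounds[1]; hi <- opts$kappa_bounds[2]

  run_em <- function(w, kappa) {
    ll_old <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(opts$max_iter)) {
      lk <- kappa * c1 - log(2 * pi) - log_i0(kappa)
      d1 <- w[1] * exp(lk)
      d2 <- ifelse(has_nt,
                   w[2] * exp(kappa * c2 - log(2 * pi) - log_i0(kappa)), 0)
      d3 <- w[3] / (2 * pi)
      tot <- d1 + d2 + d3
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= opts$tol * (abs(ll_old) + opts$tol)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      g1 <- d1 / tot; g2 <- d2 / tot; g3 <- d3 / tot
      w <- c(sum(g1), sum(g2), sum(g3)) / n
      if (!with_nt) { w[1] <- w[1] + w[2]; w[2] <- 0 }
      denom <- sum(g1) + sum(g2)
      if (denom > 1e-12) {
        cbar <- sum(g1 * c1 + g2 * c2) / denom
        kappa <- a1inv(cbar, lo, hi)
      }
    }
    list(w = w, kappa = kappa, loglik = ll, converged = converged, trace = trace)
  }

  starts <- mixture_starts(opts$n_restarts, with_nt)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- starts[i, ]
    w0 <- c(1 - st$pu - st$pnt, st$pnt, st$pu)
    fit <- run_em(w0, min(max(st$kappa, lo), hi))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(p_target = best$w[1], p_nontarget = best$w[2],
                 p_uniform = best$w[3], kappa = best$kappa,
                 loglik = best$loglik, n_trials = n,
                 converged = best$converged,
                 n_restarts_used = nrow(starts),
                 trace = best$trace),
            class = "wm_mixture_fit")
}

#' @export
print.wm_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Swap mixture fit (n = %d): p_target = %.3f, p_nontarget = %.3f, p_uniform = %.3f, kappa = %.2f\nloglik = %.2f, converged: %s\n",
    x$n_trials, x$p_target, x$p_nontarget, x$p_uniform, x$kappa, x$loglik,
    x$converged))
  invisible(x)
}

#' Swap-rate table per participant and condition
#'
#' Fits the mixture separately for each participant and condition cell on
#' interference-present trials (the only trials with a non-target) and
#' tabulates the estimated non-target proportion (the swap rate) along with
#' the other mixture parameters.
#'
#' @param records filtered trial records.
#' @param cells condition columns (default interference type x temporal
#'   predictability, pooling over onsets).
#' @param opts a [mixture_opts()].
#' @return data.frame: participant_id, cells, p_target, p_nontarget,
#'   p_uniform, kappa, loglik, converged.
#' @export
swap_table <- function(records, cells = c("interference_type", "predictability"),
                       opts = mixture_opts()) {
  r <- records[records$interference_present & !is.na(records$report_angle), ,
               drop = FALSE]
  key <- interaction(r[c("participant_id", cells)], drop = TRUE, lex.order = TRUE)
  pieces <- split(r, key)
  rows <- lapply(pieces, function(g) {
    fit <- fit_mixture(g$report_angle, g$target_angle, g$interference_angle, opts)
    cbind(g[1, c("participant_id", cells), drop = FALSE],
          data.frame(p_target = fit$p_target, p_nontarget = fit$p_nontarget,
                     p_uniform = fit$p_uniform, kappa = fit$kappa,
                     loglik = fit$loglik, converged = fit$converged))
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[c("participant_id", cells)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
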