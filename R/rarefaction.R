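#' Incidence frequency counts from a MaxN table
#'
#' Converts abundance (MaxN) to sample-based incidence: a species is
#' present in a deployment when its MaxN >= 1. Returns the reference-sample
#' summary used by all rarefaction operations.
#'
#' @param maxn a `maxn_table` ([compute_maxn]) or a deployments x species
#'   numeric matrix.
#' @return object of class `incidence_data`: `T` sampling units, `S_obs`
#'   observed species, `Q` (vector, `Q[k]` = number of species found in
#'   exactly k units, k = 1..T).
#' @export
incidence_counts <- function(maxn) {
  m <- if (inherits(maxn, "maxn_table")) maxn$maxn else as.matrix(maxn)
  T <- nrow(m)
  inc <- colSums(m >= 1)
  inc <- inc[inc > 0]
  Q <- tabulate(inc, nbins = max(T, 1L))
  structure(list(T = T, S_obs = length(inc), Q = Q),
            class = "incidence_data")
}

#' @export
print.incidence_data <- function(x, ...) {
  cat(sprintf("<incidence_data> T=%d, S_obs=%d, Q1=%d, Q2=%d\n",
              x$T, x$S_obs, Q1(x), Q2(x)))
  invisible(x)
}

Q1 <- function(inc) if (length(inc$Q) >= 1) inc$Q[1] else 0L
Q2 <- function(inc) if (length(inc$Q) >= 2) inc$Q[2] else 0L

#' Interpolated (rarefied) species richness
#'
#' Expected richness in t of the T sampling units, the hypergeometric
#' expectation over all subsets of size t:
#' S(t) = S_obs - sum_k Q_k C(T-k, t) / C(T, t). Computed with
#' log-binomials for numerical stability at large T.
#'
#' @param incidence an [incidence_counts] object.
#' @param t number of units, `1 <= t <= T` (vectorised).
#' @return expected richness, same length as `t`.
#' @export
rarefy <- function(incidence, t) {
  T <- incidence$T
  if (any(t < 1 | t > T)) stop("t must lie in [1, T]")
  ks <- which(incidence$Q > 0)
  vapply(t, function(tt) {
    miss <- sum(vapply(ks, function(k) {
      if (T - k < tt) return(0)
      incidence$Q[k] * exp(lchoose(T - k, tt) - lchoose(T, tt))
    }, numeric(1)))
    incidence$S_obs - miss
  }, numeric(1))
}

#' Chao2 asymptotic species richness
#'
#' Incidence-based nonparametric lower-bound estimator from uniques and
#' duplicates: S_obs + ((T-1)/T) Q1^2 / (2 Q2), with the bias-corrected
#' form S_obs + ((T-1)/T) Q1 (Q1 - 1) / (2 (Q2 + 1)) when Q2 = 0.
#'
#' @param incidence an [incidence_counts] object with `T >= 2`.
#' @return asymptotic richness estimate (>= S_obs).
#' @export
chao2 <- function(incidence) {
  stopifnot(incidence$T >= 2)
  q1 <- Q1(incidence); q2 <- Q2(incidence)
  Tn <- incidence$T
  if (q2 > 0)
    incidence$S_obs + (Tn - 1) / Tn * q1^2 / (2 * q2)
  else
    incidence$S_obs + (Tn - 1) / Tn * q1 * (q1 - 1) / (2 * (q2 + 1))
}

#' Extrapolated species richness beyond the reference sample
#'
#' S(T + t*) = S_obs + Q0_hat [1 - (1 - Q1 / (Q1 + T Q0_hat))^t*] with
#' Q0_hat = Chao2 - S_obs; flat at S_obs when Q1 = 0 (no signal of
#' undetected species).
#'
#' @param incidence an [incidence_counts] object.
#' @param t number of units, `t >= T` (vectorised; `t = T` returns
#'   `S_obs`, continuous with [rarefy]).
#' @return expected richness.
#' @export
extrapolate <- function(incidence, t) {
  T <- incidence$T
  if (any(t < T)) stop("extrapolation needs t >= T")
  q1 <- Q1(incidence)
  q0 <- chao2(incidence) - incidence$S_obs
  vapply(t, function(tt) {
    if (q1 == 0 || q0 <= 0) return(incidence$S_obs + 0)
    incidence$S_obs + q0 * (1 - (1 - q1 / (q1 + T * q0))^(tt - T))
  }, numeric(1))
}

# expected richness over an arbitrary t grid spanning both regimes
expected_richness <- function(incidence, t) {
  ifelse(t <= incidence$T, rarefy(incidence, pmin(t, incidence$T)),
         extrapolate(incidence, pmax(t, incidence$T)))
}

# bootstrap assemblage: estimated incidence probabilities of the observed
# species plus Q0_hat undetected species at a common estimated rate
bootstrap_assemblage <- function(incidence_matrix) {
  inc <- incidence_counts(incidence_matrix)
  Tn <- inc$T
  q1 <- Q1(inc); q2 <- Q2(inc)
  pres <- colSums(incidence_matrix >= 1)
  pres <- pres[pres > 0]
  # incidence-probability correction (standard sample-based bootstrap)
  C_hat <- if (q1 + q2 > 0) 1 - q1 / (q1 + q2) * q1 / max(sum(pres), 1) else 1
  pi_obs <- pres / Tn * C_hat
  q0 <- max(0, round(chao2(inc) - inc$S_obs))
  pi_undet <- if (q0 > 0) rep((1 - C_hat) * sum(pres / Tn) / q0, q0) else numeric(0)
  c(pi_obs, pi_undet)
}

#' Bootstrap confidence bands for a rarefaction curve
#'
#' Resamples the estimated assemblage (observed species at their estimated
#' incidence probabilities plus the estimated undetected species at a
#' common rate), regenerates T-unit incidence data per replicate, and
#' recomputes the interpolated/extrapolated curve. Percentile 95% bands by
#' default; a normal-approximation alternative is available.
#'
#' @param maxn_matrix deployments x species presence/abundance matrix (the
#'   reference sample; needed to estimate incidence probabilities).
#' @param t_grid unit grid for the curve.
#' @param B bootstrap replicates (>= 200 recommended).
#' @param seed integer seed.
#' @param level confidence level.
#' @param method `"percentile"` or `"normal"`.
#' @return data.frame: `t`, `S`, `lower`, `upper`, `regime`.
#' @export
bootstrap_ci <- function(maxn_matrix, t_grid, B = 200, seed = 1,
                         level = 0.95, method = c("percentile", "normal")) {
  method <- match.arg(method)
  m <- if (inherits(maxn_matrix, "maxn_table")) maxn_matrix$maxn else
    as.matrix(maxn_matrix)
  inc <- incidence_counts(m)
  S_hat <- expected_richness(inc, t_grid)
  pi <- bootstrap_assemblage(m)
  Tn <- inc$T
  set.seed(split_seed(seed, 1L))
  boot <- matrix(NA_real_, B, length(t_grid))
  for (b in seq_len(B)) {
    Z <- matrix(stats::rbinom(Tn * length(pi), 1, rep(pi, each = Tn)),
                Tn, length(pi))
    bi <- incidence_counts(Z)
    boot[b, ] <- if (bi$S_obs == 0) 0 else expected_richness(bi, t_grid)
  }
  a <- (1 - level) / 2
  if (method == "percentile") {
    qs <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
    ctr <- colMeans(boot)
    lower <- S_hat + (qs[1, ] - ctr)
    upper <- S_hat + (qs[2, ] - ctr)
  } else {
    se <- apply(boot, 2, stats::sd)
    zq <- stats::qnorm(1 - a)
    lower <- S_hat - zq * se
    upper <- S_hat + zq * se
  }
  data.frame(t = t_grid, S = S_hat,
             lower = pmax(0, pmin(lower, S_hat)), upper = pmax(upper, S_hat),
             regime = ifelse(t_grid <= Tn, "interpolated", "extrapolated"))
}

#' Full rarefaction/extrapolation curve with asymptote
#'
#' Convenience wrapper producing the curve table to `t_max` units plus the
#' Chao2 asymptote with its bootstrap CI, optionally per habitat stratum
#' (subsetting deployments before tallying).
#'
#' @param maxn a `maxn_table`.
#' @param t_max largest number of units on the grid.
#' @param deployments optional metadata with `habitat` for per-stratum
#'   curves.
#' @param by optional grouping column in `deployments`.
#' @param B,seed bootstrap controls.
#' @param n_grid number of grid points.
#' @return list of per-group lists: `curve` (data.frame), `asymptote`,
#'   `asymptote_ci` (bootstrap percentile 95%).
#' @export
rarefaction_curve <- function(maxn, t_max = 1500, deployments = NULL,
                              by = NULL, B = 200, seed = 1, n_grid = 40) {
  m <- if (inherits(maxn, "maxn_table")) maxn$maxn else as.matrix(maxn)
  groups <- if (is.null(by)) list(all = rownames(m)) else
    split(deployments$deployment_id, deployments[[by]])
  seeds <- split_seed(seed, length(groups))
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  for (g in seq_along(groups)) {
    mg <- m[rownames(m) %in% groups[[g]], , drop = FALSE]
    inc <- incidence_counts(mg)
    t_grid <- unique(round(c(
      seq(1, inc$T, length.out = ceiling(n_grid / 2)),
      seq(inc$T, t_max, length.out = floor(n_grid / 2)))))
    curve <- bootstrap_ci(mg, t_grid, B = B, seed = seeds[g])
    set.seed(seeds[g])
    ch <- vapply(seq_len(B), function(b) {
      pi <- bootstrap_assemblage(mg)
      Z <- matrix(stats::rbinom(inc$T * length(pi), 1, rep(pi, each = inc$T)),
                  inc$T, length(pi))
      bi <- incidence_counts(Z)
      if (bi$T >= 2 && bi$S_obs > 0) chao2(bi) else NA_real_
    }, numeric(1))
    est <- chao2(inc)
    qs <- stats::quantile(ch, c(0.025, 0.975), na.rm = TRUE)
    out[[g]] <- list(curve = curve, asymptote = est,
                     asymptote_ci = est + (qs - mean(ch, na.rm = TRUE)))
  }
  out
}
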