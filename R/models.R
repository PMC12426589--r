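#' Build the a-priori candidate model set
#'
#' Generates model specifications from a predictor list under the standard
#' survey recipe: a null model (mandatory terms only), each single
#' predictor, each single predictor crossed with main habitat type (full
#' factorial interaction), and the most complex model (depth + relief).
#' Mandatory terms (the spatially lagged response and a categorical year
#' effect) are appended to every model unless configured off. An optional
#' block of additive predictor pairs extends the set to a requested size.
#'
#' @param predictors character vector of screened predictor names.
#' @param response response column name.
#' @param family one of `"poisson"`, `"nbinom"`, `"gamma"`, `"gaussian"`.
#' @param include_lag,include_year mandatory-term toggles.
#' @param habitat_var name of the habitat factor used in interactions (set
#'   `NULL` to skip the interaction block).
#' @param complex_terms character vector for the "most complex" additive
#'   model (default `c("depth_m", "relief")` when both are available).
#' @param additive_pairs if `TRUE`, append all additive predictor pairs.
#' @param n_target optional target count; pairs are appended in order until
#'   the set reaches it (error if unreachable).
#' @return list of `model_spec` lists: `response`, `terms`, `family`,
#'   `label`. Duplicate term sets are collapsed with a warning.
#' @export
build_candidate_set <- function(predictors, response, family = "gaussian",
                                include_lag = TRUE, include_year = TRUE,
                                habitat_var = "habitat",
                                complex_terms = NULL,
                                additive_pairs = FALSE, n_target = NULL) {
  mandatory <- c(if (include_lag) "spatial_lag", if (include_year) "year")
  specs <- list(list(terms = character(0), label = "null"))
  for (p in predictors)
    specs <- c(specs, list(list(terms = p, label = p)))
  if (!is.null(habitat_var))
    for (p in predictors)
      specs <- c(specs, list(list(terms = paste0(p, " * ", habitat_var),
                                  label = paste0(p, " x ", habitat_var))))
  if (is.null(complex_terms) && all(c("depth_m", "relief") %in% predictors))
    complex_terms <- c("depth_m", "relief")
  if (!is.null(complex_terms))
    specs <- c(specs, list(list(terms = complex_terms,
                                label = paste(complex_terms, collapse = " + "))))
  key_of <- function(s) paste(sort(s$terms), collapse = "|")
  key <- vapply(specs, key_of, character(1))
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)), " duplicate model spec(s)")
    specs <- specs[!duplicated(key)]
    key <- key[!duplicated(key)]
  }
  if (additive_pairs || !is.null(n_target)) {
    prs <- if (length(predictors) >= 2) utils::combn(predictors, 2, simplify = FALSE)
           else list()
    for (pr in prs) {
      if (!is.null(n_target) && length(specs) >= n_target) break
      s <- list(terms = pr, label = paste(pr, collapse = " + "))
      if (key_of(s) %in% key) next
      specs <- c(specs, list(s))
      key <- c(key, key_of(s))
    }
  }
  if (!is.null(n_target) && length(specs) != n_target)
    stop("candidate recipe yields ", length(specs), " specs, not ", n_target)
  lapply(specs, function(s) {
    structure(list(response = response, terms = s$terms, family = family,
                   mandatory = mandatory, label = s$label),
              class = "model_spec")
  })
}

spec_formula <- function(spec) {
  rhs <- c(spec$terms, spec$mandatory)
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit one candidate GLM
#'
#' Poisson and gamma with log link and Gaussian with identity link go
#' through iteratively reweighted least squares (`stats::glm`); the
#' negative binomial is fitted with joint maximum likelihood over the shape
#' parameter (`MASS::glm.nb`). `k` counts every estimated parameter,
#' including the NB shape and the gamma dispersion. Non-convergent fits are
#' flagged (and later excluded from ranking).
#'
#' @param spec a `model_spec` from [build_candidate_set].
#' @param data data.frame with the response, predictors and mandatory
#'   terms; complete cases for the involved terms are used.
#' @return object of class `model_fit`: `spec`, `fit`, `coefficients`
#'   (estimate/SE table), `loglik`, `k`, `n`, `converged`, `deviance`,
#'   `null_deviance`.
#' @export
fit_glm <- function(spec, data) {
  f <- spec_formula(spec)
  vars <- all.vars(f)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if ("year" %in% vars) data$year <- factor(data$year)
  if (spec$family == "gamma" && any(data[[spec$response]] <= 0))
    stop("gamma family needs strictly positive responses")
  fit <- switch(spec$family,
    poisson = stats::glm(f, data = data, family = stats::poisson()),
    gamma = stats::glm(f, data = data, family = stats::Gamma(link = "log")),
    gaussian = stats::glm(f, data = data, family = stats::gaussian()),
    nbinom = suppressWarnings(MASS::glm.nb(f, data = data)),
    stop("unknown family: ", spec$family)
  )
  conv <- isTRUE(fit$converged)
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")  # counts NB shape / dispersion
  cf <- summary(fit)$coefficients
  structure(list(
    spec = spec, fit = fit,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], row.names = NULL),
    loglik = ll, k = k, n = stats::nobs(fit), converged = conv,
    deviance = stats::deviance(fit), null_deviance = fit$null.deviance,
    residuals = stats::residuals(fit, type = "deviance")
  ), class = "model_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1).
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters (including any dispersion or
#'   shape parameter).
#' @param n sample size; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank a candidate set by AICc
#'
#' Sorts converged fits by AICc and reports Delta-AICc, Akaike weights
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2), deviance-explained
#' pseudo-R2 (1 - residual deviance / null deviance; see the package
#' vignette for why this definition was chosen and the McFadden
#' alternative), Delta-AICc to the null model, and membership of the
#' within-2-units confidence set.
#'
#' @param fits list of `model_fit` objects over one response.
#' @param pseudo_r2 `"deviance"` (default) or `"mcfadden"`.
#' @return data.frame ranking table, best model first.
#' @export
rank_models <- function(fits, pseudo_r2 = c("deviance", "mcfadden")) {
  pseudo_r2 <- match.arg(pseudo_r2)
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(conv)) stop("no converged fits to rank")
  if (any(!conv)) warning(sum(!conv), " non-converged fit(s) excluded")
  fits <- fits[conv]
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      model = f$spec$label,
      terms = paste(c(f$spec$terms, f$spec$mandatory), collapse = " + "),
      family = f$spec$family,
      k = f$k, n = f$n, loglik = f$loglik,
      aicc = aicc(f$loglik, f$k, f$n),
      pseudo_r2 = if (pseudo_r2 == "deviance")
        1 - f$deviance / f$null_deviance
      else {
        null_ll <- f$loglik + (f$deviance - f$null_deviance) / 2
        1 - f$loglik / null_ll
      }
    )
  }))
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$weight <- exp(-tab$delta_aicc / 2) / sum(exp(-tab$delta_aicc / 2))
  null_aicc <- tab$aicc[tab$model == "null"]
  tab$delta_to_null <- if (length(null_aicc)) null_aicc - tab$aicc else NA_real_
  tab$in_confidence_set <- tab$delta_aicc <= 2
  rownames(tab) <- NULL
  tab
}

#' Fit and rank a full candidate set for one response
#'
#' Convenience wrapper: builds (or accepts) the candidate set, recomputes
#' the spatially lagged response from the supplied coordinates, fits every
#' spec, and returns the ranking with the fits attached. The lag is
#' recomputed per response because it is a lagged *dependent* variable.
#'
#' @param data data.frame with the response, predictors, `x`, `y`, and any
#'   mandatory-term columns.
#' @param response response column name.
#' @param predictors predictor names.
#' @param family GLM family string.
#' @param k_neighbours neighbours for the spatial lag.
#' @param ... passed to [build_candidate_set].
#' @return list: `ranking` (data.frame), `fits` (named by label),
#'   `weights` (the [knn_weights] used for the lag).
#' @export
model_suite <- function(data, response, predictors, family,
                        k_neighbours = 4, ...) {
  w <- knn_weights(data[, c("x", "y")], k = k_neighbours)
  data$spatial_lag <- knn_lag(NULL, data[[response]], weights = w)
  specs <- build_candidate_set(predictors, response, family, ...)
  fits <- lapply(specs, fit_glm, data = data)
  names(fits) <- vapply(specs, `[[`, character(1), "label")
  list(ranking = rank_models(fits), fits = fits, weights = w)
}
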