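test_that("aicc arithmetic, limits and guards", {
  expect_equal(aicc(-100, 3, 100), 206 + 24 / 96)
  expect_equal(aicc(-50, 0, 30), 100)
  expect_lt(abs(aicc(-1000, 5, 1e5) - (2 * 1000 + 10)), 0.01)
  expect_error(aicc(-10, 5, 6), "exceed")
})

test_that("candidate recipe: enumeration, null-only, target count", {
  preds <- c("depth_m", "relief", "sst_c", "exposure_deg", "remoteness_m")
  specs <- build_candidate_set(preds, "richness", "poisson")
  # 1 null + 5 singles + 5 habitat interactions + depth+relief = 12
  expect_length(specs, 12)
  labs <- vapply(specs, `[[`, character(1), "label")
  expect_true("null" %in% labs)
  expect_true("depth_m + relief" %in% labs)
  expect_equal(sum(grepl("x habitat", labs)), 5)
  # mandatory terms on every spec
  expect_true(all(vapply(specs, function(s)
    all(c("spatial_lag", "year") %in% s$mandatory), logical(1))))
  expect_length(build_candidate_set(character(0), "y"), 1)
  # additive-pairs block extends the set to exactly 17 unique specs
  s17 <- build_candidate_set(preds, "richness", "poisson", n_target = 17)
  expect_length(s17, 17)
  keys <- vapply(s17, function(s) paste(sort(s$terms), collapse = "|"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

make_glm_data <- function(n = 200, seed = 1) {
  set.seed(seed)
  data.frame(
    x = runif(n) * 1e3, y = runif(n) * 1e3,
    depth_m = runif(n, 0, 40), relief = sample(0:5, n, TRUE),
    sst_c = rnorm(n, 14), year = rep(2022:2023, length.out = n),
    habitat = sample(c("Reefs", "Sediments"), n, TRUE)
  )
}

test_that("fit_glm families behave and count their parameters", {
  d <- make_glm_data(250, 3)
  d$spatial_lag <- 0
  d$yresp <- rpois(250, exp(0.5 + 0.05 * d$depth_m))
  spec <- build_candidate_set("depth_m", "yresp", "poisson",
                              include_lag = FALSE, include_year = FALSE,
                              habitat_var = NULL)[[2]]
  f <- fit_glm(spec, d)
  expect_true(f$converged)
  expect_equal(f$k, 2)  # intercept + slope
  # gamma intercept-only reproduces the mean on the link scale
  d$g <- rep(3.7, 250)
  gf <- fit_glm(build_candidate_set(character(0), "g", "gamma",
                                    include_lag = FALSE,
                                    include_year = FALSE)[[1]], d)
  expect_equal(exp(gf$coefficients$estimate[1]), 3.7, tolerance = 1e-6)
  expect_equal(gf$k, 2)  # intercept + dispersion
  expect_error(fit_glm(build_candidate_set(character(0), "gneg", "gamma",
                                           include_lag = FALSE,
                                           include_year = FALSE)[[1]],
                       transform(d, gneg = g - 4)), "positive")
  # NB on Poisson data: dispersion near 1, AICc within 2 of the Poisson fit
  nb <- fit_glm(build_candidate_set("depth_m", "yresp", "nbinom",
                                    include_lag = FALSE,
                                    include_year = FALSE,
                                    habitat_var = NULL)[[2]], d)
  expect_equal(nb$k, 3)  # + shape
  expect_lt(abs(aicc(nb$loglik, nb$k, nb$n) - aicc(f$loglik, f$k, f$n)), 2.5)
})

test_that("rank_models: weights, deltas, confidence set, invariances", {
  mk <- function(ll, k, label) structure(
    list(spec = list(label = label, terms = label, mandatory = NULL,
                     family = "poisson"),
         loglik = ll, k = k, n = 100, converged = TRUE,
         deviance = 50, null_deviance = 100), class = "model_fit")
  r <- rank_models(list(mk(-100, 3, "a"), mk(-100, 3, "b")))
  expect_equal(r$weight, c(0.5, 0.5))
  # delta of exactly 2: closed-form weights
  r2 <- rank_models(list(mk(-100, 3, "a"), mk(-101, 3, "b")))
  expect_equal(r2$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))))
  expect_equal(r2$delta_aicc, c(0, 2))
  expect_true(all(r2$in_confidence_set))
  expect_equal(sum(r2$weight), 1)
  # ranking invariant to a constant added to all log-likelihoods
  r3 <- rank_models(list(mk(-90, 3, "a"), mk(-91, 3, "b")))
  expect_equal(r3$weight, r2$weight)
  expect_equal(r2$pseudo_r2, c(0.5, 0.5))
  # null-relative delta present when a null model is in the set
  r4 <- rank_models(list(mk(-100, 3, "a"), mk(-120, 1, "null")))
  expect_equal(r4$delta_to_null[1],
               aicc(-120, 1, 100) - aicc(-100, 3, 100))
})

test_that("poisson parameter recovery and selection at survey scale", {
  # scaled-down smoke version of the full-replicate acceptance check;
  # the bound here is loose enough (~4 sd below the nominal 95% Wald
  # coverage) not to trip on binomial noise at this replicate count
  hits <- 0L; sel <- 0L
  R <- 30
  for (r in seq_len(R)) {
    d <- make_glm_data(280, seed = 100 + r)
    set.seed(500 + r)
    d$richness <- rpois(280, exp(0.8 + 0.05 * d$depth_m))
    # lag omitted: the generator has no spatial structure, so the
    # matching model set is lag-free (a lagged response would bias slopes)
    ms <- model_suite(d, "richness", c("depth_m", "relief", "sst_c"),
                      "poisson", include_year = FALSE, include_lag = FALSE,
                      complex_terms = c("depth_m", "relief"))
    cf <- ms$fits[["depth_m"]]$coefficients
    est <- cf$estimate[cf$term == "depth_m"]
    se <- cf$se[cf$term == "depth_m"]
    if (abs(est - 0.05) <= 2 * se) hits <- hits + 1L
    top <- ms$ranking[ms$ranking$in_confidence_set, "model"]
    if (any(c("depth_m", "depth_m x habitat", "depth_m + relief") %in% top))
      sel <- sel + 1L
  }
  expect_gte(hits, 25)
  expect_gte(sel, 25)
})
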