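toy_inc <- function(pres) incidence_counts(pres)

test_that("incidence counts: worked example, empty table, brute tally", {
  pres <- rbind(c(1, 1), c(1, 0), c(1, 0))  # A in all 3 units, B in one
  inc <- toy_inc(pres)
  expect_equal(inc$T, 3)
  expect_equal(inc$S_obs, 2)
  expect_equal(inc$Q[1], 1)
  expect_equal(inc$Q[3], 1)
  expect_equal(incidence_counts(matrix(0, 3, 4))$S_obs, 0)
  set.seed(2)
  for (i in 1:10) {
    m <- matrix(rbinom(40, 1, 0.4), 8, 5)
    inc <- incidence_counts(m)
    cs <- colSums(m)
    expect_equal(sum(inc$Q), inc$S_obs)
    for (k in seq_len(8))
      expect_equal(inc$Q[k], sum(cs == k))
  }
})

test_that("rarefy: boundary identities and exhaustive-subset enumeration", {
  set.seed(3)
  for (i in 1:15) {
    T <- sample(3:8, 1)
    pres <- matrix(rbinom(T * 6, 1, runif(1, 0.2, 0.7)), T, 6)
    if (!any(colSums(pres) > 0)) pres[1, 1] <- 1
    inc <- incidence_counts(pres)
    expect_equal(rarefy(inc, T), inc$S_obs)
    expect_equal(rarefy(inc, 1), sum(seq_along(inc$Q) * inc$Q) / T)
    for (t in seq_len(T))
      expect_equal(rarefy(inc, t), enum_rarefy(pres, t), tolerance = 1e-10)
    # monotone non-decreasing
    expect_true(all(diff(rarefy(inc, seq_len(T))) >= -1e-12))
  }
  expect_error(rarefy(incidence_counts(diag(3)), 5), "\\[1, T\\]")
})

test_that("chao2: closed forms and Q1 = 0 degeneracy", {
  inc <- structure(list(T = 100, S_obs = 50,
                        Q = c(10, 5, rep(0, 98))),
                   class = "incidence_data")
  expect_equal(chao2(inc), 50 + 0.99 * 100 / 10)  # 59.9
  inc0 <- structure(list(T = 10, S_obs = 5, Q = c(0, 2, 3, rep(0, 7))),
                    class = "incidence_data")
  expect_equal(chao2(inc0), 5)
  # bias-corrected branch when Q2 = 0
  incq <- structure(list(T = 10, S_obs = 5, Q = c(3, 0, 2, rep(0, 7))),
                    class = "incidence_data")
  expect_equal(chao2(incq), 5 + 0.9 * 3 * 2 / 2)
  # always at least S_obs
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rbinom(60, 1, 0.3), 12, 5)
    if (!any(colSums(m) > 0)) m[1, 1] <- 1
    expect_gte(chao2(incidence_counts(m)), incidence_counts(m)$S_obs)
  }
})

test_that("extrapolate: continuity, hand evaluation, asymptotic limit", {
  inc <- structure(list(T = 10, S_obs = 20, Q = c(4, 2, rep(0, 8))),
                   class = "incidence_data")
  expect_equal(extrapolate(inc, 10), 20)
  q0 <- chao2(inc) - 20
  hand <- 20 + q0 * (1 - (1 - 4 / (4 + 10 * q0))^10)
  expect_equal(extrapolate(inc, 20), hand)
  expect_equal(extrapolate(inc, 1e7), chao2(inc), tolerance = 1e-6)
  # flat when no uniques
  inc0 <- structure(list(T = 10, S_obs = 5, Q = c(0, 5, rep(0, 8))),
                    class = "incidence_data")
  expect_equal(extrapolate(inc0, 100), 5)
  expect_error(extrapolate(inc, 5), "t >= T")
  # continuity and monotonicity across the boundary
  set.seed(6)
  m <- matrix(rbinom(200, 1, 0.25), 20, 10)
  inc2 <- incidence_counts(m)
  curve <- c(rarefy(inc2, 1:20), extrapolate(inc2, 21:60))
  expect_true(all(diff(curve) >= -1e-9))
})

test_that("bootstrap bands: degenerate zero width, width shrinks with T", {
  full <- matrix(1, 10, 4)  # every species in every unit
  ci <- bootstrap_ci(full, t_grid = c(2, 5, 10, 20), B = 50, seed = 1)
  expect_equal(ci$lower, ci$S)
  expect_equal(ci$upper, ci$S)
  expect_equal(ci$regime, c(rep("interpolated", 3), "extrapolated"))
  set.seed(9)
  probs <- runif(30, 0.05, 0.5)
  sim_inc <- function(T) matrix(rbinom(T * 30, 1, rep(probs, each = T)),
                                T, 30)
  w50 <- bootstrap_ci(sim_inc(50), t_grid = 25, B = 100, seed = 2)
  w200 <- bootstrap_ci(sim_inc(200), t_grid = 25, B = 100, seed = 2)
  expect_lt(w200$upper - w200$lower, w50$upper - w50$lower)
})

test_that("rarefaction_curve wrapper: grid regimes and per-stratum subsetting", {
  sim <- simulate_annotations(toy_plan(30, seed = 12), species_pool(12),
                              n_frames = 5, seed = 8)
  mx <- compute_maxn(validate_annotations(sim$annotations),
                     deployments = sim$deployments$deployment_id)
  rc <- rarefaction_curve(mx, t_max = 100, B = 50, seed = 3)
  cv <- rc$all$curve
  expect_true(all(diff(cv$S) >= -1e-9))
  expect_gte(rc$all$asymptote, max(cv$S[cv$regime == "interpolated"]) - 1e-9)
  dep <- sim$deployments
  rc2 <- rarefaction_curve(mx, t_max = 60, deployments = dep,
                           by = "habitat", B = 30, seed = 4)
  expect_setequal(names(rc2), c("Reefs", "Sediments"))
  # stratum curves are built from the stratum subset only
  sub <- mx$maxn[dep$deployment_id[dep$habitat == "Reefs"], , drop = FALSE]
  expect_equal(max(rc2$Reefs$curve$S[rc2$Reefs$curve$regime ==
                                       "interpolated"]),
               incidence_counts(sub)$S_obs)
})
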