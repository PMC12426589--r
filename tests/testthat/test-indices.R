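test_that("richness and shannon match their closed forms and vegan", {
  expect_equal(richness(c(A = 3, B = 1, C = 0)), 2)
  expect_equal(richness(c(A = 0, B = 0)), 0)
  expect_equal(shannon(c(a = 5, b = 5, c = 5, d = 5)), log(4))
  expect_equal(shannon(c(a = 7)), 0)
  expect_equal(shannon(c(A = 2, B = 1, C = 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_warning(expect_true(is.na(shannon(c(a = 0, b = 0)))), "undefined")
  # rescaling invariance and the ln S maximum
  set.seed(1)
  for (i in 1:10) {
    v <- rpois(6, 4) + 1
    expect_equal(shannon(v), shannon(10 * v))
    expect_lte(shannon(v), log(length(v)) + 1e-12)
  }
  # vegan as independent oracle on random rows
  m <- matrix(rpois(60, 3), 10, 6)
  m[1, ] <- c(1, 0, 0, 0, 0, 0)
  ours <- apply(m, 1, function(r) if (sum(r) > 0) shannon(r) else NA)
  expect_equal(unname(ours), unname(vegan::diversity(m, index = "shannon")))
})

test_that("dispersion index: definition, Poisson calibration, NB contrast", {
  expect_equal(dispersion_index(rep(4, 10)), 0)
  expect_warning(expect_true(is.na(dispersion_index(rep(0, 5)))), "zero mean")
  set.seed(7)
  expect_lt(abs(dispersion_index(rpois(1e5, 7)) - 1), 0.05)
  expect_gt(dispersion_index(rnbinom(1e4, size = 0.3, mu = 5)), 2)
})

lens <- data.frame(
  deployment_id = c("d1", "d1", "d2", "d3"),
  taxon = c("tx", "tx", "tx", "tx"),
  length_mm = c(300, 340, 100, 200),
  subhabitat = c("reefA", "reefA", "reefA", "sandB"))
reg <- data.frame(taxon = c("tx", "never"), a = 1e-5, b = 3,
                  ref_length_mm = c(NA, 250), length_type = "total",
                  family = "fam", is_family = FALSE)

test_that("proxy-length cascade walks its tiers in order", {
  r <- resolve_length("tx", "d1", lens, "reefA", reg)
  expect_equal(r$length_mm, 320)
  expect_equal(r$tier, "measured-in-sample")
  # unmeasured here, measured elsewhere in the same sub-habitat: pooled mean
  r <- resolve_length("tx", "d9", lens, "reefA", reg)
  expect_equal(r$length_mm, mean(c(300, 340, 100)))
  expect_equal(r$tier, "subhabitat-mean")
  # no sub-habitat data: study-wide mean
  r <- resolve_length("tx", "d9", lens, "unseen-hab", reg)
  expect_equal(r$length_mm, mean(lens$length_mm))
  expect_equal(r$tier, "study-mean")
  # never measured in the study: registry reference
  r <- resolve_length("never", "d1", lens, "reefA", reg)
  expect_equal(r$length_mm, 250)
  expect_equal(r$tier, "reference")
  # mono gear skips the in-sample tier
  r <- resolve_length("tx", "d1", lens, "reefA", reg, gear = "mono")
  expect_equal(r$tier, "subhabitat-mean")
  expect_error(resolve_length("ghost", "d1", lens, "reefA", reg),
               "ghost")
})

test_that("family-level taxa resolve to the study-level family mean", {
  reg_fam <- rbind(reg,
                   data.frame(taxon = "fam", a = 1e-5, b = 3,
                              ref_length_mm = NA, length_type = "total",
                              family = NA, is_family = TRUE))
  r <- resolve_length("fam", "d1", lens, "reefA", reg_fam)
  expect_equal(r$tier, "family-mean")
  expect_equal(r$length_mm, mean(lens$length_mm))
})

test_that("biomass is the a L^b MaxN sum in kg and additive", {
  res <- list(tx = list(length_mm = 100, tier = "reference", n = 0))
  expect_equal(biomass(c(tx = 2), res, reg), 2 * 1e-5 * 100^3 / 1000)
  expect_equal(biomass(c(tx = 0), res, reg), 0)
  # spreadsheet-style recomputation over a random 5-taxon row
  set.seed(3)
  reg5 <- data.frame(taxon = paste0("t", 1:5), a = runif(5, 1e-6, 1e-4),
                     b = runif(5, 2.5, 3.3), ref_length_mm = NA,
                     length_type = "total", family = "f", is_family = FALSE)
  L <- runif(5, 80, 600); n <- rpois(5, 3) + 1
  res5 <- lapply(L, function(l) list(length_mm = l, tier = "study-mean",
                                     n = 1))
  names(res5) <- reg5$taxon
  row <- setNames(n, reg5$taxon)
  manual <- sum(reg5$a * L^reg5$b * n) / 1000
  expect_equal(biomass(row, res5, reg5), manual)
  # linearity in MaxN per taxon
  expect_equal(biomass(row * 2, res5, reg5), 2 * manual)
  expect_error(biomass(c(unknown = 1), res5, reg5), "unknown")
})

test_that("index_table: tier tally is all-measured under full detectability", {
  plan <- toy_plan(15, seed = 9)
  pool <- species_pool(5, seed = 2)
  pool$detectability <- 1
  sim <- simulate_annotations(plan, pool, n_frames = 6, seed = 4)
  mx <- filter_demersal(compute_maxn(validate_annotations(sim$annotations),
                                     deployments = plan$site_id), pool)
  idx <- index_table(mx, sim$annotations, sim$deployments, lw_registry(pool))
  expect_equal(sum(idx$tier_measured_in_sample),
               sum(rowSums(mx$maxn > 0)))
  expect_true(all(idx$biomass_kg >= 0))
  expect_true(all(idx$richness <= rowSums(mx$maxn > 0)))
  expect_true(all(is.na(idx$shannon) | idx$shannon >= 0))
})

test_that("habitat contrasts: identical groups, exact W, grouped means", {
  idx <- data.frame(deployment_id = sprintf("d%d", 1:6),
                    richness = c(1, 2, 3, 4, 5, 6),
                    abundance = 1, shannon = 1, biomass_kg = 1)
  dep <- data.frame(deployment_id = idx$deployment_id,
                    habitat = rep(c("Reefs", "Sediments"), each = 3),
                    subhabitat = rep(c("circalittoral rock",
                                       "subtidal sediments"), each = 3))
  hs <- habitat_summary(idx, dep)
  # exact enumeration: with groups {1,2,3} vs {4,5,6} no x beats any y
  w <- hs$habitat_tests$W[hs$habitat_tests$index == "richness"]
  count_u <- sum(outer(1:3, 4:6, ">"))
  expect_equal(unname(w), count_u)
  # identical exchangeable groups: two-sided p = 1
  p1 <- hs$habitat_tests$p[hs$habitat_tests$index == "abundance"]
  expect_equal(unname(p1), 1)
  sm <- hs$summary
  expect_equal(sm$mean[sm$index == "richness" & sm$level == "habitat" &
                         sm$group == "Reefs"], 2)
  # tiny groups report missing statistics
  hs2 <- habitat_summary(idx[1:3, ], dep[1:3, ])
  expect_true(is.na(hs2$habitat_tests$W[1]))
})

test_that("Kruskal-Wallis/Dunn pipeline detects a known habitat effect", {
  set.seed(11)
  n <- 40
  dep <- data.frame(deployment_id = sprintf("d%d", 1:(2 * n)),
                    habitat = rep(c("Reefs", "Sediments"), each = n),
                    subhabitat = rep(c("circalittoral rock",
                                       "subtidal sediments"), each = n))
  idx <- data.frame(deployment_id = dep$deployment_id,
                    richness = c(rpois(n, 7), rpois(n, 4)),
                    abundance = rpois(2 * n, 5), shannon = 1, biomass_kg = 1)
  hs <- habitat_summary(idx, dep)
  expect_lt(hs$habitat_tests$p[hs$habitat_tests$index == "richness"], 0.05)
  expect_lt(hs$subhabitat_tests$p[hs$subhabitat_tests$index == "richness"],
            0.05)
  d <- hs$dunn$richness
  expect_equal(nrow(d), 1)
  expect_lt(d$p_adj, 0.05)
})
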