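ann3 <- data.frame(
  deployment_id = "d01", time_s = c(60, 120, 180), taxon = "sp01",
  count = c(1L, 3L, 2L), length_mm = NA_real_, measurable = 0L)

test_that("annotation validation drops invariant-violating rows with warnings", {
  bad <- rbind(ann3,
               data.frame(deployment_id = "d01", time_s = 4000,
                          taxon = "sp01", count = 1L, length_mm = NA_real_,
                          measurable = 0L),
               data.frame(deployment_id = "d01", time_s = 300,
                          taxon = "sp01", count = 0L, length_mm = NA_real_,
                          measurable = 0L))
  expect_warning(v <- validate_annotations(bad), "dropped 2")
  expect_equal(nrow(v), 3)
  expect_equal(attr(v, "n_dropped"), 2)
  # synonym folding and vocabulary flagging
  syn <- validate_annotations(
    data.frame(deployment_id = "d", time_s = 1, taxon = "  SP  one ",
               count = 1L, length_mm = NA_real_, measurable = 0L),
    synonyms = c("sp one" = "sp01"))
  expect_equal(syn$taxon, "sp01")
  expect_warning(
    u <- validate_annotations(ann3, vocabulary = "other"),
    "unmatched")
  expect_true(all(u$unmatched))
})

test_that("read_annotations enforces schema and round-trips simulator output", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(ann3[, -4], f, row.names = FALSE)
  expect_error(read_annotations(f), "count")
  expect_error(read_annotations("no/such/file.csv"), "not found")

  sim <- simulate_annotations(toy_plan(10, seed = 5), species_pool(5),
                              n_frames = 8, seed = 3)
  dir <- withr::local_tempdir()
  files <- write_simulation(sim, dir)
  back <- read_annotations(files["annotations"])
  expect_equal(nrow(back), nrow(sim$annotations))
  expect_equal(back$count, sim$annotations$count)
  expect_equal(back$length_mm, sim$annotations$length_mm)
  dep <- read_deployments(files["deployments"])
  expect_equal(dep$deployment_id, sim$deployments$deployment_id)
})

test_that("compute_maxn: frame maxima, persistence, tie time, zero fill", {
  mx <- compute_maxn(ann3)
  expect_equal(unname(mx$maxn[1, 1]), 3L)
  expect_equal(unname(mx$maxn_time[1, 1]), 120)
  # one individual persisting over 10 frames counts once
  persist <- data.frame(deployment_id = "d01", time_s = seq(0, 540, 60),
                        taxon = "sp01", count = 1L)
  expect_equal(unname(compute_maxn(persist)$maxn[1, 1]), 1L)
  # rows at the same frame sum; earliest frame wins ties
  split2 <- data.frame(deployment_id = "d", time_s = c(60, 60, 120),
                       taxon = "a", count = c(2L, 1L, 3L))
  m2 <- compute_maxn(split2)
  expect_equal(unname(m2$maxn[1, 1]), 3L)
  expect_equal(unname(m2$maxn_time[1, 1]), 60)
  # absent deployments appear as all-zero rows
  m3 <- compute_maxn(ann3, deployments = c("d01", "d99"))
  expect_equal(unname(m3$maxn["d99", ]), 0L)
})

test_that("compute_maxn equals the brute-force oracle and ignores frame order", {
  set.seed(42)
  for (i in 1:20) {
    ann <- random_annotations(5, 8, 10)
    mx <- compute_maxn(ann)
    expect_equal(unname(mx$maxn), unname(brute_maxn(ann)))
    perm <- ann[sample.int(nrow(ann)), ]
    expect_equal(compute_maxn(perm)$maxn, mx$maxn)
    expect_equal(rowSums(compute_maxn(perm)$maxn), rowSums(mx$maxn))
  }
})

test_that("filter_demersal drops pelagic taxa and never increases cells", {
  pool <- species_pool(6)
  sim <- simulate_annotations(toy_plan(12, seed = 6), pool, n_frames = 6,
                              seed = 2)
  mx <- compute_maxn(validate_annotations(sim$annotations))
  dem <- filter_demersal(mx, pool)
  truth <- pool$taxon[pool$guild == "demersal"]
  expect_setequal(colnames(dem$maxn), intersect(colnames(mx$maxn), truth))
  expect_true(all(dem$maxn <= mx$maxn[, colnames(dem$maxn)]))
  # identity on an all-demersal table
  all_dem <- mx$maxn[, colnames(mx$maxn) %in% truth, drop = FALSE]
  expect_equal(dem$maxn, all_dem)
  expect_error(filter_demersal(mx, pool[-1, ]), "missing trait")
})
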