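#' Default end-to-end run configuration
#'
#' The stated synthetic world: a 10 x 10 km archipelago at 100-m cells,
#' 280 deployments stratified over the four sub-habitats (82 circalittoral
#' rock, 99 infralittoral rock, 24 seagrass, 75 sediments — the realised
#' stratum sizes of a temperate archipelago survey of this design), 200-m
#' minimum spacing, a 0-40 m depth envelope, 30 species, 60 scanned frames
#' per 60-min deployment, 200-m terrain buffers, r/VIF screen at 0.55/5,
#' 4-neighbour spatial lag, 1-km^2 hexagons, extrapolation to 1500 units
#' with 200 bootstrap replicates.
#'
#' @param seed root seed; each stage receives a child seed via
#'   [split_seed].
#' @param out_dir directory for the plain-text stage handoffs.
#' @return nested config list; edit fields before passing to
#'   [run_pipeline].
#' @export
default_config <- function(seed = 1, out_dir = tempfile("bruvkit_run_")) {
  list(
    seed = seed, out_dir = out_dir,
    stages = c(seascape = TRUE, design = TRUE, simulate = TRUE,
               ingest = TRUE, indices = TRUE, covariates = TRUE,
               spatial = TRUE, models = TRUE, rarefaction = TRUE),
    seascape = list(extent = c(0, 10000, 0, 10000), cell_size = 100,
                    n_islands = 3),
    design = list(n_per_stratum = c("circalittoral rock" = 82,
                                    "infralittoral rock" = 99,
                                    "subtidal seagrass" = 24,
                                    "subtidal sediments" = 75),
                  min_dist = 200, depth_range = c(0, 40)),
    simulate = list(n_species = 30, n_frames = 60),
    covariates = list(buffer_radius = 200),
    screen = list(r_max = 0.55, vif_max = 5),
    spatial = list(k_neighbours = 4, hex_area = 1e6),
    models = list(
      responses = list(
        richness = list(family = "poisson", include_year = TRUE),
        abundance = list(family = "nbinom", include_year = TRUE),
        biomass_kg = list(family = "gamma", include_year = FALSE)
      )
    ),
    rarefaction = list(t_max = 1500, B = 200)
  )
}

#' Run the full survey-analysis pipeline
#'
#' Executes the enabled stages in dependency order — seascape generation,
#' GRTS design, observation simulation, annotation ingest, ecological
#' indices, terrain covariates and collinearity screen, hexagonal
#' aggregation and spatial lag, GLM candidate-set ranking, rarefaction —
#' writing every intermediate table as delimited text (plus ASCII-grid
#' rasters and GeoJSON layers) under `config$out_dir`, and returns a
#' machine-readable run report. Any stage failure halts with the stage
#' name.
#'
#' @param config a [default_config]-shaped list.
#' @return list of class `bruv_report`: per-stage row counts, seeds,
#'   timing, warnings, headline statistics, and the in-memory stage
#'   outputs under `$objects`.
#' @export
run_pipeline <- function(config = default_config()) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(config$seed, 9L)
  names(seeds) <- c("seascape", "design", "simulate", "ingest", "indices",
                    "covariates", "spatial", "models", "rarefaction")
  report <- list(seed = config$seed, stage_seeds = as.list(seeds),
                 out_dir = config$out_dir, stages = list(), warnings = list())
  obj <- list()
  on_stage <- function(name) {
    if (!isTRUE(config$stages[[name]]))
      stop("stage '", name, "' is required but disabled in the config")
  }
  run_stage <- function(name, fn) {
    t1 <- Sys.time()
    wlog <- character(0)
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        wlog <<- c(wlog, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    report$stages[[name]] <<- c(res$info,
                                list(elapsed_s = round(as.numeric(
                                  difftime(Sys.time(), t1, units = "secs")), 3),
                                  n_warnings = length(wlog)))
    if (length(wlog)) report$warnings[[name]] <<- wlog
    res$value
  }

  on_stage("seascape")
  obj$seascape <- run_stage("seascape", function() {
    sc <- do.call(generate_seascape,
                  c(list(seed = seeds[["seascape"]]), config$seascape))
    write_ascii_grid(sc$bathymetry, file.path(config$out_dir, "bathymetry.asc"))
    write_ascii_grid(sc$habitat, file.path(config$out_dir, "habitat.asc"))
    write_geojson(sc$islands, file.path(config$out_dir, "islands.geojson"))
    list(value = sc, info = list(cells = prod(dim(sc$bathymetry))))
  })

  on_stage("design")
  obj$plan <- run_stage("design", function() {
    sc <- obj$seascape
    cells <- raster_cells(sc$bathymetry)
    frame <- data.frame(x = cells$x, y = cells$y,
                        stratum = sc$habitat_levels[as.vector(
                          raster_extract(sc$habitat, cells$x, cells$y))],
                        depth = cells$value)
    plan <- grts_sample(frame, config$design$n_per_stratum,
                        min_dist = config$design$min_dist,
                        depth_range = config$design$depth_range,
                        seed = seeds[["design"]])
    utils::write.csv(plan, file.path(config$out_dir, "plan.csv"),
                     row.names = FALSE)
    list(value = plan, info = list(n_sites = nrow(plan)))
  })

  on_stage("simulate")
  obj$sim <- run_stage("simulate", function() {
    plan <- obj$plan
    plan$subhabitat <- plan$stratum
    plan$remoteness_m <- remoteness(plan$x, plan$y, obj$seascape$islands)
    plan$year <- rep(c(2022L, 2023L), length.out = nrow(plan))
    pool <- species_pool(config$simulate$n_species, seed = seeds[["simulate"]])
    sim <- simulate_annotations(plan, pool,
                                n_frames = config$simulate$n_frames,
                                seed = seeds[["simulate"]])
    write_simulation(sim, config$out_dir)
    list(value = sim, info = list(n_annotations = nrow(sim$annotations),
                                  n_species = nrow(pool)))
  })

  on_stage("ingest")
  obj$maxn <- run_stage("ingest", function() {
    ann <- read_annotations(file.path(config$out_dir, "annotations.csv"),
                            vocabulary = obj$sim$pool$taxon)
    dep <- read_deployments(file.path(config$out_dir, "deployments.csv"))
    mx <- compute_maxn(ann, deployments = dep$deployment_id)
    dem <- filter_demersal(mx, obj$sim$pool)
    utils::write.csv(data.frame(deployment_id = rownames(dem$maxn),
                                dem$maxn, check.names = FALSE),
                     file.path(config$out_dir, "maxn_demersal.csv"),
                     row.names = FALSE)
    obj$annotations <<- ann; obj$deployments <<- dep
    list(value = list(all = mx, demersal = dem),
         info = list(n_taxa = ncol(mx$maxn),
                     n_demersal = ncol(dem$maxn)))
  })

  on_stage("indices")
  obj$indices <- run_stage("indices", function() {
    idx <- index_table(obj$maxn$demersal, obj$annotations, obj$deployments,
                       lw_registry(obj$sim$pool),
                       diversity_maxn = obj$maxn$all)
    utils::write.csv(idx, file.path(config$out_dir, "indices.csv"),
                     row.names = FALSE)
    hs <- habitat_summary(idx, obj$deployments)
    utils::write.csv(hs$summary, file.path(config$out_dir,
                                           "habitat_summary.csv"),
                     row.names = FALSE)
    obj$habitat_tests <<- hs
    list(value = idx, info = list(
      mean_richness = round(mean(idx$richness), 2),
      dispersion_richness = round(dispersion_index(idx$richness), 2),
      dispersion_abundance = round(dispersion_index(idx$abundance), 2)))
  })

  on_stage("covariates")
  obj$covariates <- run_stage("covariates", function() {
    cov <- covariate_table(obj$deployments, obj$seascape$bathymetry,
                           obj$seascape$islands,
                           buffer_radius = config$covariates$buffer_radius)
    scr <- collinearity_screen(
      cov[, c("depth_m", "sst_c", "relief", "slope_deg", "ruggedness_m",
              "exposure_deg", "remoteness_m")],
      r_max = config$screen$r_max, vif_max = config$screen$vif_max,
      auto_drop = TRUE)
    utils::write.csv(cov, file.path(config$out_dir, "covariates.csv"),
                     row.names = FALSE)
    obj$screen <<- scr
    list(value = cov, info = list(retained = paste(scr$retained,
                                                   collapse = ", ")))
  })

  on_stage("spatial")
  obj$hex <- run_stage("spatial", function() {
    idx <- obj$indices
    dep <- obj$deployments
    pts <- dep[match(idx$deployment_id, dep$deployment_id), c("x", "y")]
    hx <- hex_aggregate(pts, idx[, c("richness", "abundance", "shannon",
                                     "biomass_kg")],
                        cell_area = config$spatial$hex_area)
    utils::write.csv(hx, file.path(config$out_dir, "hex_grid.csv"),
                     row.names = FALSE)
    w <- knn_weights(pts, k = config$spatial$k_neighbours)
    write_weights(w, file.path(config$out_dir, "weights.csv"))
    obj$weights <<- w
    list(value = hx, info = list(n_cells = nrow(hx)))
  })

  on_stage("models")
  obj$models <- run_stage("models", function() {
    dep <- obj$deployments
    idx <- obj$indices
    cov <- obj$covariates
    dat <- cbind(idx,
                 cov[match(idx$deployment_id, cov$deployment_id),
                     setdiff(names(cov), c("deployment_id", "depth_m",
                                           "sst_c", "relief"))],
                 dep[match(idx$deployment_id, dep$deployment_id),
                     c("x", "y", "year", "habitat", "depth_m", "sst_c",
                       "relief")])
    preds <- intersect(obj$screen$retained,
                       c("depth_m", "sst_c", "relief", "exposure_deg",
                         "remoteness_m"))
    out <- list()
    for (resp in names(config$models$responses)) {
      mc <- config$models$responses[[resp]]
      d <- dat
      if (mc$family == "gamma") d <- d[d[[resp]] > 0, ]
      ms <- model_suite(d, resp, preds, mc$family,
                        k_neighbours = config$spatial$k_neighbours,
                        include_year = isTRUE(mc$include_year),
                        complex_terms = intersect(c("depth_m", "relief"),
                                                  preds))
      utils::write.csv(ms$ranking,
                       file.path(config$out_dir,
                                 paste0("ranking_", resp, ".csv")),
                       row.names = FALSE)
      out[[resp]] <- ms
    }
    info <- lapply(out, function(ms) ms$ranking$model[1])
    list(value = out, info = list(best = info))
  })

  on_stage("rarefaction")
  obj$rarefaction <- run_stage("rarefaction", function() {
    rc <- rarefaction_curve(obj$maxn$all, t_max = config$rarefaction$t_max,
                            B = config$rarefaction$B,
                            seed = seeds[["rarefaction"]])
    utils::write.csv(rc$all$curve, file.path(config$out_dir, "rarefaction.csv"),
                     row.names = FALSE)
    list(value = rc, info = list(asymptote = round(rc$all$asymptote, 1)))
  })

  report$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")), 2)
  report$objects <- obj
  class(report) <- "bruv_report"
  jsonlite::write_json(report[setdiff(names(report), "objects")],
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' @export
print.bruv_report <- function(x, ...) {
  cat(sprintf("<bruv_report> seed %d, %.1f s, stages: %s\n", x$seed,
              x$elapsed_s, paste(names(x$stages), collapse = " > ")))
  invisible(x)
}
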