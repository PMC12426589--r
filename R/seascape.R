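#' Derive reproducible child seeds from one root seed
#'
#' One root seed expands into per-stage seeds through a fixed splitting rule
#' so that every pipeline stage is independently reproducible: the root seed
#' initialises R's RNG once and `n` 31-bit integers are drawn.
#'
#' @param seed root integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# sub-habitat integer codes used in habitat rasters
SUBHABITATS <- c("circalittoral rock", "infralittoral rock",
                 "subtidal seagrass", "subtidal sediments")
subhab_main <- function(sub) ifelse(sub %in% SUBHABITATS[1:2], "Reefs", "Sediments")

# separable gaussian smoothing of a matrix (reflective edges); cheap
# stand-in for a gaussian random field with controllable length scale
smooth_field <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(-half:half, sd = sigma_cells)
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(1L, seq(1L - half, n + half)), n)
  conv_rows <- function(a) {
    ap <- a[pad_idx(nrow(a)), , drop = FALSE]
    out <- a
    for (i in seq_len(nrow(a))) {
      out[i, ] <- crossprod(k, ap[i:(i + 2L * half), , drop = FALSE])
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' Generate a synthetic seascape: bathymetry, habitats, islands
#'
#' Builds a seeded artificial archipelago on a square grid. Bathymetry is a
#' radial offshore gradient away from the island group plus smoothed
#' Gaussian noise with a controllable length scale, clamped to `[0, 60]` m.
#' A second smoothed noise field splits the seabed into rock and soft
#' sediment; depth then splits rock into infralittoral (shallow) versus
#' circalittoral (deep) and soft bottom into seagrass (shallow) versus bare
#' sediments, mirroring the sub-habitat strata of temperate MPA surveys.
#'
#' @param seed integer; all randomness derives from it.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size cell edge (m), > 0.
#' @param depth_amplitude amplitude of the noise component (m).
#' @param length_scale noise correlation length (m).
#' @param rock_depth_max infralittoral/circalittoral rock split depth (m).
#' @param seagrass_depth_max maximum seagrass depth (m).
#' @param n_islands number of inhabited-island points placed near the
#'   shallow core of the archipelago.
#' @return list of class `bruv_seascape`: `bathymetry` and `habitat`
#'   ([bruv_raster]; habitat coded 1:4 as `circalittoral rock`,
#'   `infralittoral rock`, `subtidal seagrass`, `subtidal sediments`),
#'   `islands` (data.frame `x`, `y`, `name`), `habitat_levels`, and the
#'   generating parameters.
#' @export
generate_seascape <- function(seed, extent = c(0, 10000, 0, 10000),
                              cell_size = 100,
                              depth_amplitude = 12, length_scale = 800,
                              rock_depth_max = 15, seagrass_depth_max = 8,
                              n_islands = 3) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent: need c(xmin, xmax, ymin, ymax) with positive spans")
  if (cell_size <= 0) stop("cell_size must be > 0")
  nc <- max(1L, round((extent[2] - extent[1]) / cell_size))
  nr <- max(1L, round((extent[4] - extent[3]) / cell_size))

  seeds <- split_seed(seed, 3L)
  cx <- (extent[1] + extent[2]) / 2
  cy <- (extent[3] + extent[4]) / 2
  xs <- extent[1] + (seq_len(nc) - 0.5) * cell_size
  ys <- extent[3] + (nr - seq_len(nr) + 0.5) * cell_size
  dist_c <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  max_d <- max(dist_c)

  set.seed(seeds[1])
  noise <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                        length_scale / cell_size)
  noise <- noise / max(stats::sd(noise), 1e-12)
  # offshore gradient: 0 m at the archipelago centre, ~50 m at the rim
  depth <- 50 * (dist_c / max_d)^1.2 + depth_amplitude * noise
  depth <- pmin(pmax(depth, 0), 60)

  set.seed(seeds[2])
  rockiness <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                            length_scale / cell_size)
  is_rock <- rockiness > stats::median(rockiness)
  habitat <- matrix(4L, nr, nc)                       # subtidal sediments
  habitat[!is_rock & depth <= seagrass_depth_max] <- 3L  # seagrass
  habitat[is_rock] <- 1L                              # circalittoral rock
  habitat[is_rock & depth <= rock_depth_max] <- 2L    # infralittoral rock

  set.seed(seeds[3])
  # islands sit in the shallow core
  ang <- stats::runif(n_islands, 0, 2 * pi)
  rad <- stats::runif(n_islands, 0.1 * max_d, 0.45 * max_d)
  islands <- data.frame(
    x = cx + rad * cos(ang), y = cy + rad * sin(ang),
    name = paste0("island_", seq_len(n_islands))
  )

  structure(list(
    bathymetry = bruv_raster(depth, extent[1], extent[3], cell_size),
    habitat = bruv_raster(habitat, extent[1], extent[3], cell_size),
    islands = islands,
    habitat_levels = SUBHABITATS,
    params = list(seed = seed, extent = extent, cell_size = cell_size,
                  depth_amplitude = depth_amplitude,
                  length_scale = length_scale,
                  rock_depth_max = rock_depth_max,
                  seagrass_depth_max = seagrass_depth_max)
  ), class = "bruv_seascape")
}

#' Ground-truth species pool for the synthetic observation process
#'
#' Returns the default 30-taxon pool used by the simulator, spanning
#' demersal teleosts, wrasses, benthic elasmobranchs, crustaceans and a few
#' pelagic shoalers. Each row records the parameters of the generating
#' model: habitat-affinity multipliers per sub-habitat, baseline
#' log-abundance, per-metre depth slopes on the log link (allowed to differ
#' between reef and sediment deployments), a negative-binomial size
#' parameter `k`, a zero-inflated hyperabundance mixture for shoaling taxa,
#' lognormal length parameters with depth/remoteness/exposure slopes on the
#' log scale, a measurability probability, and length-weight `a`, `b`.
#'
#' @param n_species pool size (recycled over the built-in archetypes).
#' @param seed seed for the per-taxon parameter jitter.
#' @return data.frame of class `species_truth`, one row per taxon.
#' @export
species_pool <- function(n_species = 30, seed = 20220601) {
  stopifnot(n_species >= 1)
  set.seed(split_seed(seed, 1L))
  # archetypes: reef teleost (pollack-like), wrasse, benthic elasmobranch
  # (catshark-like), crustacean, demersal shoaler (sand-eel-like; retained
  # by the demersal filter but responsible for rare hyperabundant counts),
  # and a pelagic shoaler that the demersal filter drops
  arche <- data.frame(
    guild = c("demersal", "demersal", "demersal", "demersal", "demersal",
              "pelagic"),
    group = c("teleost", "teleost", "elasmobranch", "crustacean", "teleost",
              "teleost"),
    # affinity multipliers: circalittoral, infralittoral, seagrass, sediments
    a1 = c(1.6, 1.0, 1.3, 1.2, 0.3, 1.0),
    a2 = c(1.0, 1.5, 0.8, 0.8, 0.3, 1.0),
    a3 = c(0.5, 0.8, 1.4, 0.6, 1.5, 1.0),
    a4 = c(0.4, 0.4, 0.6, 1.0, 2.0, 1.0),
    log_abund = c(-0.4, -0.8, -1.3, -1.6, -1.5, -2.0),
    depth_slope_reef = c(0.025, 0.015, 0.02, 0.01, 0.0, 0.0),
    depth_slope_sed = c(0.045, 0.025, 0.02, 0.02, 0.02, 0.0),
    nb_k = c(1.5, 1.0, 0.8, 0.6, 0.4, 0.3),
    shoaling = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    shoal_prob = c(0, 0, 0, 0, 0.12, 0.1),
    shoal_mult = c(1, 1, 1, 1, 120, 60),
    length_median = c(350, 180, 550, 120, 110, 150),
    length_sigma = c(0.25, 0.2, 0.15, 0.2, 0.12, 0.15),
    len_depth = c(0.008, -0.004, 0.003, -0.005, 0, 0),
    len_remote = c(4e-5, 3e-5, 1e-5, 0, 0, 0),
    len_expose = c(-8e-4, -5e-4, 0, 0, 0, 0),
    detectability = c(0.7, 0.6, 0.8, 0.5, 0.2, 0.3),
    lw_a = c(1.0e-5, 1.8e-5, 2.5e-6, 3.0e-4, 5.0e-6, 8.0e-6),
    lw_b = c(3.0, 3.05, 3.1, 2.7, 3.0, 3.1)
  )
  idx <- rep(seq_len(nrow(arche)), length.out = n_species)
  pool <- arche[idx, ]
  pool$taxon <- sprintf("%s_sp%02d", pool$group, seq_len(n_species))
  # mild per-taxon jitter so taxa are distinguishable but effects stay known
  pool$log_abund <- pool$log_abund + stats::rnorm(n_species, 0, 0.3)
  pool$length_median <- pool$length_median * exp(stats::rnorm(n_species, 0, 0.15))
  rownames(pool) <- pool$taxon
  pool <- pool[, c("taxon", setdiff(names(pool), "taxon"))]
  class(pool) <- c("species_truth", "data.frame")
  pool
}

#' Simulate frame-level BRUV annotations over a deployment plan
#'
#' The full observation process: for each deployment x taxon a latent true
#' MaxN is drawn from a log-linear negative-binomial model (baseline +
#' log habitat affinity + habitat-specific depth slope; shoaling taxa get a
#' hyperabundant multiplier with the stated mixture probability); frame
#' counts are then thinned binomially from the latent MaxN with one
#' uniformly chosen frame forced to the maximum, so the MaxN statistic is
#' exact by construction. Individuals at the MaxN frame receive lognormal
#' body lengths with the pool's depth/remoteness/exposure slopes and are
#' flagged measurable with the taxon's detectability.
#'
#' @param plan deployment plan: data.frame with `site_id`, `x`, `y`,
#'   `depth_m`, `subhabitat` (one of the four sub-habitat labels); optional
#'   `remoteness_m`, `exposure_deg` (default 0) feed the length model.
#' @param pool a [species_pool] data.frame.
#' @param n_frames frames scanned per deployment (>= 1).
#' @param seed integer seed.
#' @param frame_interval_s seconds between scanned frames.
#' @return list of class `bruv_simulation`: `annotations` (long table with
#'   columns `deployment_id`, `time_s`, `taxon`, `count`, `length_mm`,
#'   `measurable`), `deployments` (metadata table ready for
#'   [read_deployments] semantics), `latent_maxn` (deployment x taxon
#'   matrix of the generating MaxN), `mean_length` (same shape, generating
#'   mean lengths), and `pool`.
#' @export
simulate_annotations <- function(plan, pool, n_frames = 60, seed = 1,
                                 frame_interval_s = 60) {
  if (nrow(pool) == 0) stop("species pool is empty")
  stopifnot(n_frames >= 1)
  if (is.null(plan$remoteness_m)) plan$remoteness_m <- 0
  if (is.null(plan$exposure_deg)) plan$exposure_deg <- 0
  nD <- nrow(plan); nS <- nrow(pool)
  set.seed(split_seed(seed, 1L))

  sub_idx <- match(plan$subhabitat, SUBHABITATS)
  if (anyNA(sub_idx)) stop("plan contains unknown sub-habitat labels")
  is_reef <- sub_idx <= 2L
  aff <- as.matrix(pool[, c("a1", "a2", "a3", "a4")])

  latent <- matrix(0L, nD, nS, dimnames = list(plan$site_id, pool$taxon))
  mean_len <- matrix(NA_real_, nD, nS, dimnames = dimnames(latent))
  ann <- vector("list", nD * nS)
  times <- (seq_len(n_frames) - 1L) * frame_interval_s
  pos <- 0L
  for (s in seq_len(nS)) {
    sp <- pool[s, ]
    slope <- ifelse(is_reef, sp$depth_slope_reef, sp$depth_slope_sed)
    mu <- exp(sp$log_abund + log(aff[s, sub_idx]) + slope * plan$depth_m)
    shoal <- sp$shoaling & (stats::runif(nD) < sp$shoal_prob)
    mu <- mu * ifelse(shoal, sp$shoal_mult, 1)
    m <- stats::rnbinom(nD, size = sp$nb_k, mu = mu)
    latent[, s] <- m
    lmed <- log(sp$length_median) + sp$len_depth * plan$depth_m +
      sp$len_remote * plan$remoteness_m + sp$len_expose * plan$exposure_deg
    mean_len[, s] <- exp(lmed + sp$length_sigma^2 / 2)
    for (d in which(m > 0)) {
      M <- m[d]
      # binomial thinning conditional on the latent MaxN; one frame forced to M
      cnt <- stats::rbinom(n_frames, M, 0.5)
      cnt[sample.int(n_frames, 1L)] <- M
      keep <- cnt > 0L
      lens <- exp(stats::rnorm(M, lmed[d], sp$length_sigma))
      meas <- stats::runif(M) < sp$detectability
      # the MaxN frame carries per-individual rows (lengths); others carry
      # a single summed-count row with no length
      tmax <- times[which.max(cnt)]
      other <- keep & times != tmax
      pos <- pos + 1L
      ann[[pos]] <- data.frame(
        deployment_id = plan$site_id[d],
        time_s = c(rep(tmax, M), times[other]),
        taxon = sp$taxon,
        count = c(rep(1L, M), cnt[other]),
        length_mm = c(ifelse(meas, round(lens, 1), NA_real_),
                      rep(NA_real_, sum(other))),
        measurable = c(as.integer(meas), rep(0L, sum(other)))
      )
    }
  }
  annotations <- if (pos > 0) do.call(rbind, ann[seq_len(pos)]) else
    data.frame(deployment_id = character(), time_s = numeric(),
               taxon = character(), count = integer(),
               length_mm = numeric(), measurable = integer())
  ord <- order(annotations$deployment_id, annotations$time_s, annotations$taxon)
  annotations <- annotations[ord, ]
  rownames(annotations) <- NULL

  deployments <- data.frame(
    deployment_id = plan$site_id,
    x = plan$x, y = plan$y,
    year = if (is.null(plan$year)) 2022L else plan$year,
    gear = if (is.null(plan$gear)) "stereo" else plan$gear,
    depth_m = plan$depth_m,
    sst_c = if (is.null(plan$sst_c))
      round(14 + 1.5e-4 * (plan$y - min(plan$y)) + stats::rnorm(nD, 0, 0.6), 2)
    else plan$sst_c,
    relief = if (is.null(plan$relief)) pmin(5L, pmax(0L, as.integer(round(
      ifelse(is_reef, 3, 1) + stats::rnorm(nD, 0, 0.8))))) else plan$relief,
    habitat = subhab_main(plan$subhabitat),
    subhabitat = plan$subhabitat
  )

  structure(list(annotations = annotations, deployments = deployments,
                 latent_maxn = latent, mean_length = mean_len, pool = pool),
            class = "bruv_simulation")
}
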