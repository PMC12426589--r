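# Horn 3x3 finite-difference slope/aspect on a depth raster.
# Depth is positive-down; the surface differentiated is elevation = -depth,
# so aspect points down-elevation-gradient (downslope), the QGIS/Horn
# convention: 0 deg = north, 90 = east, 180 = south, 270 = west.
horn_gradients <- function(r) {
  z <- -r$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("raster too small for 3x3 terrain operators")
  pad <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  # map orientation: row-1 is north, columns increase eastwards
  dzdx <- ((pad[i - 1, j + 1] + 2 * pad[i, j + 1] + pad[i + 1, j + 1]) -
           (pad[i - 1, j - 1] + 2 * pad[i, j - 1] + pad[i + 1, j - 1])) /
    (8 * r$cellsize)
  dzdy <- ((pad[i - 1, j - 1] + 2 * pad[i - 1, j] + pad[i - 1, j + 1]) -
           (pad[i + 1, j - 1] + 2 * pad[i + 1, j] + pad[i + 1, j + 1])) /
    (8 * r$cellsize)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360  # downslope direction
  list(slope = slope, aspect = aspect)
}

#' Terrain statistics within a buffer around a point
#'
#' Slope and aspect are computed per cell with the Horn 3x3 operators (the
#' default of desktop-GIS raster terrain analysis) over the whole raster;
#' statistics are then taken over the cells whose centres fall inside the
#' circular buffer. Aspect is aggregated with the circular (vector) mean,
#' since arithmetic averaging is wrong at the 0/360 wrap. Ruggedness is the
#' depth range (max - min) within the buffer.
#'
#' @param bathy depth [bruv_raster] (m, positive down).
#' @param x,y point coordinates (m).
#' @param buffer_radius buffer radius (m).
#' @return list: `slope_mean_deg`, `ruggedness_m`, `aspect_deg` (circular
#'   mean, `NA` when the buffer is flat), `n_cells`.
#' @export
terrain_stats <- function(bathy, x, y, buffer_radius = 200) {
  g <- horn_gradients(bathy)
  cells <- raster_cells(bathy)
  inb <- (cells$x - x)^2 + (cells$y - y)^2 <= buffer_radius^2
  if (sum(inb) < 4) stop("buffer intersects fewer than 4 raster cells")
  sl <- g$slope[cbind(cells$row[inb], cells$col[inb])]
  asp <- g$aspect[cbind(cells$row[inb], cells$col[inb])]
  depth <- cells$value[inb]
  flat <- sl < 1e-9
  if (all(flat)) {
    aspect <- NA_real_
  } else {
    a <- asp[!flat] * pi / 180
    aspect <- (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
  }
  list(slope_mean_deg = mean(sl),
       ruggedness_m = max(depth) - min(depth),
       aspect_deg = aspect,
       n_cells = sum(inb))
}

#' Exposure: angular distance of the mean aspect from due west
#'
#' Circular absolute difference `min(|a - 270|, 360 - |a - 270|)` in
#' degrees, in `[0, 180]`: 0 when the seabed faces the prevailing westerly
#' swell exactly, 180 when it faces due east. (Survey write-ups sometimes
#' describe the far end as "lowest exposure"; this implementation fixes the
#' 0-at-west orientation and documents it, since only the ordering matters
#' to the models.)
#'
#' @param aspect_deg circular mean aspect in `[0, 360)`; `NA` propagates.
#' @return degrees from due west in `[0, 180]`.
#' @export
exposure <- function(aspect_deg) {
  d <- abs(aspect_deg %% 360 - 270)
  pmin(d, 360 - d)
}

#' Remoteness: minimum distance to an inhabited island
#'
#' Plain Euclidean minimum over island point geometries (island centroids)
#' in the projected plane; a proxy for cumulative human pressure.
#'
#' @param x,y point coordinates (m); vectorised.
#' @param islands data.frame with island `x`, `y` columns.
#' @return numeric vector of distances (m).
#' @export
remoteness <- function(x, y, islands) {
  if (is.null(islands) || nrow(islands) == 0) stop("empty islands layer")
  d2 <- outer(x, islands$x, `-`)^2 + outer(y, islands$y, `-`)^2
  sqrt(apply(d2, 1, min))
}

#' Assemble the per-deployment covariate table
#'
#' Depth, SST and relief come from deployment metadata (recorded in situ);
#' slope, ruggedness and exposure are derived from the bathymetry within a
#' buffer; remoteness from the islands layer.
#'
#' @param deployments deployment metadata data.frame.
#' @param bathy depth [bruv_raster].
#' @param islands island points data.frame.
#' @param buffer_radius terrain buffer (m).
#' @return data.frame keyed by `deployment_id`.
#' @export
covariate_table <- function(deployments, bathy, islands, buffer_radius = 200) {
  ts <- lapply(seq_len(nrow(deployments)), function(i)
    terrain_stats(bathy, deployments$x[i], deployments$y[i], buffer_radius))
  data.frame(
    deployment_id = deployments$deployment_id,
    depth_m = deployments$depth_m,
    sst_c = deployments$sst_c,
    relief = deployments$relief,
    slope_deg = vapply(ts, `[[`, numeric(1), "slope_mean_deg"),
    ruggedness_m = vapply(ts, `[[`, numeric(1), "ruggedness_m"),
    exposure_deg = exposure(vapply(ts, `[[`, numeric(1), "aspect_deg")),
    remoteness_m = remoteness(deployments$x, deployments$y, islands)
  )
}

#' Pearson / VIF collinearity screen
#'
#' Pairwise Pearson correlations (complete cases pairwise) and per-variable
#' variance inflation factors, VIF_j = 1 / (1 - R2_j) from regressing
#' variable j on the remaining variables. Variables exceeding either
#' threshold are flagged; flagging is advisory, with an optional auto-drop
#' that iteratively removes the flagged variable with the highest VIF until
#' all pass. A perfectly collinear variable reports `Inf`.
#'
#' @param covs data.frame of numeric candidate predictors.
#' @param r_max flag threshold on `|r|`.
#' @param vif_max flag threshold on VIF.
#' @param auto_drop if `TRUE`, iterate highest-VIF removal.
#' @return list: `correlations` matrix, `vif` named vector, `flagged`
#'   character vector, `retained` character vector, `dropped` (empty unless
#'   `auto_drop`).
#' @export
collinearity_screen <- function(covs, r_max = 0.55, vif_max = 5,
                                auto_drop = FALSE) {
  covs <- covs[, vapply(covs, is.numeric, logical(1)), drop = FALSE]
  stopifnot(ncol(covs) >= 2)
  vif_of <- function(df) {
    vapply(names(df), function(v) {
      others <- setdiff(names(df), v)
      fit <- stats::lm(stats::reformulate(others, v), data = df)
      r2 <- summary(fit)$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  cm <- stats::cor(covs, use = "pairwise.complete.obs")
  vif <- vif_of(covs)
  high_r <- unique(unlist(lapply(seq_len(ncol(cm)), function(i)
    rownames(cm)[abs(cm[, i]) > r_max & seq_len(nrow(cm)) != i])))
  flagged <- union(high_r, names(vif)[vif > vif_max])
  dropped <- character(0)
  keep <- names(covs)
  if (auto_drop) {
    df <- covs
    repeat {
      v <- vif_of(df)
      cr <- stats::cor(df, use = "pairwise.complete.obs")
      diag(cr) <- 0
      bad <- names(v)[v > vif_max | apply(abs(cr) > r_max, 1, any)]
      if (!length(bad) || ncol(df) <= 2) break
      worst <- bad[which.max(v[bad])]
      dropped <- c(dropped, worst)
      df <- df[, setdiff(names(df), worst), drop = FALSE]
    }
    keep <- names(df)
  }
  list(correlations = cm, vif = vif, flagged = flagged,
       retained = keep, dropped = dropped)
}
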