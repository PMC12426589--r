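# axial hex coordinates, flat-top orientation, side length s, origin at
# (x0, y0); cube-rounding gives the containing hexagon of each point
hex_axial <- function(x, y, s, x0 = 0, y0 = 0) {
  px <- (x - x0) / s; py <- (y - y0) / s
  q <- 2 / 3 * px
  r <- -1 / 3 * px + sqrt(3) / 3 * py
  # cube rounding
  xs <- q; zs <- r; ys <- -xs - zs
  rx <- round(xs); ry <- round(ys); rz <- round(zs)
  dx <- abs(rx - xs); dy <- abs(ry - ys); dz <- abs(rz - zs)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  data.frame(q = rx, r = rz)
}

hex_center <- function(q, r, s, x0 = 0, y0 = 0) {
  data.frame(x = x0 + s * 1.5 * q, y = y0 + s * sqrt(3) * (r + q / 2))
}

#' Aggregate point values on a hexagonal grid
#'
#' Flat-top hexagonal tessellation with the requested cell area (1 km^2 by
#' default), origin anchored at the minimum of the point extent so
#' placement is reproducible. Every point falls in exactly one cell; each
#' supplied value column is summarised by its unweighted per-cell mean.
#'
#' @param points data.frame with `x`, `y` (projected m).
#' @param values data.frame (or named list) of numeric columns aligned with
#'   `points`.
#' @param cell_area hexagon area in m^2.
#' @return data.frame: `cell_id`, axial `q`, `r`, cell-centre `x`, `y`,
#'   `n` points, and one mean column per value.
#' @export
hex_aggregate <- function(points, values, cell_area = 1e6) {
  stopifnot(cell_area > 0)
  s <- sqrt(2 * cell_area / (3 * sqrt(3)))
  x0 <- min(points$x); y0 <- min(points$y)
  ax <- hex_axial(points$x, points$y, s, x0, y0)
  key <- paste(ax$q, ax$r, sep = ":")
  cells <- unique(data.frame(q = ax$q, r = ax$r, key = key))
  cells <- cells[order(cells$q, cells$r), ]
  ctr <- hex_center(cells$q, cells$r, s, x0, y0)
  out <- data.frame(cell_id = seq_len(nrow(cells)), q = cells$q, r = cells$r,
                    x = ctr$x, y = ctr$y,
                    n = as.vector(table(key)[cells$key]))
  values <- as.data.frame(values)
  for (v in names(values)) {
    m <- tapply(values[[v]], key, mean, na.rm = TRUE)
    out[[paste0("mean_", v)]] <- as.vector(m[cells$key])
  }
  attr(out, "side_m") <- s
  out
}

#' k-nearest-neighbour spatial weights
#'
#' Row-standardised equal weights over each site's `k` nearest other sites
#' (Euclidean, projected plane). Ties in distance are broken
#' deterministically by site index.
#'
#' @param coords data.frame/matrix with `x`, `y`.
#' @param k neighbours per site (default 4).
#' @return object of class `knn_weights`: list `neighbours` (n x k integer
#'   matrix), `weights` (n x k, rows summing to 1), `n`, `k`.
#' @export
knn_weights <- function(coords, k = 4) {
  coords <- as.data.frame(coords)
  n <- nrow(coords)
  if (n <= k) stop("need more than k sites (n = ", n, ", k = ", k, ")")
  nb <- matrix(0L, n, k)
  d2 <- outer(coords$x, coords$x, `-`)^2 + outer(coords$y, coords$y, `-`)^2
  diag(d2) <- Inf
  for (i in seq_len(n)) nb[i, ] <- order(d2[i, ])[seq_len(k)]
  structure(list(neighbours = nb, weights = matrix(1 / k, n, k),
                 n = n, k = k), class = "knn_weights")
}

#' Spatially lagged value vector
#'
#' The equally weighted mean of the values at each site's `k` nearest other
#' sites: the spatially lagged dependent variable included as a predictor
#' to absorb residual spatial autocorrelation.
#'
#' @param coords data.frame with `x`, `y`, or a prebuilt [knn_weights] via
#'   `weights`.
#' @param values numeric response vector.
#' @param k neighbours (default 4).
#' @param weights optional [knn_weights] to reuse.
#' @return numeric lag vector.
#' @export
knn_lag <- function(coords, values, k = 4, weights = NULL) {
  w <- if (is.null(weights)) knn_weights(coords, k) else weights
  stopifnot(length(values) == w$n)
  rowSums(matrix(values[w$neighbours], w$n, w$k) * w$weights)
}

#' Moran's I with a permutation test
#'
#' I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centred
#' values and W the total weight. The p-value is two-sided on the
#' distribution of I under `n_perm` random permutations of the values over
#' sites (the observed arrangement counts as one permutation).
#'
#' @param values numeric vector (length >= 8 sites).
#' @param weights a [knn_weights] object.
#' @param n_perm number of permutations (>= 99 recommended; 999 default).
#' @param seed integer seed for the permutations.
#' @return list: `I`, `p_value`, `expected` (-1/(n-1)), `n_perm`.
#' @export
morans_i <- function(values, weights, n_perm = 999, seed = 1) {
  n <- weights$n
  stopifnot(length(values) == n, n >= 8)
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 < 1e-300) {
    warning("Moran's I undefined: zero-variance values")
    return(list(I = NA_real_, p_value = NA_real_,
                expected = -1 / (n - 1), n_perm = n_perm))
  }
  W <- sum(weights$weights)
  istat <- function(zz)
    (n / W) * sum(rowSums(matrix(zz[weights$neighbours], n, weights$k) *
                            weights$weights) * zz) / sum(zz^2)
  I <- istat(z)
  set.seed(split_seed(seed, 1L))
  perm <- vapply(seq_len(n_perm), function(b) istat(z[sample.int(n)]),
                 numeric(1))
  ge <- sum(abs(perm - mean(perm)) >= abs(I - mean(perm)))
  list(I = I, p_value = (ge + 1) / (n_perm + 1),
       expected = -1 / (n - 1), n_perm = n_perm)
}

#' Write kNN weights as a sparse triplet text file
#'
#' @param w a [knn_weights].
#' @param path output file (columns `site_i, site_j, weight`).
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  trip <- data.frame(site_i = rep(seq_len(w$n), w$k),
                     site_j = as.vector(w$neighbours),
                     weight = as.vector(w$weights))
  utils::write.csv(trip[order(trip$site_i, trip$site_j), ], path,
                   row.names = FALSE)
  invisible(path)
}
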