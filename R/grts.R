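#' Spatially balanced stratified site selection (GRTS on a cell frame)
#'
#' Generalized random tessellation stratified sampling over a discretised
#' sample frame. Each stratum's eligible cells (depth inside the envelope)
#' receive hierarchical quadrant-recursive base-4 addresses; the address
#' digits are scrambled with an independent random permutation per level and
#' sites are drawn in reverse-hierarchical order, which yields a spatially
#' balanced equal-probability sample. Candidates closer than `min_dist` to
#' an already accepted site (across the whole plan) are skipped and replaced
#' by the next address in order.
#'
#' @param frame data.frame of frame cells: columns `x`, `y` (cell centres,
#'   m), `stratum` (label), and `depth` (m, positive down) unless
#'   `depth_range` is `NULL`.
#' @param n_per_stratum named integer vector, e.g. `c(reef = 200, sediment
#'   = 100)`.
#' @param min_dist minimum pairwise distance between accepted sites (m).
#' @param depth_range length-2 numeric depth envelope (m) or `NULL` to skip
#'   depth screening.
#' @param seed integer seed; the plan is deterministic given it.
#' @return data.frame of class `deployment_plan` with columns `site_id`,
#'   `stratum`, `x`, `y`, `address` (base-4 digit string), `order_rank`,
#'   `depth_m`.
#' @export
grts_sample <- function(frame, n_per_stratum, min_dist = 0,
                        depth_range = NULL, seed = 1) {
  stopifnot(min_dist >= 0, all(n_per_stratum >= 1),
            !is.null(names(n_per_stratum)))
  if (!is.null(depth_range)) {
    stopifnot(length(depth_range) == 2)
    frame <- frame[!is.na(frame$depth) & frame$depth >= depth_range[1] &
                     frame$depth <= depth_range[2], ]
  }
  seeds <- split_seed(seed, length(n_per_stratum))
  acc_x <- numeric(0); acc_y <- numeric(0)
  out <- vector("list", length(n_per_stratum))
  for (i in seq_along(n_per_stratum)) {
    sname <- names(n_per_stratum)[i]
    n <- n_per_stratum[[i]]
    cells <- frame[frame$stratum == sname, ]
    if (nrow(cells) < n)
      stop(sprintf("stratum '%s': %d eligible cells for %d requested sites",
                   sname, nrow(cells), n))
    ord <- grts_order(cells$x, cells$y, n, seeds[i])
    cells <- cells[ord$idx, ]
    taken <- logical(nrow(cells))
    picked <- integer(0)
    for (j in seq_len(nrow(cells))) {
      if (length(picked) == n) break
      if (min_dist > 0 && length(acc_x)) {
        d2 <- (acc_x - cells$x[j])^2 + (acc_y - cells$y[j])^2
        if (any(d2 < min_dist^2)) next
      }
      picked <- c(picked, j)
      acc_x <- c(acc_x, cells$x[j]); acc_y <- c(acc_y, cells$y[j])
    }
    if (length(picked) < n)
      stop(sprintf(
        "stratum '%s': infeasible request, only %d of %d sites placeable at min_dist %g m",
        sname, length(picked), n, min_dist))
    sel <- cells[picked, ]
    out[[i]] <- data.frame(
      site_id = sprintf("%s_%03d", sname, seq_len(n)),
      stratum = sname, x = sel$x, y = sel$y,
      address = ord$address[ord$idx][picked],
      order_rank = picked,
      depth_m = if (is.null(sel$depth)) NA_real_ else sel$depth
    )
  }
  plan <- do.call(rbind, out)
  rownames(plan) <- NULL
  class(plan) <- c("deployment_plan", "data.frame")
  plan
}

# hierarchical quadrant-recursive randomized ordering of frame cells.
# Returns the visit order (reverse-hierarchical) and each cell's scrambled
# base-4 address string.
grts_order <- function(x, y, n, seed) {
  set.seed(seed)
  nlev <- 1L
  while (4^nlev < 4 * n) nlev <- nlev + 1L
  xr <- range(x); yr <- range(y)
  # half-open binning across nlev dyadic levels
  fx <- (x - xr[1]) / max(xr[2] - xr[1], 1e-9) * (1 - 1e-12)
  fy <- (y - yr[1]) / max(yr[2] - yr[1], 1e-9) * (1 - 1e-12)
  digits <- matrix(0L, length(x), nlev)
  for (l in seq_len(nlev)) {
    bx <- as.integer(floor(fx * 2^l)) %% 2L
    by <- as.integer(floor(fy * 2^l)) %% 2L
    raw <- 2L * by + bx                      # quadrant index 0..3
    perm <- sample.int(4L) - 1L              # independent permutation per level
    digits[, l] <- perm[raw + 1L]
  }
  addr_num <- as.vector(digits %*% 4^(nlev - seq_len(nlev)))
  # reverse-hierarchical order: sort by digits read last level first;
  # cells sharing a max-level address are cycled (one per address per
  # pass) so consecutive draws stay spatially spread
  rev_num <- as.vector(digits %*% 4^(seq_len(nlev) - 1L))
  tie <- stats::runif(length(x))
  pass <- stats::ave(tie, rev_num, FUN = rank)
  idx <- order(pass, rev_num, tie)
  addr <- apply(digits, 1L, paste0, collapse = "")
  list(idx = idx, address = addr, address_num = addr_num)
}

#' Voronoi balance diagnostic for a deployment plan
#'
#' Assigns every frame cell to its nearest site and returns the variance of
#' the per-site totals of inclusion mass (cell counts, or a `mass` column if
#' present). 0 indicates a perfectly even spatial partition; larger values
#' indicate clustering. Single-site plans return 0 by convention.
#'
#' @param plan a [grts_sample] plan (needs `x`, `y`).
#' @param frame the sample frame the plan was drawn from (`x`, `y`,
#'   optional `mass`).
#' @return non-negative number.
#' @export
balance_metric <- function(plan, frame) {
  stopifnot(nrow(plan) >= 1)
  if (nrow(plan) == 1) return(0)
  mass <- if (is.null(frame$mass)) rep(1, nrow(frame)) else frame$mass
  d2 <- outer(frame$x, plan$x, `-`)^2 + outer(frame$y, plan$y, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  tot <- as.vector(tapply(mass, factor(nearest, levels = seq_len(nrow(plan))),
                          sum, default = 0))
  stats::var(tot)
}

#' Uniform-random comparison sampler over the same frame
#'
#' Baseline sampler for balance comparisons: simple random sampling of
#' frame cells without replacement, no spatial structure.
#'
#' @inheritParams grts_sample
#' @return a plan data.frame with the same columns as [grts_sample].
#' @export
srs_sample <- function(frame, n_per_stratum, seed = 1) {
  seeds <- split_seed(seed, length(n_per_stratum))
  out <- lapply(seq_along(n_per_stratum), function(i) {
    sname <- names(n_per_stratum)[i]
    cells <- frame[frame$stratum == sname, ]
    set.seed(seeds[i])
    sel <- cells[sample.int(nrow(cells), n_per_stratum[[i]]), ]
    data.frame(site_id = sprintf("%s_%03d", sname, seq_len(nrow(sel))),
               stratum = sname, x = sel$x, y = sel$y,
               address = NA_character_, order_rank = seq_len(nrow(sel)),
               depth_m = if (is.null(sel$depth)) NA_real_ else sel$depth)
  })
  plan <- do.call(rbind, out)
  rownames(plan) <- NULL
  plan
}
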