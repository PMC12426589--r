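# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles are deliberately naive (nested loops, exhaustive
# enumeration) and never reuse package internals beyond plain data access.

# nested-loop MaxN: max over frames of summed counts per deployment x taxon
brute_maxn <- function(ann) {
  deps <- sort(unique(ann$deployment_id))
  taxa <- sort(unique(ann$taxon))
  out <- matrix(0L, length(deps), length(taxa), dimnames = list(deps, taxa))
  for (d in deps) for (tx in taxa) {
    sub <- ann[ann$deployment_id == d & ann$taxon == tx, ]
    if (!nrow(sub)) next
    best <- 0L
    for (tt in unique(sub$time_s)) {
      s <- sum(sub$count[sub$time_s == tt])
      if (s > best) best <- s
    }
    out[d, tx] <- best
  }
  out
}

# random frame-level annotation table
random_annotations <- function(n_dep, n_tax, n_frames, p = 0.2,
                               max_count = 4) {
  deps <- sprintf("d%02d", seq_len(n_dep))
  taxa <- sprintf("sp%02d", seq_len(n_tax))
  rows <- expand.grid(deployment_id = deps, time_s = seq_len(n_frames) * 30,
                      taxon = taxa, stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < p, ]
  if (!nrow(rows)) rows <- data.frame(deployment_id = deps[1], time_s = 30,
                                      taxon = taxa[1])
  rows$count <- sample.int(max_count, nrow(rows), replace = TRUE)
  rows$length_mm <- NA_real_
  rows$measurable <- 0L
  rows
}

# exhaustive-subset rarefaction: mean richness over all size-t subsets of
# the rows of a presence matrix
enum_rarefy <- function(pres, t) {
  subs <- combn(nrow(pres), t)
  mean(apply(subs, 2, function(ix)
    sum(colSums(pres[ix, , drop = FALSE]) > 0)))
}

# square grid sample frame, one stratum
grid_frame <- function(n_side, cellsize = 100, stratum = "s",
                       depth = 10) {
  g <- expand.grid(col = seq_len(n_side), row = seq_len(n_side))
  data.frame(x = (g$col - 0.5) * cellsize, y = (g$row - 0.5) * cellsize,
             stratum = stratum, depth = depth)
}

# a small deployment plan on a grid, mixed sub-habitats
toy_plan <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    site_id = sprintf("d%03d", seq_len(n)),
    x = runif(n, 0, 5000), y = runif(n, 0, 5000),
    depth_m = runif(n, 2, 38),
    subhabitat = sample(c("circalittoral rock", "infralittoral rock",
                          "subtidal seagrass", "subtidal sediments"),
                        n, replace = TRUE)
  )
}
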