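#' Per-deployment species richness
#'
#' Number of taxa with MaxN >= 1 in one deployment.
#'
#' @param maxn_row named numeric/integer vector of MaxN values.
#' @return integer count.
#' @export
richness <- function(maxn_row) sum(maxn_row >= 1, na.rm = TRUE)

#' Shannon diversity (natural log)
#'
#' H' = -sum p_i log p_i with p_i the MaxN share of taxon i; zero entries
#' are excluded. Natural-log units (nats), matching the conventional
#' community-ecology default. An all-zero row has no defined value and
#' returns `NA` with a warning.
#'
#' @param maxn_row named numeric vector of MaxN values.
#' @return H' in nats.
#' @export
shannon <- function(maxn_row) {
  tot <- sum(maxn_row, na.rm = TRUE)
  if (tot <= 0) {
    warning("Shannon index undefined for an all-zero deployment")
    return(NA_real_)
  }
  p <- maxn_row[!is.na(maxn_row) & maxn_row > 0] / tot
  -sum(p * log(p))
}

#' Variance-to-mean dispersion index
#'
#' ~1 for Poisson counts; values well above 1 indicate overdispersion and
#' motivate a negative-binomial error model.
#'
#' @param values numeric vector, or a pre-computed `c(mean, variance)` pair
#'   via `mean_var`.
#' @param mean_var optional length-2 numeric `c(mean, variance)` overriding
#'   `values`.
#' @return variance / mean; `NA` with a warning when the mean is zero.
#' @export
dispersion_index <- function(values = NULL, mean_var = NULL) {
  if (!is.null(mean_var)) {
    m <- mean_var[1]; v <- mean_var[2]
  } else {
    m <- mean(values, na.rm = TRUE); v <- stats::var(values, na.rm = TRUE)
  }
  if (is.na(m) || m == 0) {
    warning("dispersion index undefined: zero mean")
    return(NA_real_)
  }
  v / m
}

PROXY_TIERS <- c("measured-in-sample", "subhabitat-mean", "study-mean",
                 "reference", "family-mean")

#' Resolve a mean body length through the proxy cascade
#'
#' Picks the mean length used for a taxon's biomass in one deployment by
#' the first applicable rule: (1) mean of the accepted measurements of that
#' taxon in this deployment; (2) pooled mean of all its measurements within
#' the same sub-habitat across the study; (3) study-wide species mean;
#' (4) a registry reference length. Family-level taxa (flagged in the
#' registry) resolve to the study-level family mean. Mono-gear deployments
#' skip tier 1 (no stereo measurements are trusted from them).
#'
#' @param taxon taxon name.
#' @param deployment deployment id.
#' @param lengths measured-length table: data.frame `deployment_id`,
#'   `taxon`, `length_mm`, `subhabitat` (accepted measurements only).
#' @param subhabitat the deployment's sub-habitat label.
#' @param registry length-weight registry ([lw_registry]); its
#'   `ref_length_mm` column feeds tier 4 and `family` feeds family means.
#' @param gear `"stereo"` or `"mono"`.
#' @return list: `length_mm`, `tier` (`measured-in-sample`,
#'   `subhabitat-mean`, `study-mean`, `reference`, or `family-mean`), and
#'   `n`, the number of measurements behind the value.
#' @export
resolve_length <- function(taxon, deployment, lengths, subhabitat,
                           registry, gear = "stereo") {
  own <- lengths$taxon == taxon
  reg <- registry[match(taxon, registry$taxon), ]
  if (!is.na(reg$taxon) && isTRUE(reg$is_family)) {
    fam <- registry$taxon[!is.na(registry$family) & registry$family == taxon &
                            !isTRUE(registry$is_family)]
    v <- lengths$length_mm[lengths$taxon %in% c(taxon, fam)]
    if (length(v))
      return(list(length_mm = mean(v), tier = "family-mean", n = length(v)))
  }
  if (gear != "mono") {
    v <- lengths$length_mm[own & lengths$deployment_id == deployment]
    if (length(v))
      return(list(length_mm = mean(v), tier = "measured-in-sample",
                  n = length(v)))
  }
  v <- lengths$length_mm[own & lengths$subhabitat == subhabitat]
  if (length(v))
    return(list(length_mm = mean(v), tier = "subhabitat-mean", n = length(v)))
  v <- lengths$length_mm[own]
  if (length(v))
    return(list(length_mm = mean(v), tier = "study-mean", n = length(v)))
  if (!is.na(reg$taxon) && !is.na(reg$ref_length_mm))
    return(list(length_mm = reg$ref_length_mm, tier = "reference", n = 0L))
  stop("no length resolution possible for taxon '", taxon,
       "': never measured and no registry reference length")
}

#' Length-weight registry from a species pool or a delimited file
#'
#' Registry columns: `taxon`, `a` (g per mm^b), `b`, `ref_length_mm`,
#' `length_type`, `family`, `is_family`. `a` and `b` are the power-law
#' coefficients of W = a L^b with L in mm and W in g.
#'
#' @param pool a [species_pool]; its `lw_a`, `lw_b` and median lengths
#'   become the registry (reference length = lognormal median).
#' @return data.frame registry.
#' @export
lw_registry <- function(pool) {
  data.frame(
    taxon = pool$taxon, a = pool$lw_a, b = pool$lw_b,
    ref_length_mm = pool$length_median,
    length_type = ifelse(pool$group == "crustacean", "carapace", "total"),
    family = pool$group, is_family = FALSE
  )
}

#' Deployment biomass from MaxN and resolved lengths
#'
#' sum over taxa of a L^b MaxN, g converted to kg; L is the resolved mean
#' length in mm.
#'
#' @param maxn_row named MaxN vector for one deployment.
#' @param resolutions named list of [resolve_length] results for every
#'   positive-MaxN taxon.
#' @param registry [lw_registry] table.
#' @return biomass in kg.
#' @export
biomass <- function(maxn_row, resolutions, registry) {
  present <- names(maxn_row)[!is.na(maxn_row) & maxn_row > 0]
  if (!length(present)) return(0)
  miss <- setdiff(present, registry$taxon)
  if (length(miss)) stop("no length-weight entry for: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(present, names(resolutions))
  if (length(miss)) stop("no length resolution for: ",
                         paste(miss, collapse = ", "))
  g <- vapply(present, function(tx) {
    reg <- registry[match(tx, registry$taxon), ]
    L <- resolutions[[tx]]$length_mm
    reg$a * L^reg$b * maxn_row[[tx]]
  }, numeric(1))
  sum(g) / 1000
}

#' Build the per-deployment index table
#'
#' Computes richness, relative abundance (summed MaxN), Shannon H' and
#' total biomass for every deployment, resolving lengths through the proxy
#' cascade and tallying which tier served each taxon. Following common
#' BRUV practice, diversity can be computed on the full assemblage while
#' richness/abundance/biomass use a demersal subset: pass the subset
#' switches explicitly.
#'
#' @param maxn a `maxn_table` (typically demersal-filtered for richness/
#'   abundance/biomass).
#' @param annotations validated annotations carrying the length records.
#' @param deployments deployment metadata data.frame.
#' @param registry [lw_registry].
#' @param diversity_maxn optional unfiltered `maxn_table` for Shannon
#'   (defaults to `maxn`).
#' @return data.frame `deployment_id, richness, abundance, shannon,
#'   biomass_kg` plus one `tier_*` count column per proxy tier;
#'   attribute `resolutions` keeps the per-taxon detail.
#' @export
index_table <- function(maxn, annotations, deployments, registry,
                        diversity_maxn = maxn) {
  lengths <- annotations[!is.na(annotations$length_mm) &
                           annotations$measurable == 1, ]
  lengths$subhabitat <- deployments$subhabitat[
    match(lengths$deployment_id, deployments$deployment_id)]
  dep <- rownames(maxn$maxn)
  gear <- deployments$gear[match(dep, deployments$deployment_id)]
  gear[is.na(gear)] <- "stereo"
  tiers <- matrix(0L, length(dep), length(PROXY_TIERS),
                  dimnames = list(dep, paste0("tier_", gsub("-", "_", PROXY_TIERS))))
  res_all <- vector("list", length(dep)); names(res_all) <- dep
  bio <- numeric(length(dep))
  for (i in seq_along(dep)) {
    row <- maxn$maxn[i, ]
    present <- names(row)[row > 0]
    subhab <- deployments$subhabitat[match(dep[i], deployments$deployment_id)]
    res <- lapply(present, function(tx)
      resolve_length(tx, dep[i], lengths, subhab, registry, gear = gear[i]))
    names(res) <- present
    for (r in res) {
      j <- match(r$tier, PROXY_TIERS)
      tiers[i, j] <- tiers[i, j] + 1L
    }
    res_all[[i]] <- res
    bio[i] <- biomass(row, res, registry)
  }
  div <- suppressWarnings(apply(diversity_maxn$maxn[dep, , drop = FALSE], 1, shannon))
  out <- data.frame(
    deployment_id = dep,
    richness = apply(maxn$maxn, 1, richness),
    abundance = rowSums(maxn$maxn),
    shannon = div,
    biomass_kg = bio
  )
  out <- cbind(out, as.data.frame(tiers))
  rownames(out) <- NULL
  attr(out, "resolutions") <- res_all
  out
}

# Dunn's post hoc test on Kruskal-Wallis ranks with tie correction and
# Bonferroni adjustment; returns one row per group pair.
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  ng <- tapply(r, groups, length)
  mr <- tapply(r, groups, mean)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[[a]] + 1 / ng[[b]]))
    z[j] <- (mr[[a]] - mr[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_adj = pmin(1, stats::p.adjust(p, method = p_adjust)))
}

#' Habitat and sub-habitat contrasts of the ecological indices
#'
#' Grouped mean and SD per main habitat and sub-habitat for each index,
#' plus the nonparametric contrasts: Mann-Whitney U between the two main
#' habitats, Kruskal-Wallis across sub-habitats, and Dunn pairwise post hoc
#' tests with Bonferroni adjustment. Groups with fewer than two
#' deployments get `NA` statistics.
#'
#' @param indices an [index_table] result.
#' @param deployments deployment metadata with `habitat`, `subhabitat`.
#' @param vars index columns to summarise.
#' @return list: `summary` (grouped mean/SD long table), `habitat_tests`
#'   (Mann-Whitney W and p per index), `subhabitat_tests` (Kruskal-Wallis H
#'   and p), `dunn` (pairwise table per index).
#' @export
habitat_summary <- function(indices, deployments,
                            vars = c("richness", "abundance", "shannon",
                                     "biomass_kg")) {
  m <- match(indices$deployment_id, deployments$deployment_id)
  if (anyNA(m)) stop("unlabelled deployments: ",
                     paste(indices$deployment_id[is.na(m)], collapse = ", "))
  hab <- deployments$habitat[m]
  sub <- deployments$subhabitat[m]
  summ <- do.call(rbind, lapply(vars, function(v) {
    x <- indices[[v]]
    grp <- function(g, label) data.frame(
      index = v, level = label, group = names(tapply(x, g, mean)),
      mean = as.vector(tapply(x, g, mean, na.rm = TRUE)),
      sd = as.vector(tapply(x, g, stats::sd, na.rm = TRUE)),
      n = as.vector(tapply(x, g, length)))
    rbind(grp(hab, "habitat"), grp(sub, "subhabitat"))
  }))
  rownames(summ) <- NULL
  ht <- do.call(rbind, lapply(vars, function(v) {
    x <- indices[[v]]; ok <- !is.na(x)
    if (length(unique(hab[ok])) == 2 && all(table(hab[ok]) >= 2)) {
      w <- suppressWarnings(stats::wilcox.test(x[ok] ~ hab[ok]))
      # all-tied data degenerates the normal approximation; identical
      # exchangeable groups carry no evidence, so report p = 1
      pv <- if (is.nan(w$p.value) && stats::var(x[ok]) == 0) 1 else w$p.value
      data.frame(index = v, W = unname(w$statistic), p = pv)
    } else data.frame(index = v, W = NA_real_, p = NA_real_)
  }))
  st <- do.call(rbind, lapply(vars, function(v) {
    x <- indices[[v]]; ok <- !is.na(x)
    if (length(unique(sub[ok])) >= 2 && all(table(sub[ok]) >= 2)) {
      k <- stats::kruskal.test(x[ok], factor(sub[ok]))
      data.frame(index = v, H = unname(k$statistic), p = k$p.value)
    } else data.frame(index = v, H = NA_real_, p = NA_real_)
  }))
  dn <- lapply(stats::setNames(vars, vars), function(v) {
    x <- indices[[v]]; ok <- !is.na(x)
    if (length(unique(sub[ok])) >= 2 && all(table(sub[ok]) >= 2))
      dunn_test(x[ok], sub[ok]) else NULL
  })
  list(summary = summ, habitat_tests = ht, subhabitat_tests = st, dunn = dn)
}
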