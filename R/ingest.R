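#' Read and validate a frame-level annotation table
#'
#' Reads an EventMeasure-export-like delimited text file with columns
#' `deployment_id, time_s, taxon, count, length_mm, measurable`
#' (comma-separated, header row, UTF-8). Rows violating the record
#' invariants are dropped with row-numbered warnings: time offsets outside
#' the standardised 60-min window (`time_s` outside `[0, 3600]`), `count <
#' 1`, or non-positive lengths. Taxon names are normalised (case and
#' whitespace folding) and optionally mapped through a synonym table;
#' names absent from a supplied vocabulary are passed through flagged
#' `unmatched` with a warning.
#'
#' @param path file path.
#' @param synonyms optional named character vector mapping alternate names
#'   to canonical taxa.
#' @param vocabulary optional character vector of accepted taxon names.
#' @return data.frame of validated annotation records with an `unmatched`
#'   logical column; attribute `n_dropped` records rejected row count.
#' @export
read_annotations <- function(path, synonyms = NULL, vocabulary = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("deployment_id", "time_s", "taxon", "count")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("annotation schema error, missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(raw$length_mm)) raw$length_mm <- NA_real_
  if (is.null(raw$measurable)) raw$measurable <- 0L
  validate_annotations(raw, synonyms = synonyms, vocabulary = vocabulary)
}

#' @rdname read_annotations
#' @param annotations in-memory data.frame with the same columns.
#' @export
validate_annotations <- function(annotations, synonyms = NULL,
                                 vocabulary = NULL) {
  a <- annotations
  a$taxon <- tolower(gsub("\\s+", " ", trimws(a$taxon)))
  if (!is.null(synonyms)) {
    hit <- match(a$taxon, tolower(names(synonyms)))
    a$taxon[!is.na(hit)] <- tolower(synonyms[hit[!is.na(hit)]])
  }
  bad_time <- is.na(a$time_s) | a$time_s < 0 | a$time_s > 3600
  bad_count <- is.na(a$count) | a$count < 1
  bad_len <- !is.na(a$length_mm) & a$length_mm <= 0
  bad <- bad_time | bad_count | bad_len
  if (any(bad)) {
    warning(sprintf("dropped %d invalid annotation row(s): %s", sum(bad),
                    paste(utils::head(which(bad), 10), collapse = ", ")))
    a <- a[!bad, ]
  }
  a$count <- as.integer(a$count)
  a$unmatched <- FALSE
  if (!is.null(vocabulary)) {
    a$unmatched <- !(a$taxon %in% tolower(vocabulary))
    if (any(a$unmatched))
      warning("unknown taxa flagged unmatched: ",
              paste(unique(a$taxon[a$unmatched]), collapse = ", "))
  }
  rownames(a) <- NULL
  attr(a, "n_dropped") <- sum(bad)
  a
}

#' Read deployment metadata
#'
#' Columns: `deployment_id, x, y, year, gear, depth_m, sst_c, relief,
#' habitat, subhabitat`. Relief must lie in 0..5 and sub-habitat must be
#' consistent with the main habitat (rock sub-habitats under Reefs).
#'
#' @param path delimited text file.
#' @return validated data.frame.
#' @export
read_deployments <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("deployment_id", "x", "y", "depth_m", "habitat", "subhabitat")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("deployment schema error, missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(d$relief) && any(!d$relief %in% 0:5, na.rm = TRUE))
    stop("relief scores must be integers in 0..5")
  ok <- subhab_main(d$subhabitat) == d$habitat
  if (any(!ok, na.rm = TRUE))
    stop("sub-habitat inconsistent with habitat for: ",
         paste(d$deployment_id[!ok], collapse = ", "))
  d
}

#' Compute the MaxN table from validated annotations
#'
#' MaxN for a deployment x taxon is the maximum over frames of the summed
#' count at that frame — the standard BRUV relative-abundance statistic
#' that avoids double counting individuals present across many frames.
#' Also records, per cell, the time of the frame at which the maximum
#' occurred (earliest frame on ties; used downstream to select length
#' measurements).
#'
#' @param annotations validated annotation data.frame
#'   ([read_annotations]).
#' @param deployments optional vector of deployment ids to force into the
#'   table (zero rows for deployments with no records).
#' @return object of class `maxn_table`: list with `maxn` (integer matrix,
#'   deployments x taxa, absent taxa 0), `maxn_time` (matrix of frame
#'   times, `NA` where MaxN is 0).
#' @export
compute_maxn <- function(annotations, deployments = NULL) {
  a <- annotations
  dep <- sort(unique(c(as.character(a$deployment_id), deployments)))
  tax <- sort(unique(a$taxon))
  mx <- matrix(0L, length(dep), length(tax), dimnames = list(dep, tax))
  mt <- matrix(NA_real_, length(dep), length(tax), dimnames = list(dep, tax))
  if (nrow(a)) {
    frame_sum <- stats::aggregate(
      count ~ deployment_id + taxon + time_s, data = a, FUN = sum)
    # earliest frame among those attaining the per-cell maximum
    frame_sum <- frame_sum[order(frame_sum$deployment_id, frame_sum$taxon,
                                 -frame_sum$count, frame_sum$time_s), ]
    first <- !duplicated(frame_sum[, c("deployment_id", "taxon")])
    best <- frame_sum[first, ]
    idx <- cbind(match(as.character(best$deployment_id), dep),
                 match(best$taxon, tax))
    mx[idx] <- as.integer(best$count)
    mt[idx] <- best$time_s
  }
  structure(list(maxn = mx, maxn_time = mt), class = "maxn_table")
}

#' @export
print.maxn_table <- function(x, ...) {
  cat(sprintf("<maxn_table> %d deployments x %d taxa, total MaxN %d\n",
              nrow(x$maxn), ncol(x$maxn), sum(x$maxn)))
  invisible(x)
}

#' Subset a MaxN table to demersal- and benthic-associated taxa
#'
#' Drops pelagic-flagged taxa using a trait table. Reef/seabed-associated
#' shoalers stay in if their trait entry says `demersal`; the decision
#' lives in the trait data, not in code.
#'
#' @param maxn a [compute_maxn] result.
#' @param traits data.frame with columns `taxon` and `guild`
#'   (`"demersal"` or `"pelagic"`); a [species_pool] works directly.
#' @return a `maxn_table` restricted to demersal taxa.
#' @export
filter_demersal <- function(maxn, traits) {
  tax <- colnames(maxn$maxn)
  hit <- match(tax, tolower(traits$taxon))
  if (anyNA(hit))
    stop("missing trait entries for: ", paste(tax[is.na(hit)], collapse = ", "))
  keep <- traits$guild[hit] == "demersal"
  structure(list(maxn = maxn$maxn[, keep, drop = FALSE],
                 maxn_time = maxn$maxn_time[, keep, drop = FALSE]),
            class = "maxn_table")
}

#' Write / read the simulator's tables as delimited text
#'
#' @param sim a [simulate_annotations] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "annotations.csv")
  fd <- file.path(dir, "deployments.csv")
  utils::write.csv(sim$annotations, fa, row.names = FALSE, na = "")
  utils::write.csv(sim$deployments, fd, row.names = FALSE, na = "")
  invisible(c(annotations = fa, deployments = fd))
}
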