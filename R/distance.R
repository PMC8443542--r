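BASES <- c("A", "C", "G", "T")

#' Pairwise p-distance matrix with pairwise deletion
#'
#' For every pair of aligned sequences, the compared sites are the
#' positions where both rows carry an unambiguous base (A, C, G or T,
#' case-insensitive); gaps and IUPAC ambiguity codes are excluded pair by
#' pair (pairwise deletion). The p-distance is the proportion of compared
#' sites that differ; pairs with zero compared sites get a missing
#' distance.
#'
#' @param aln An [msa] with at least two rows.
#' @return A list of class `p_dist` with `ids`, `d` (symmetric distance
#'   matrix, `NA` where no sites were comparable) and `n_sites` (symmetric
#'   matrix of compared-site counts; the diagonal holds each sequence's
#'   unambiguous-base count).
#' @examples
#' p_distance_matrix(msa(c(a = "AAAA", b = "AAAT")))$d
#' @export
p_distance_matrix <- function(aln) {
  if (length(aln) < 2L) stopf("p-distance matrix requires at least 2 sequences")
  if (!inherits(aln, "msa")) aln <- msa(aln)  # accept a named vector too
  m <- as.matrix(aln)
  codes <- matrix(match(m, BASES), nrow = nrow(m))  # NA for gaps/ambiguity
  n <- nrow(codes)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ns) <- as.integer(rowSums(!is.na(codes)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      k <- sum(ok)
      ns[i, j] <- ns[j, i] <- k
      d[i, j] <- d[j, i] <- if (k == 0L) NA_real_ else
        sum(codes[i, ok] != codes[j, ok]) / k
    }
  }
  structure(list(ids = ids, d = d, n_sites = ns), class = "p_dist")
}

#' @export
print.p_dist <- function(x, ...) {
  cat(sprintf("<p_dist> %d sequences\n", length(x$ids)))
  invisible(x)
}

#' Flag distance outliers within groups
#'
#' Within each group of at least `min_group_size` members, an upper Tukey
#' fence is computed over the group's pairwise distances: `Q3 + multiplier
#' x IQR`, with quartiles by linear interpolation. A member is an outlier
#' when its summary distance to the other group members (median by
#' default; `statistic = "mean"` is available) strictly exceeds the fence.
#' Missing distances are excluded from both the fence and the member
#' summaries; a member of a qualifying group with no comparable distance
#' at all cannot be placed and is flagged as an outlier. Groups smaller
#' than `min_group_size` contribute no outliers.
#'
#' @param dm A [p_distance_matrix()] result.
#' @param groups Named character vector or list mapping every id in `dm`
#'   to its group label (genus or binomial).
#' @param multiplier Fence multiplier (default 1.5).
#' @param min_group_size Smallest group size evaluated (default 4;
#'   quartiles on fewer points are unstable).
#' @param statistic Per-member summary of within-group distances.
#' @return Character vector of outlier ids.
#' @export
flag_distance_outliers <- function(dm, groups, multiplier = 1.5,
                                   min_group_size = 4L,
                                   statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stat_fn <- if (statistic == "median") stats::median else mean
  if (!is.numeric(multiplier) || multiplier <= 0)
    stopf("multiplier must be positive")
  groups <- unlist(groups)
  missing <- setdiff(dm$ids, names(groups))
  if (length(missing))
    stopf("ids without a group label: %s", paste(missing, collapse = ", "))
  outliers <- character()
  for (g in unique(groups[dm$ids])) {
    ids_g <- dm$ids[groups[dm$ids] == g]
    if (length(ids_g) < min_group_size) next
    sub <- dm$d[ids_g, ids_g, drop = FALSE]
    pair_vals <- sub[upper.tri(sub)]
    pair_vals <- pair_vals[!is.na(pair_vals)]
    if (length(pair_vals) == 0L) {
      outliers <- c(outliers, ids_g)  # nothing comparable in the group
      next
    }
    q <- stats::quantile(pair_vals, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- q[2L] + multiplier * (q[2L] - q[1L])
    for (id in ids_g) {
      vals <- sub[id, setdiff(ids_g, id)]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L || stat_fn(vals) > fence)
        outliers <- c(outliers, id)
    }
  }
  unique(outliers)
}

#' Per-species barcode-gap report
#'
#' For every species, reports the maximum intraspecific p-distance
#' (`max_intra`; missing when the species has fewer than two members or no
#' comparable conspecific pair), the minimum distance to any other species
#' (`min_inter`; missing when no heterospecific pair is comparable) and
#' whether a barcode gap is present (`min_inter > max_intra`, strictly;
#' missing when either side is).
#'
#' @param dm A [p_distance_matrix()] result.
#' @param species Named character vector mapping every id in `dm` to its
#'   species (binomial).
#' @return Data frame with columns `species`, `n`, `max_intra`,
#'   `min_inter`, `gap_present`.
#' @export
barcode_gap_report <- function(dm, species) {
  species <- unlist(species)
  missing <- setdiff(dm$ids, names(species))
  if (length(missing))
    stopf("ids without a species label: %s", paste(missing, collapse = ", "))
  sp_of <- species[dm$ids]
  rows <- lapply(unique(sp_of), function(s) {
    ids_s <- dm$ids[sp_of == s]
    ids_o <- dm$ids[sp_of != s]
    intra <- if (length(ids_s) >= 2L) {
      sub <- dm$d[ids_s, ids_s, drop = FALSE]
      v <- sub[upper.tri(sub)]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    } else NA_real_
    inter <- if (length(ids_o) >= 1L) {
      v <- dm$d[ids_s, ids_o, drop = FALSE]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    } else NA_real_
    data.frame(species = s, n = length(ids_s), max_intra = intra,
               min_inter = inter,
               gap_present = if (is.na(intra) || is.na(inter)) NA else
                 inter > intra,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
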