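# Independent brute-force oracles; these deliberately avoid the code paths
# used by the implementation (explicit per-position loops, hand-rolled
# quartile interpolation).

oracle_p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  stopifnot(length(a) == length(b))
  compared <- 0L
  diff <- 0L
  for (k in seq_along(a)) {
    ok_a <- a[k] == "A" || a[k] == "C" || a[k] == "G" || a[k] == "T"
    ok_b <- b[k] == "A" || b[k] == "C" || b[k] == "G" || b[k] == "T"
    if (ok_a && ok_b) {
      compared <- compared + 1L
      if (a[k] != b[k]) diff <- diff + 1L
    }
  }
  list(d = if (compared == 0L) NA_real_ else diff / compared, n = compared)
}

# type-7 quantile by explicit interpolation
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_outliers <- function(d, group_ids, multiplier = 1.5,
                            stat = stats::median) {
  sub <- d[group_ids, group_ids, drop = FALSE]
  vals <- c()
  for (i in seq_along(group_ids))
    for (j in seq_along(group_ids))
      if (i < j && !is.na(sub[i, j])) vals <- c(vals, sub[i, j])
  q1 <- oracle_quantile7(vals, 0.25)
  q3 <- oracle_quantile7(vals, 0.75)
  fence <- q3 + multiplier * (q3 - q1)
  out <- c()
  for (id in group_ids) {
    v <- sub[id, setdiff(group_ids, id)]
    v <- v[!is.na(v)]
    if (length(v) == 0 || stat(v) > fence) out <- c(out, id)
  }
  out
}

oracle_barcode_gap <- function(d, species_of) {
  ids <- rownames(d)
  res <- list()
  for (s in unique(species_of[ids])) {
    ins <- ids[species_of[ids] == s]
    outs <- ids[species_of[ids] != s]
    intra <- c()
    for (i in ins) for (j in ins)
      if (i < j && !is.na(d[i, j])) intra <- c(intra, d[i, j])
    inter <- c()
    for (i in ins) for (j in outs)
      if (!is.na(d[i, j])) inter <- c(inter, d[i, j])
    res[[s]] <- list(
      max_intra = if (length(intra)) max(intra) else NA_real_,
      min_inter = if (length(inter)) min(inter) else NA_real_)
  }
  res
}

random_gapped_msa <- function(n, len, gap_prob = 0.1, ambig_prob = 0.05) {
  alphabet <- c("A", "C", "G", "T", "-", "N", "R", "Y")
  probs <- c(rep((1 - gap_prob - ambig_prob) / 4, 4), gap_prob,
             rep(ambig_prob / 3, 3))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(seqs) <- sprintf("r%02d", seq_len(n))
  msa(seqs)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

rbind_tables <- function(a, b)
  total_table(rbind(as.data.frame(a), as.data.frame(b)))
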