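# Longitudinal virome stability: Bray-Curtis dissimilarities between
# samples and a label-permutation test comparing intra-individual
# (same person, two timepoints) against inter-individual (different
# people, same timepoint) dissimilarities.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; 0 for identical non-empty profiles, 1 for
#' profiles with disjoint support.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero; exclude empty samples upstream")
  sum(abs(x - y)) / tot
}

#' Intra- and inter-individual Bray-Curtis pair table
#'
#' Computes all pairwise Bray-Curtis dissimilarities (via
#' [vegan::vegdist()]) and labels the pairs relevant to the stability
#' question: `intra` pairs the two timepoints of one individual, `inter`
#' pairs different individuals within each timepoint separately (the two
#' timepoints' inter pairs are pooled). vOTUs detected in no sample and
#' samples with no detected vOTU are excluded before computing
#' dissimilarities.
#'
#' @param abundance numeric matrix, samples x vOTUs; rownames are sample
#'   ids.
#' @param metadata data.frame with columns `sample_id`, `individual`,
#'   `timepoint`.
#' @return data.frame with columns `sample_a`, `sample_b`, `bc`, `label`.
#' @export
pair_dissimilarities <- function(abundance, metadata) {
  if (is.null(rownames(abundance)))
    stop("`abundance` must have sample ids as rownames")
  keep_s <- rowSums(abundance) > 0
  keep_v <- colSums(abundance) > 0
  abundance <- abundance[keep_s, keep_v, drop = FALSE]
  md <- metadata[match(rownames(abundance), metadata$sample_id), ]
  if (any(is.na(md$individual)))
    stop("metadata missing for some samples")
  n <- nrow(abundance)
  d <- as.matrix(vegan::vegdist(abundance, method = "bray"))

  idx <- which(upper.tri(d), arr.ind = TRUE)
  ia <- idx[, 1L]; ib <- idx[, 2L]
  same_ind <- md$individual[ia] == md$individual[ib]
  same_tp <- md$timepoint[ia] == md$timepoint[ib]
  label <- rep(NA_character_, length(ia))
  label[same_ind & !same_tp] <- "intra"
  label[!same_ind & same_tp] <- "inter"
  keep <- !is.na(label)
  data.frame(sample_a = rownames(abundance)[ia[keep]],
             sample_b = rownames(abundance)[ib[keep]],
             bc = d[idx][keep],
             label = label[keep],
             row.names = NULL)
}

# Two-sided unpaired rank-sum p-value, normal approximation with tie
# correction and continuity correction (the large-sample path of
# wilcox.test). `r` are the pooled ranks, `tie_term` the precomputed tie
# correction, `sx` the rank sum of the first group of size nx.
.ranksum_p <- function(sx, nx, ny, tie_term) {
  z <- sx - nx * (nx + 1) / 2 - nx * ny / 2
  sigma <- sqrt((nx * ny / 12) * ((nx + ny + 1) - tie_term))
  z <- (z - sign(z) * 0.5) / sigma
  2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5)
}

#' Label-permutation test of virome stability
#'
#' The observed statistic is the two-sided unpaired rank-sum p-value
#' comparing intra- against inter-individual Bray-Curtis values. On each
#' iteration the dissimilarity values are randomly reassigned between the
#' pooled pair slots (equivalent to permuting the intra/inter labels) and
#' the rank-test p-value is recomputed; the empirical p-value is the
#' proportion of permuted p-values strictly lower than the observed one,
#' so its resolution is `1/iterations`.
#'
#' @param pairs data.frame with columns `bc` and `label`
#'   (`"intra"`/`"inter"`), e.g. from [pair_dissimilarities()].
#' @param iterations number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `observed_p`, `empirical_p`, `iterations`, `seed`,
#'   `n_intra`, `n_inter`.
#' @export
stability_test <- function(pairs, iterations = 10000L, seed = NULL) {
  if (iterations < 1L) stop("`iterations` must be at least 1")
  if (!all(c("intra", "inter") %in% pairs$label))
    stop("both pair labels must be present")
  bc <- pairs$bc
  is_intra <- pairs$label == "intra"
  nx <- sum(is_intra); ny <- sum(!is_intra); n <- nx + ny
  r <- rank(bc)
  nties <- table(r)
  tie_term <- sum(nties^3 - nties) / (n * (n - 1))
  observed_p <- .ranksum_p(sum(r[is_intra]), nx, ny, tie_term)
  perm_p <- .with_seed(seed, {
    vapply(seq_len(iterations), function(i)
      .ranksum_p(sum(r[sample.int(n, nx)]), nx, ny, tie_term), numeric(1))
  })
  list(observed_p = observed_p,
       empirical_p = mean(perm_p < observed_p),
       iterations = as.integer(iterations),
       seed = seed, n_intra = nx, n_inter = ny)
}
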