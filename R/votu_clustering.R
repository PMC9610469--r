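# Species-level clustering of viral genome sequences into vOTUs by
# average nucleotide identity (ANI), with greedy centroid clustering and
# the terminal-repeat-aware representative selection rule.

#' Average nucleotide identity from local alignments
#'
#' ANI between two sequences is the alignment-length-weighted mean percent
#' identity over their local alignments; each sequence's coverage is the
#' fraction of its length spanned by the merged alignment intervals.
#'
#' @param alignments data.frame with columns `identity`, `length`,
#'   `q_from`, `q_to`, `t_from`, `t_to` (e.g. from [align_pair()] or a
#'   BLASTN outfmt-6 table).
#' @param query_length,target_length sequence lengths (nt).
#' @return list with `ani` (percent, `NA` when no alignments),
#'   `query_cov` and `target_cov` (percent).
#' @export
compute_ani <- function(alignments, query_length, target_length) {
  if (is.null(alignments) || nrow(alignments) == 0L)
    return(list(ani = NA_real_, query_cov = 0, target_cov = 0))
  w <- as.numeric(alignments$length)
  ani <- sum(alignments$identity * w) / sum(w)
  qcov <- 100 * .merged_width(alignments$q_from, alignments$q_to) / query_length
  tcov <- 100 * .merged_width(alignments$t_from, alignments$t_to) / target_length
  list(ani = ani, query_cov = qcov, target_cov = tcov)
}

# Normalize an ANI record table to one row per unordered pair as seen
# from a given member sequence: coverage of the member itself.
.pair_lookup <- function(ani_records) {
  k1 <- paste(ani_records$query_id, ani_records$target_id, sep = "\r")
  k2 <- paste(ani_records$target_id, ani_records$query_id, sep = "\r")
  list(keys = c(k1, k2),
       ani = c(ani_records$ani, ani_records$ani),
       cov = c(ani_records$query_cov, ani_records$target_cov))
}

#' Greedy centroid clustering into vOTUs
#'
#' Sequences are visited in order of decreasing length (ties by id). Each
#' sequence joins the earliest-founded centroid to which it shows ANI >=
#' `min_ani` with at least `min_cov` percent of the member (shorter)
#' sequence covered by the alignments; otherwise it founds a new centroid.
#' Members are compared to centroids only, and centroids are never
#' reassigned, so the output is a partition.
#'
#' @param ani_records data.frame with columns `query_id`, `target_id`,
#'   `ani`, `query_cov`, `target_cov` (coverage of each sequence by the
#'   merged pair alignments, percent).
#' @param lengths named numeric vector of sequence lengths (nt) for every
#'   sequence to cluster.
#' @param min_ani ANI threshold (percent).
#' @param min_cov member-coverage threshold (percent).
#' @return data.frame with columns `seq_id`, `votu` (integer cluster
#'   index in founding order), `is_centroid`.
#' @export
cluster_votus <- function(ani_records, lengths, min_ani = 95, min_cov = 85) {
  ids <- names(lengths)
  if (is.null(ids) || any(ids == ""))
    stop("`lengths` must be a fully named vector")
  ord <- ids[order(-as.numeric(lengths), ids)]
  lk <- if (!is.null(ani_records) && nrow(ani_records) > 0L)
    .pair_lookup(ani_records)
  else list(keys = character(), ani = numeric(), cov = numeric())

  centroids <- character()
  assignment <- integer(length(ord)); names(assignment) <- ord
  for (sq in ord) {
    joined <- NA_integer_
    if (length(centroids) > 0L) {
      keys <- paste(sq, centroids, sep = "\r")
      m <- match(keys, lk$keys)
      ok <- !is.na(m) & lk$ani[m] >= min_ani & lk$cov[m] >= min_cov
      if (any(ok)) joined <- which(ok)[1L]
    }
    if (is.na(joined)) {
      centroids <- c(centroids, sq)
      joined <- length(centroids)
    }
    assignment[[sq]] <- joined
  }
  data.frame(seq_id = names(assignment),
             votu = unname(assignment),
             is_centroid = names(assignment) %in% centroids,
             row.names = NULL)
}

#' Select the representative genome of a vOTU
#'
#' If any member carries terminal repeats, the representative is the
#' terminal-repeat member whose length is the median of the
#' terminal-repeat members' lengths; with an even count, the member
#' closest to the arithmetic median is taken, ties going to the shorter
#' (then lexicographically smaller id). Without terminal-repeat members,
#' the longest TerL-encoding member is chosen, falling back to the
#' longest member overall (length ties by id).
#'
#' @param members data.frame with columns `seq_id`, `length`, `has_tr`
#'   (logical: terminal repeats present), `has_terl` (logical: TerL gene
#'   detected).
#' @return the representative `seq_id`.
#' @export
select_representative <- function(members) {
  if (is.null(members) || nrow(members) == 0L)
    stop("vOTU has no members")
  tr <- members[members$has_tr, , drop = FALSE]
  if (nrow(tr) > 0L) {
    med <- median(as.numeric(tr$length))
    o <- order(abs(tr$length - med), tr$length, tr$seq_id)
    return(tr$seq_id[o[1L]])
  }
  pool <- members[members$has_terl, , drop = FALSE]
  if (nrow(pool) == 0L) pool <- members
  o <- order(-as.numeric(pool$length), pool$seq_id)
  pool$seq_id[o[1L]]
}
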