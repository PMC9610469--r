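# Internal seed-and-extend nucleotide aligner.
#
# A deliberately small local aligner used where the pipeline needs pairwise
# nucleotide alignments (intragenomic repeat discovery, pairwise ANI,
# protospacer screening) without shelling out to an external search tool.
# Exact word seeding (default word size 11, matching a BLASTN megablast-free
# `-task blastn` seed scale) followed by ungapped X-drop extension; identity
# is matches / alignment columns. Gapped alignment is not attempted: the
# contract downstream is thresholds on length and identity, and the planted
# signals this package quantifies are ungapped.

# All start positions of exact word matches between two sequences.
# Returns a data.frame(pa, pb). Words containing ambiguity codes never seed.
.seed_pairs <- function(sa, sb, word, self_ordered = FALSE, max_word_pairs = 400L) {
  la <- nchar(sa); lb <- nchar(sb)
  if (la < word || lb < word) return(data.frame(pa = integer(), pb = integer()))
  wa <- substring(sa, 1:(la - word + 1L), word:la)
  wb <- substring(sb, 1:(lb - word + 1L), word:lb)
  ok_a <- !grepl("[^ACGT]", wa); ok_b <- !grepl("[^ACGT]", wb)
  ia <- which(ok_a); ib <- which(ok_b)
  if (length(ia) == 0L || length(ib) == 0L)
    return(data.frame(pa = integer(), pb = integer()))
  fa <- wa[ia]; fb <- wb[ib]
  shared <- intersect(fa, fb)
  if (length(shared) == 0L)
    return(data.frame(pa = integer(), pb = integer()))
  ga <- split(ia[fa %in% shared], fa[fa %in% shared])
  gb <- split(ib[fb %in% shared], fb[fb %in% shared])
  out_a <- vector("list", length(shared)); out_b <- out_a
  for (i in seq_along(shared)) {
    pa <- ga[[shared[i]]]; pb <- gb[[shared[i]]]
    if (length(pa) * length(pb) > max_word_pairs) next  # low-complexity guard
    g <- expand.grid(pa = pa, pb = pb, KEEP.OUT.ATTRS = FALSE)
    if (self_ordered) g <- g[g$pa < g$pb, , drop = FALSE]
    out_a[[i]] <- g$pa; out_b[[i]] <- g$pb
  }
  data.frame(pa = unlist(out_a, use.names = FALSE),
             pb = unlist(out_b, use.names = FALSE))
}

# Merge word seeds lying on a common diagonal into maximal segments,
# allowing gaps of up to `max_gap` nt between consecutive seed starts.
.merge_diagonal_seeds <- function(pairs, word, max_gap = 60L) {
  if (nrow(pairs) == 0L)
    return(data.frame(a1 = integer(), a2 = integer(),
                      b1 = integer(), b2 = integer()))
  d <- pairs$pb - pairs$pa
  o <- order(d, pairs$pa)
  pa <- pairs$pa[o]; d <- d[o]
  new_seg <- c(TRUE, diff(d) != 0L | diff(pa) > max_gap)
  seg <- cumsum(new_seg)
  a1 <- tapply(pa, seg, min); a2 <- tapply(pa, seg, max) + word - 1L
  dd <- tapply(d, seg, `[`, 1L)
  data.frame(a1 = as.integer(a1), a2 = as.integer(a2),
             b1 = as.integer(a1 + dd), b2 = as.integer(a2 + dd))
}

# Ungapped X-drop extension of one diagonal segment.  ra/rb are raw vectors
# of the two sequences.  Match +1, mismatch -2, stop when the running score
# drops `xdrop` below its maximum.  Returns extended coordinates and the
# match count over the final extent.
.extend_ungapped <- function(ra, rb, a1, a2, b1, b2, xdrop = 12L) {
  la <- length(ra); lb <- length(rb)
  # left
  score <- 0L; best <- 0L; best_k <- 0L; k <- 0L
  while (a1 - k - 1L >= 1L && b1 - k - 1L >= 1L) {
    k <- k + 1L
    score <- score + if (ra[a1 - k] == rb[b1 - k]) 1L else -2L
    if (score > best) { best <- score; best_k <- k }
    if (score < best - xdrop) break
  }
  a1 <- a1 - best_k; b1 <- b1 - best_k
  # right
  score <- 0L; best <- 0L; best_k <- 0L; k <- 0L
  while (a2 + k + 1L <= la && b2 + k + 1L <= lb) {
    k <- k + 1L
    score <- score + if (ra[a2 + k] == rb[b2 + k]) 1L else -2L
    if (score > best) { best <- score; best_k <- k }
    if (score < best - xdrop) break
  }
  a2 <- a2 + best_k; b2 <- b2 + best_k
  matches <- sum(ra[a1:a2] == rb[b1:b2])
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, matches = matches)
}

.extend_segments <- function(segs, ra, rb, xdrop = 12L) {
  if (nrow(segs) == 0L) {
    return(data.frame(a1 = integer(), a2 = integer(), b1 = integer(),
                      b2 = integer(), length = integer(),
                      identity = numeric()))
  }
  ext <- t(vapply(seq_len(nrow(segs)), function(i) {
    .extend_ungapped(ra, rb, segs$a1[i], segs$a2[i], segs$b1[i], segs$b2[i],
                     xdrop = xdrop)
  }, numeric(5)))
  len <- as.integer(ext[, "a2"] - ext[, "a1"] + 1L)
  data.frame(a1 = as.integer(ext[, "a1"]), a2 = as.integer(ext[, "a2"]),
             b1 = as.integer(ext[, "b1"]), b2 = as.integer(ext[, "b2"]),
             length = len, identity = 100 * ext[, "matches"] / len)
}

#' Local alignments between two nucleotide sequences
#'
#' Seed-and-extend local alignment on both strands. Used internally to
#' supply alignment tables to [find_self_repeats()] and [compute_ani()]
#' when precomputed BLASTN-style hits are not provided.
#'
#' @param query,target nucleotide strings.
#' @param word exact seed word size.
#' @param min_len minimum alignment length to report.
#' @param min_identity minimum percent identity to report.
#' @param max_gap maximum gap (nt) between seed starts merged into one
#'   ungapped segment.
#' @return data.frame with columns `q_from`, `q_to`, `t_from`, `t_to`
#'   (1-based inclusive, always on the forward strand of each sequence),
#'   `length`, `identity` (percent) and `orientation`
#'   (`"direct"`/`"inverted"`).
#' @export
align_pair <- function(query, target, word = 11L, min_len = 100L,
                       min_identity = 80, max_gap = 60L) {
  sq <- .check_sequence(query, "query")
  st <- .check_sequence(target, "target")
  rq <- charToRaw(sq)
  res <- list()

  hits_one <- function(sb, orientation) {
    pr <- .seed_pairs(sq, sb, word)
    segs <- .merge_diagonal_seeds(pr, word, max_gap)
    .extend_segments(segs, rq, charToRaw(sb)) -> h
    h$orientation <- rep(orientation, nrow(h))
    h
  }
  hd <- hits_one(st, "direct")
  hi <- hits_one(revcomp(st), "inverted")
  if (nrow(hi) > 0L) {           # map revcomp coordinates back to target
    lt <- nchar(st)
    b1 <- lt - hi$b2 + 1L; b2 <- lt - hi$b1 + 1L
    hi$b1 <- b1; hi$b2 <- b2
  }
  h <- rbind(hd, hi)
  h <- h[h$length >= min_len & h$identity >= min_identity, , drop = FALSE]
  h <- unique(h)
  data.frame(q_from = h$a1, q_to = h$a2, t_from = h$b1, t_to = h$b2,
             length = h$length, identity = h$identity,
             orientation = h$orientation, row.names = NULL)
}
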