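# Genome-level sequence features: terminal repeats, composition skew
# profiles, intragenomic repeat pairs, and diversity-generating
# retroelement (DGR) candidates.

#' Detect direct or inverted terminal repeats
#'
#' A genome sequence assembled through a circular replication intermediate
#' carries a direct terminal repeat (DTR): its first k nucleotides are
#' identical to its last k. Protein-primed replication leaves an inverted
#' terminal repeat (ITR): the 3' end equals the reverse complement of the
#' 5' end. Repeats of at least `min_len` (default 20 nt) are reported;
#' matching is exact. The longest qualifying repeat of each kind is found
#' (searching up to half the sequence length so the two copies cannot
#' overlap); if both kinds qualify the longer wins, with ties going to DTR.
#'
#' @param sequence nucleotide string (IUPAC letters).
#' @param min_len minimum repeat length (nt) to call.
#' @return list with elements `kind` (`"DTR"`, `"ITR"` or `"none"`) and
#'   `length` (nt; 0 when `kind == "none"`).
#' @export
detect_terminal_repeats <- function(sequence, min_len = 20L) {
  s <- .check_sequence(sequence)
  L <- nchar(s)
  min_len <- as.integer(min_len)
  if (L < 2L * min_len)
    stop("sequence must be at least 2 * min_len nucleotides long")
  r <- charToRaw(s)
  rc <- charToRaw(revcomp(s))
  kmax <- L %/% 2L

  # DTR: longest k with prefix(k) == suffix(k), i.e. r[1:k] == r[(L-k+1):L].
  # ITR: suffix(k) == revcomp(prefix(k)), equivalently prefix(rc, k) ==
  # prefix(r, k) since rc[1:k] is the reverse complement of the suffix.
  # Cheap anchor probes before the full slice comparison keep the scan
  # linear on random sequence.
  longest_dtr <- function() {
    for (k in kmax:min_len) {
      if (r[1L] != r[L - k + 1L]) next
      if (r[k] != r[L]) next
      m <- (k + 1L) %/% 2L
      if (r[m] != r[L - k + m]) next
      if (identical(r[1:k], r[(L - k + 1L):L])) return(k)
    }
    0L
  }
  # the ITR condition is nested in k, so the longest match is simply the
  # leading run of agreement between the sequence and its reverse
  # complement, capped at half the length
  longest_itr <- function() {
    eq <- r[1:kmax] == rc[1:kmax]
    k <- if (all(eq)) kmax else which(!eq)[1L] - 1L
    if (k >= min_len) k else 0L
  }
  dtr <- longest_dtr()
  itr <- longest_itr()
  if (dtr == 0L && itr == 0L) return(list(kind = "none", length = 0L))
  if (dtr >= itr) list(kind = "DTR", length = dtr)
  else list(kind = "ITR", length = itr)
}

#' Nucleotide skew profile along a genome
#'
#' GC skew (G-C)/(G+C) and AT skew (A-T)/(A+T) in windows of `window` nt
#' placed every `step` nt, starting at position 1, for as long as a full
#' window fits. A skew is `NA` where its denominator is zero. The
#' cumulative GC skew is the running sum of per-window GC skews (missing
#' windows contribute 0); a V-shaped cumulative curve is the classic
#' signature of bidirectional replication.
#'
#' @param sequence nucleotide string.
#' @param window window width (nt).
#' @param step window spacing (nt).
#' @return data.frame with columns `window_start`, `window_center`,
#'   `gc_skew`, `at_skew`, `cumulative_gc_skew`. Zero rows (with a
#'   warning) if the sequence is shorter than one window.
#' @export
skew_profile <- function(sequence, window = 1001L, step = 200L) {
  s <- .check_sequence(sequence)
  L <- nchar(s)
  empty <- data.frame(window_start = integer(), window_center = numeric(),
                      gc_skew = numeric(), at_skew = numeric(),
                      cumulative_gc_skew = numeric())
  if (L < window) {
    warning("sequence shorter than one window; empty skew track")
    return(empty)
  }
  starts <- seq.int(1L, L - window + 1L, by = step)
  v <- Biostrings::Views(Biostrings::DNAString(s), start = starts,
                         width = window)
  f <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  gc_den <- f[, "G"] + f[, "C"]
  at_den <- f[, "A"] + f[, "T"]
  gc <- ifelse(gc_den > 0, (f[, "G"] - f[, "C"]) / gc_den, NA_real_)
  at <- ifelse(at_den > 0, (f[, "A"] - f[, "T"]) / at_den, NA_real_)
  data.frame(window_start = starts,
             window_center = starts + (window - 1) / 2,
             gc_skew = gc, at_skew = at,
             cumulative_gc_skew = cumsum(ifelse(is.na(gc), 0, gc)))
}

#' Find intragenomic repeat pairs
#'
#' Compares a genome sequence to itself (both strands) with the internal
#' seed-and-extend aligner and reports pairs of repeated regions with
#' alignment length >= `min_len` and identity >= `min_identity`, mirroring
#' a BLASTN self-comparison screen. The trivial full-length self-identity
#' is excluded, and symmetric duplicates (A,B)/(B,A) are collapsed so that
#' `start_a < start_b` (palindromic self-matches, where both intervals
#' coincide, are dropped).
#'
#' @param sequence nucleotide string.
#' @param min_len minimum alignment length (nt).
#' @param min_identity minimum percent identity.
#' @param word seed word size of the internal aligner.
#' @return data.frame with columns `start_a`, `end_a`, `start_b`, `end_b`
#'   (1-based inclusive), `length`, `identity`, `orientation`.
#' @export
find_self_repeats <- function(sequence, min_len = 100L, min_identity = 80,
                              word = 11L) {
  s <- .check_sequence(sequence)
  r <- charToRaw(s)
  L <- nchar(s)

  # direct: ordered seed pairs (pa < pb) exclude the trivial diagonal
  pr <- .seed_pairs(s, s, word, self_ordered = TRUE)
  segs <- .merge_diagonal_seeds(pr, word)
  hd <- .extend_segments(segs, r, r)
  hd$orientation <- rep("direct", nrow(hd))

  # inverted: compare to the reverse complement, map back, canonicalize
  rc <- revcomp(s)
  pri <- .seed_pairs(s, rc, word)
  segsi <- .merge_diagonal_seeds(pri, word)
  hi <- .extend_segments(segsi, r, charToRaw(rc))
  if (nrow(hi) > 0L) {
    b1 <- L - hi$b2 + 1L; b2 <- L - hi$b1 + 1L
    hi$b1 <- b1; hi$b2 <- b2
    swap <- hi$b1 < hi$a1
    tmp1 <- hi$a1[swap]; tmp2 <- hi$a2[swap]
    hi$a1[swap] <- hi$b1[swap]; hi$a2[swap] <- hi$b2[swap]
    hi$b1[swap] <- tmp1; hi$b2[swap] <- tmp2
    hi <- hi[!(hi$a1 == hi$b1 & hi$a2 == hi$b2), , drop = FALSE]  # palindrome
    hi <- unique(hi)
  }
  hi$orientation <- rep("inverted", nrow(hi))

  h <- rbind(hd, hi)
  h <- h[h$length >= min_len & h$identity >= min_identity, , drop = FALSE]
  data.frame(start_a = h$a1, end_a = h$a2, start_b = h$b1, end_b = h$b2,
             length = h$length, identity = h$identity,
             orientation = h$orientation, row.names = NULL)
}

#' Call diversity-generating retroelement (DGR) candidates
#'
#' A DGR signature is a reverse transcriptase (RT) gene plus a pair of
#' nucleotide repeats with at least one repeat in close proximity to the
#' RT gene. For every (RT gene, repeat pair) combination where the minimum
#' gap between either repeat interval and the RT interval is at most
#' `proximity` nt, one candidate is emitted. Repeat pairs that simply
#' restate the genome's terminal repeat can be excluded by supplying
#' `terminal_repeat` and `genome_length`.
#'
#' @param repeats data.frame as returned by [find_self_repeats()].
#' @param rt_genes data.frame with columns `start`, `end` (1-based
#'   inclusive RT gene intervals).
#' @param proximity maximum gap (nt) between a repeat and the RT gene.
#' @param terminal_repeat optional result of [detect_terminal_repeats()].
#' @param genome_length required when `terminal_repeat` is given.
#' @return data.frame with columns `rt_start`, `rt_end`, repeat-pair
#'   coordinates, and `min_distance_to_rt`.
#' @export
detect_dgr_candidates <- function(repeats, rt_genes, proximity = 1000L,
                                  terminal_repeat = NULL,
                                  genome_length = NULL) {
  out <- data.frame(rt_start = integer(), rt_end = integer(),
                    start_a = integer(), end_a = integer(),
                    start_b = integer(), end_b = integer(),
                    min_distance_to_rt = integer())
  if (is.null(repeats) || nrow(repeats) == 0L ||
      is.null(rt_genes) || nrow(rt_genes) == 0L) return(out)

  if (!is.null(terminal_repeat) && terminal_repeat$kind != "none") {
    if (is.null(genome_length))
      stop("`genome_length` is required to exclude terminal-repeat pairs")
    k <- terminal_repeat$length
    is_tr <- repeats$start_a <= k & repeats$end_b >= genome_length - k + 1L
    repeats <- repeats[!is_tr, , drop = FALSE]
  }
  if (nrow(repeats) == 0L) return(out)

  rows <- list()
  for (i in seq_len(nrow(rt_genes))) {
    ga <- .interval_gap(repeats$start_a, repeats$end_a,
                        rt_genes$start[i], rt_genes$end[i])
    gb <- .interval_gap(repeats$start_b, repeats$end_b,
                        rt_genes$start[i], rt_genes$end[i])
    d <- pmin(ga, gb)
    keep <- which(d <= proximity)
    if (length(keep) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        rt_start = rt_genes$start[i], rt_end = rt_genes$end[i],
        start_a = repeats$start_a[keep], end_a = repeats$end_a[keep],
        start_b = repeats$start_b[keep], end_b = repeats$end_b[keep],
        min_distance_to_rt = as.integer(d[keep]))
  }
  if (length(rows) == 0L) return(out)
  do.call(rbind, rows)
}
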