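# Genetic-code assignment for phage genomes with stop-codon reassignment.
#
# Some gut phages recode a stop codon to an amino acid: genetic code 4
# reads TGA as tryptophan, genetic code 15 reads TAG as glutamine. Under
# the standard bacterial code 11 the genes of such genomes fragment at the
# recoded codon, so comparing the total coding potential reached under
# each candidate code reveals the code in use.

.STOPS <- list(`11` = c("TAA", "TAG", "TGA"),
               `4`  = c("TAA", "TAG"),
               `15` = c("TAA", "TGA"))
.STARTS <- c("ATG", "GTG", "TTG")

# ORFs in the three forward frames of `s` under `code`, in coordinates of
# `s`. Maximal stop-to-stop stretches (or running to the sequence end),
# trimmed to the first start codon, minimum length filter applied later.
.orfs_forward <- function(s, code) {
  L <- nchar(s)
  stops <- .STOPS[[as.character(code)]]
  res <- vector("list", 3L)
  for (f in 0:2) {
    cs <- seq.int(f + 1L, L - 2L, by = 3L)
    if (length(cs) == 0L) next
    codons <- substring(s, cs, cs + 2L)
    stop_i <- which(codons %in% stops)
    seg_from <- c(1L, stop_i + 1L)           # codon index after each stop
    seg_to <- c(stop_i, length(codons))      # inclusive of the stop codon
    keep <- seg_from <= seg_to
    seg_from <- seg_from[keep]; seg_to <- seg_to[keep]
    starts_mask <- codons %in% .STARTS
    orf <- lapply(seq_along(seg_from), function(i) {
      idx <- seg_from[i]:seg_to[i]
      st <- idx[starts_mask[idx]]
      if (length(st) == 0L) return(NULL)
      c(from = cs[st[1L]], to = cs[seg_to[i]] + 2L)
    })
    orf <- orf[!vapply(orf, is.null, logical(1))]
    if (length(orf) > 0L)
      res[[f + 1L]] <- data.frame(start = vapply(orf, `[[`, 0, "from"),
                                  end = vapply(orf, `[[`, 0, "to"))
  }
  do.call(rbind, res)
}

#' Predict open reading frames under a given genetic code
#'
#' Six-frame scan for maximal stop-to-stop open reading frames, trimmed to
#' the first ATG/GTG/TTG start codon, with a stretch running to the
#' sequence end also allowed to close an ORF. ORFs shorter than `min_len`
#' are dropped, and overlapping calls are resolved by greedy selection in
#' order of decreasing length (ties by genome position).
#'
#' @param sequence nucleotide string.
#' @param code genetic code: 11 (standard bacterial), 4 (TGA read as
#'   tryptophan) or 15 (TAG read as glutamine).
#' @param min_len minimum ORF length (nt), start through stop inclusive.
#' @return data.frame with columns `start`, `end` (1-based inclusive on
#'   the forward strand), `strand`, `length`, `code`.
#' @export
predict_orfs <- function(sequence, code = 11, min_len = 300L) {
  s <- .check_sequence(sequence)
  if (!code %in% c(11, 4, 15)) stop("`code` must be one of 11, 4, 15")
  L <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      code = integer())
  if (L < min_len) return(empty)

  fw <- .orfs_forward(s, code)
  rv <- .orfs_forward(revcomp(s), code)
  orfs <- list()
  if (!is.null(fw) && nrow(fw) > 0L)
    orfs$fw <- data.frame(start = fw$start, end = fw$end, strand = "+")
  if (!is.null(rv) && nrow(rv) > 0L)
    orfs$rv <- data.frame(start = L - rv$end + 1L, end = L - rv$start + 1L,
                          strand = "-")
  o <- do.call(rbind, orfs)
  if (is.null(o) || nrow(o) == 0L) return(empty)
  o$length <- o$end - o$start + 1L
  o <- o[o$length >= min_len, , drop = FALSE]
  if (nrow(o) == 0L) return(empty)

  # greedy non-overlap selection by descending length
  o <- o[order(-o$length, o$start, o$strand), , drop = FALSE]
  ir <- IRanges::IRanges(start = o$start, end = o$end)
  kept <- IRanges::IRanges()
  take <- logical(nrow(o))
  for (i in seq_len(nrow(o))) {
    if (IRanges::countOverlaps(ir[i], kept) == 0L) {
      take[i] <- TRUE
      kept <- c(kept, ir[i])
    }
  }
  o <- o[take, , drop = FALSE]
  o <- o[order(o$start), , drop = FALSE]
  o$code <- as.integer(code)
  rownames(o) <- NULL
  o
}

#' Total coding potential of a set of ORFs
#'
#' The default score is the summed nucleotide length of the selected
#' non-overlapping ORFs, which carries the decisive signal for code
#' assignment: recoding a stop codon fuses fragmented genes into long
#' ORFs. Externally computed per-gene coding scores (e.g. from a gene
#' caller) may be substituted via `scores` to reproduce a score-based
#' procedure exactly.
#'
#' @param orfs data.frame from [predict_orfs()].
#' @param scores optional numeric vector of external per-ORF scores; when
#'   given, their sum is returned instead of the length total.
#' @return single non-negative number.
#' @export
score_coding_potential <- function(orfs, scores = NULL) {
  if (!is.null(scores)) {
    if (any(is.na(scores))) stop("external scores must not be NA")
    return(sum(scores))
  }
  if (is.null(orfs) || nrow(orfs) == 0L) return(0)
  sum(as.numeric(orfs$length))
}

#' Assign the genetic code of a genome sequence
#'
#' Sequences shorter than `min_eligible_len` (default 20 kb) always keep
#' the standard bacterial code 11. For longer sequences the total coding
#' potential is computed under codes 11, 4 and 15; an alternative code is
#' assigned only when its score strictly exceeds the standard-code score
#' by more than `margin` (default 10%). If both alternative codes clear
#' the margin the higher-scoring one wins; an exact tie falls back to
#' code 11.
#'
#' @param sequence nucleotide string; omit when `scores` are supplied.
#' @param scores optional named numeric vector `c("11"=,"4"=,"15"=)` of
#'   precomputed total coding scores.
#' @param seq_length sequence length (nt); required with `scores`.
#' @param margin relative excess required of an alternative code.
#' @param min_eligible_len minimum length (nt) for alternative-code calls.
#' @param min_orf_len minimum ORF length passed to [predict_orfs()].
#' @return list with elements `scores` (named numeric), `assigned_code`
#'   (11, 4 or 15) and `eligible` (logical).
#' @export
assign_genetic_code <- function(sequence = NULL, scores = NULL,
                                seq_length = NULL, margin = 0.10,
                                min_eligible_len = 20000L,
                                min_orf_len = 300L) {
  if (is.null(scores)) {
    if (is.null(sequence)) stop("supply `sequence` or `scores`")
    s <- .check_sequence(sequence)
    seq_length <- nchar(s)
    eligible <- seq_length >= min_eligible_len
    if (!eligible) {
      scores <- c(`11` = NA_real_, `4` = NA_real_, `15` = NA_real_)
      return(list(scores = scores, assigned_code = 11L, eligible = FALSE))
    }
    scores <- vapply(c(11, 4, 15), function(cd)
      score_coding_potential(predict_orfs(s, cd, min_len = min_orf_len)),
      numeric(1))
    names(scores) <- c("11", "4", "15")
  } else {
    if (is.null(seq_length)) stop("`seq_length` is required with precomputed scores")
    if (any(is.na(scores)) || any(scores < 0))
      stop("coding scores must be non-negative")
    scores <- scores[c("11", "4", "15")]
    eligible <- seq_length >= min_eligible_len
    if (!eligible)
      return(list(scores = scores, assigned_code = 11L, eligible = FALSE))
  }
  s11 <- scores[["11"]]
  cand <- c(4L, 15L)
  pass <- vapply(cand, function(cd)
    scores[[as.character(cd)]] > (1 + margin) * s11, logical(1))
  assigned <- 11L
  if (any(pass)) {
    cc <- cand[pass]
    if (length(cc) == 2L) {
      s4 <- scores[["4"]]; s15 <- scores[["15"]]
      assigned <- if (s4 > s15) 4L else if (s15 > s4) 15L else 11L
    } else assigned <- cc
  }
  list(scores = scores, assigned_code = assigned, eligible = TRUE)
}
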