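#' @importFrom stats pnorm rbinom rnorm runif median cor p.adjust glm
#'   binomial coef vcov quantile rank sd plogis
#' @importFrom utils write.table read.delim
NULL

# Valid IUPAC nucleotide letters (upper case, as used throughout).
.IUPAC <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

.check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(sprintf("`%s` must be a single character string", arg))
  s <- toupper(sequence)
  chars <- unique(strsplit(s, "")[[1]])
  bad <- setdiff(chars, .IUPAC)
  if (length(bad) > 0L)
    stop(sprintf("`%s` contains non-IUPAC characters: %s",
                 arg, paste(bad, collapse = ", ")))
  s
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence single nucleotide string (IUPAC letters).
#' @return the reverse complement, upper case.
#' @export
revcomp <- function(sequence) {
  s <- .check_sequence(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Gap (nt) between two 1-based inclusive intervals; 0 if they touch/overlap.
.interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(a_start, b_start) - pmin(a_end, b_end) - 1L)
}

# Length of the union of 1-based inclusive intervals.
.merged_width <- function(from, to) {
  if (length(from) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = from, end = to))))
}
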