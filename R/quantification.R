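# Read-mapping summaries: coverage breadth and depth, breadth-gated
# relative abundance, detection, and prevalence.

#' Coverage statistics from per-position depth
#'
#' Breadth is the percent of genome positions covered by at least one
#' read; mean depth is total depth mass divided by genome length.
#'
#' @param depth data.frame with columns `pos` (1-based) and `depth`;
#'   positions with zero depth may be omitted.
#' @param genome_length genome length (nt).
#' @param n_reads mapped read count reported by the mapper.
#' @return list with `L`, `covered_positions`, `breadth` (percent),
#'   `n_reads`, `mean_depth`.
#' @export
coverage_stats <- function(depth, genome_length, n_reads = NA_integer_) {
  L <- as.numeric(genome_length)
  if (is.null(depth) || nrow(depth) == 0L)
    return(list(L = L, covered_positions = 0L, breadth = 0,
                n_reads = n_reads, mean_depth = 0))
  if (any(depth$pos < 1L | depth$pos > L))
    stop("depth positions outside [1, genome_length]")
  covered <- length(unique(depth$pos[depth$depth >= 1L]))
  list(L = L, covered_positions = covered,
       breadth = 100 * covered / L,
       n_reads = n_reads,
       mean_depth = sum(as.numeric(depth$depth)) / L)
}

#' Breadth-gated relative abundance
#'
#' The abundance of a vOTU in a sample is `(N * 1e6) / (L * S)` — mapped
#' reads per million sample reads, normalized by genome length — and is
#' set to zero when the breadth of genome coverage is below 75%
#' (detection gate). Breadth of exactly 75% counts as detected.
#'
#' @param n_reads reads mapped to the genome (N).
#' @param genome_length genome length in nt (L).
#' @param sample_reads total filtered, quality-trimmed reads in the
#'   sample (S).
#' @param breadth coverage breadth, percent.
#' @param min_breadth detection gate (percent); abundance is zero below.
#' @return numeric abundance (vectorized over its arguments).
#' @export
abundance <- function(n_reads, genome_length, sample_reads, breadth,
                      min_breadth = 75) {
  if (any(sample_reads <= 0)) stop("`sample_reads` must be positive")
  if (any(genome_length <= 0)) stop("`genome_length` must be positive")
  if (any(n_reads < 0)) stop("`n_reads` must be non-negative")
  ifelse(breadth < min_breadth, 0,
         (n_reads * 1e6) / (genome_length * sample_reads))
}

#' Per-cohort prevalence and the high-prevalence flag
#'
#' Prevalence of a vOTU in a cohort is the percent of that cohort's
#' samples in which it was detected. A vOTU is highly prevalent when its
#' prevalence strictly exceeds `min_prevalence` percent (default 5%) in
#' at least one cohort.
#'
#' @param detection logical matrix, samples x vOTUs (column names used as
#'   vOTU ids).
#' @param cohorts character vector of cohort labels, one per sample.
#' @param min_prevalence percent threshold, strictly exceeded.
#' @return data.frame with columns `votu`, `cohort`, `prevalence`
#'   (percent) and `highly_prevalent` (the per-vOTU flag, repeated on
#'   each of its rows).
#' @export
prevalence <- function(detection, cohorts, min_prevalence = 5) {
  if (nrow(detection) != length(cohorts))
    stop("every sample needs a cohort label")
  votus <- colnames(detection)
  if (is.null(votus)) votus <- paste0("vOTU", seq_len(ncol(detection)))
  out <- list()
  for (ch in unique(cohorts)) {
    m <- detection[cohorts == ch, , drop = FALSE]
    out[[ch]] <- data.frame(votu = votus, cohort = ch,
                            prevalence = 100 * colMeans(m))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  flag <- tapply(res$prevalence, res$votu, function(p)
    any(p > min_prevalence))
  res$highly_prevalent <- as.logical(flag[res$votu])
  res
}
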