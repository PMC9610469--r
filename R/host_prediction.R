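# Host prediction for vOTUs by three routes — prophage-fragment matching,
# CRISPR spacer-protospacer matching, and co-abundance meta-analysis —
# plus their reconciliation (prophage evidence takes priority on
# phylum-level conflict).

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")

# Deepest shared lineage across rows of a taxonomy data.frame; ranks
# after the first disagreement are set to NA.
.consensus_lineage <- function(lin) {
  out <- lin[1L, .RANKS, drop = FALSE]
  for (i in seq_along(.RANKS)) {
    v <- lin[[.RANKS[i]]]
    if (length(unique(v[!is.na(v)])) != 1L || any(is.na(v))) {
      out[1L, .RANKS[i:length(.RANKS)]] <- NA_character_
      break
    }
  }
  out
}

.empty_prediction <- function() {
  cols <- c("votu", "method", .RANKS, "support")
  df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  df$support <- numeric()
  df
}

#' Host prediction from prophage host fragments
#'
#' Prophage-containing contigs carry flanking fragments of the host
#' genome. Fragments of at least `min_fragment_len` nt are compared to
#' microbial reference genomes; hits must reach `min_identity` percent
#' identity and `min_hit_len` alignment length. Each fragment is assigned
#' the reference target with maximal merged query coverage, and the
#' fragment assignments are aggregated per vOTU; vOTUs whose fragments
#' disagree at the host phylum level are disregarded. When a vOTU has
#' more than `max_fragments` fragments, a random subset of
#' `max_fragments` is analyzed (controlled by `seed`).
#'
#' @param fragments data.frame with columns `votu`, `fragment_id`,
#'   `length`.
#' @param hits data.frame with columns `fragment_id`, `target_id`,
#'   `identity`, `length`, `q_from`, `q_to`.
#' @param taxonomy data.frame mapping `target_id` to the seven rank
#'   columns `kingdom` ... `species`.
#' @param min_fragment_len,min_identity,min_hit_len filtering thresholds.
#' @param max_fragments fragment subsampling cap per vOTU.
#' @param seed RNG seed for fragment subsampling.
#' @return data.frame, one row per predicted vOTU, with the lineage
#'   columns and `support` = number of assigned fragments.
#' @export
predict_host_prophage <- function(fragments, hits, taxonomy,
                                  min_fragment_len = 1000L,
                                  min_identity = 95, min_hit_len = 1000L,
                                  max_fragments = 100L, seed = NULL) {
  out <- .empty_prediction()
  frags <- fragments[fragments$length >= min_fragment_len, , drop = FALSE]
  if (nrow(frags) == 0L) return(out)
  frags <- .with_seed(seed, {
    do.call(rbind, lapply(split(frags, frags$votu), function(f) {
      if (nrow(f) > max_fragments) f[sample.int(nrow(f), max_fragments), ]
      else f
    }))
  })
  h <- hits[hits$identity >= min_identity & hits$length >= min_hit_len &
              hits$fragment_id %in% frags$fragment_id, , drop = FALSE]
  if (nrow(h) == 0L) return(out)
  known <- h$target_id %in% taxonomy$target_id
  if (any(!known)) {
    warning("dropping hits to targets without taxonomy: ",
            paste(unique(h$target_id[!known]), collapse = ", "))
    h <- h[known, , drop = FALSE]
  }
  if (nrow(h) == 0L) return(out)

  # per fragment: target with maximal merged query coverage
  assign_one <- function(hf) {
    per_t <- split(hf, hf$target_id)
    cov <- vapply(per_t, function(x) .merged_width(x$q_from, x$q_to), 0L)
    names(per_t)[order(-cov, names(per_t))][1L]
  }
  frag_target <- vapply(split(h, h$fragment_id), assign_one, character(1))
  frag_votu <- frags$votu[match(names(frag_target), frags$fragment_id)]

  rows <- lapply(split(seq_along(frag_target), frag_votu), function(ii) {
    lin <- taxonomy[match(frag_target[ii], taxonomy$target_id), .RANKS]
    phy <- unique(lin$phylum)
    if (length(phy) > 1L) return(NULL)      # incompatible at phylum level
    cons <- .consensus_lineage(lin)
    cbind(data.frame(votu = frag_votu[ii][1L], method = "prophage"),
          cons, data.frame(support = length(ii)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(out)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Match CRISPR spacers against a phage genome
#'
#' Full-length matching of each spacer against both strands of the
#' genome, allowing up to `floor((1 - min_identity/100) * nchar(spacer))`
#' mismatches. Identity is computed over the full spacer length
#' (unaligned spacer positions would count as mismatches; this matcher
#' only emits full-length matches). The score is an internal
#' match/mismatch score (+2 / -3) used for ranking during deduplication.
#'
#' @param spacers named character vector of spacer sequences.
#' @param genome nucleotide string.
#' @param min_identity lowest identity (percent) worth reporting.
#' @return data.frame with columns `spacer_id`, `start`, `end`, `strand`,
#'   `identity_over_spacer`, `bitscore`, `full_length`.
#' @export
match_spacers <- function(spacers, genome, min_identity = 80) {
  g <- Biostrings::DNAString(.check_sequence(genome, "genome"))
  rows <- list()
  for (id in names(spacers)) {
    sp <- .check_sequence(spacers[[id]], id)
    len <- nchar(sp)
    max_mm <- floor((1 - min_identity / 100) * len)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sp else revcomp(sp)
      m <- Biostrings::matchPattern(pat, g, max.mismatch = max_mm)
      if (length(m) == 0L) next
      mm <- vapply(seq_along(m), function(i)
        Biostrings::neditAt(pat, g, at = BiocGenerics::start(m)[i]),
        integer(1))
      matches <- len - mm
      rows[[length(rows) + 1L]] <- data.frame(
        spacer_id = id,
        start = BiocGenerics::start(m), end = BiocGenerics::end(m),
        strand = strand,
        identity_over_spacer = 100 * matches / len,
        bitscore = 2 * matches - 3 * mm,
        full_length = TRUE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(spacer_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity_over_spacer = numeric(), bitscore = numeric(),
                      full_length = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Host prediction from CRISPR spacer-protospacer matches
#'
#' Matches are first deduplicated: among matches of multiple spacers of
#' one host to exactly the same phage region, and among matches of one
#' spacer to multiple regions, only the highest-bitscore match is kept.
#' A host is then linked to a vOTU if there is at least one full-length
#' match at >= `high_identity` percent identity over the spacer, or at
#' least `min_multi` deduplicated matches each at >= `low_identity`
#' percent. vOTUs linked to hosts from more than one phylum are
#' disregarded; otherwise the best-supported host (largest summed
#' bitscore) provides the lineage.
#'
#' @param matches data.frame with columns `votu`, `host_id`, `spacer_id`,
#'   `start`, `end`, `identity_over_spacer`, `bitscore`, `full_length`.
#' @param taxonomy data.frame mapping `host_id` to the seven rank
#'   columns.
#' @param high_identity single-match identity threshold (percent).
#' @param low_identity multi-match identity threshold (percent).
#' @param min_multi matches required on the low-identity route.
#' @return data.frame, one row per predicted vOTU, with lineage columns
#'   and `support` = number of deduplicated supporting matches.
#' @export
predict_host_crispr <- function(matches, taxonomy, high_identity = 95,
                                low_identity = 80, min_multi = 2L) {
  out <- .empty_prediction()
  if (is.null(matches) || nrow(matches) == 0L) return(out)
  m <- matches[matches$identity_over_spacer >= low_identity, , drop = FALSE]
  if (nrow(m) == 0L) return(out)

  # dedup 1: same phage region hit by several spacers of one host
  key1 <- paste(m$votu, m$host_id, m$start, m$end, sep = "\r")
  m <- do.call(rbind, lapply(split(m, key1), function(x)
    x[order(-x$bitscore, x$spacer_id)[1L], , drop = FALSE]))
  # dedup 2: same spacer hitting several regions of the phage genome
  key2 <- paste(m$votu, m$host_id, m$spacer_id, sep = "\r")
  m <- do.call(rbind, lapply(split(m, key2), function(x)
    x[order(-x$bitscore, x$start)[1L], , drop = FALSE]))

  linked <- lapply(split(m, paste(m$votu, m$host_id, sep = "\r")), function(x) {
    strong <- any(x$full_length & x$identity_over_spacer >= high_identity)
    multi <- nrow(x) >= min_multi
    if (strong || multi) x else NULL
  })
  linked <- linked[!vapply(linked, is.null, logical(1))]
  if (length(linked) == 0L) return(out)
  link_df <- do.call(rbind, linked)

  rows <- lapply(split(link_df, link_df$votu), function(x) {
    hosts <- unique(x$host_id)
    lin <- taxonomy[match(hosts, taxonomy$host_id), .RANKS]
    if (length(unique(lin$phylum)) > 1L) return(NULL)  # phylum conflict
    supp <- vapply(split(x$bitscore, x$host_id), sum, 0)
    best <- names(supp)[order(-supp, names(supp))][1L]
    cbind(data.frame(votu = x$votu[1L], method = "crispr"),
          taxonomy[match(best, taxonomy$host_id), .RANKS],
          data.frame(support = nrow(x)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(out)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Random-effects meta-analysis of per-cohort Spearman correlations
#'
#' Correlations are pooled on the Fisher z scale (`z = atanh(r)`,
#' variance `1/(n-3)`) with the Sidik-Jonkman between-cohort
#' heterogeneity estimator: initial `tau0^2 = mean((z - mean(z))^2)`;
#' weights `u = 1/(v/tau0^2 + 1)`; `tau^2 = sum(u*(z - mu_u)^2)/(k-1)`
#' with `mu_u` the u-weighted mean. The pooled z uses inverse-variance
#' weights `1/(v + tau^2)`; `tau0^2 = 0` (homogeneous inputs) falls back
#' to the fixed-effect pool, and a single cohort reduces to that cohort's
#' estimate. The p-value is two-sided normal.
#'
#' @param r numeric vector of per-cohort Spearman correlations.
#' @param n integer vector of per-cohort sample sizes; cohorts with
#'   `n <= 3` are dropped with a warning.
#' @return list with `k`, `pooled_r`, `z`, `se`, `tau2`, `p`.
#' @export
meta_correlation <- function(r, n) {
  if (length(r) != length(n)) stop("`r` and `n` differ in length")
  drop <- n <= 3
  if (any(drop)) {
    warning(sum(drop), " cohort(s) with n <= 3 dropped")
    r <- r[!drop]; n <- n[!drop]
  }
  k <- length(r)
  if (k == 0L) stop("no usable cohorts")
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z transform")
  z <- atanh(r)
  v <- 1 / (n - 3)
  if (k == 1L) {
    se <- sqrt(v)
    return(list(k = 1L, pooled_r = r, z = z, se = se, tau2 = 0,
                p = 2 * pnorm(-abs(z / se))))
  }
  tau0 <- mean((z - mean(z))^2)
  if (tau0 == 0) {
    w <- 1 / v
    tau2 <- 0
  } else {
    u <- 1 / (v / tau0 + 1)
    mu_u <- sum(u * z) / sum(u)
    tau2 <- sum(u * (z - mu_u)^2) / (k - 1)
    w <- 1 / (v + tau2)
  }
  zp <- sum(w * z) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(k = k, pooled_r = tanh(zp), z = zp, se = se, tau2 = tau2,
       p = 2 * pnorm(-abs(zp / se)))
}

#' Per-cohort Spearman correlations between taxa and vOTU abundances
#'
#' For each (taxon, vOTU) pair and each cohort, computes the Spearman
#' rank correlation (average ranks for ties) over that cohort's samples.
#' Taxa present (nonzero) in at most `min_samples` samples of a cohort
#' are skipped for that cohort.
#'
#' @param taxa,votus abundance matrices, samples x features, with
#'   matching rows.
#' @param cohorts cohort label per sample.
#' @param min_samples presence threshold (strictly exceeded).
#' @return data.frame with columns `taxon`, `votu`, `cohort`, `r`, `n`.
#' @export
cohort_spearman <- function(taxa, votus, cohorts, min_samples = 10L) {
  stopifnot(nrow(taxa) == nrow(votus), nrow(taxa) == length(cohorts))
  rows <- list()
  for (ch in unique(cohorts)) {
    sel <- cohorts == ch
    tm <- taxa[sel, , drop = FALSE]; vm <- votus[sel, , drop = FALSE]
    present <- colSums(tm > 0) > min_samples
    if (!any(present)) next
    rmat <- suppressWarnings(
      cor(apply(tm[, present, drop = FALSE], 2, rank),
          apply(vm, 2, rank)))
    g <- expand.grid(taxon = rownames(rmat), votu = colnames(rmat),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows[[ch]] <- data.frame(g, cohort = ch, r = as.vector(rmat),
                             n = sum(sel))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!is.na(out$r), , drop = FALSE]
}

#' Host prediction from co-abundance meta-analysis
#'
#' Runs [meta_correlation()] for every (taxon, vOTU) pair over its
#' cohorts, corrects the pooled p-values with Benjamini-Hochberg across
#' all pairs, and predicts each vOTU's host as the taxon with the minimal
#' FDR (ties by larger absolute pooled correlation, then lexicographic
#' taxon name).
#'
#' @param cors data.frame from [cohort_spearman()].
#' @return list with `table` (per-pair meta-analysis results with `fdr`)
#'   and `predictions` (per-vOTU best taxon with `pooled_r`, `p`, `fdr`).
#' @export
predict_host_coabundance <- function(cors) {
  if (is.null(cors) || nrow(cors) == 0L) stop("no correlations supplied")
  # shrink |r| = 1 away from the pole of the z transform
  cors$r <- pmax(pmin(cors$r, 0.999999), -0.999999)
  key <- paste(cors$taxon, cors$votu, sep = "\r")
  metas <- lapply(split(cors, key), function(x) {
    m <- meta_correlation(x$r, x$n)
    data.frame(taxon = x$taxon[1L], votu = x$votu[1L], k = m$k,
               pooled_r = m$pooled_r, tau2 = m$tau2, p = m$p)
  })
  tab <- do.call(rbind, metas)
  rownames(tab) <- NULL
  tab$fdr <- p.adjust(tab$p, method = "BH")
  preds <- do.call(rbind, lapply(split(tab, tab$votu), function(x) {
    x[order(x$fdr, -abs(x$pooled_r), x$taxon)[1L], , drop = FALSE]
  }))
  rownames(preds) <- NULL
  list(table = tab, predictions = preds)
}

#' Reconcile host predictions across methods
#'
#' Per vOTU: when prophage- and CRISPR-based predictions agree at the
#' host phylum level, the prophage lineage is reported with merged
#' support; when they conflict, the prophage prediction wins. A vOTU with
#' only one sequence-based prediction keeps it. The co-abundance
#' prediction is reported alongside with a flag stating whether its
#' taxon's phylum agrees with the reconciled call (`NA` when either side
#' is missing).
#'
#' @param prophage,crispr prediction data.frames from
#'   [predict_host_prophage()] / [predict_host_crispr()]; either may be
#'   empty.
#' @param coabundance optional predictions data.frame from
#'   [predict_host_coabundance()] with a `phylum` column (join the taxon
#'   lineage beforehand).
#' @return data.frame with the reconciled lineage per vOTU, `method`
#'   (`"prophage"`, `"crispr"` or `"prophage+crispr"`), and, when
#'   co-abundance is given, `coabundance_taxon` and `coabundance_agrees`.
#' @export
reconcile_hosts <- function(prophage, crispr, coabundance = NULL) {
  votus <- union(prophage$votu, crispr$votu)
  rows <- lapply(votus, function(v) {
    p <- prophage[prophage$votu == v, , drop = FALSE]
    c_ <- crispr[crispr$votu == v, , drop = FALSE]
    if (nrow(p) > 0L && nrow(c_) > 0L) {
      agree <- identical(p$phylum[1L], c_$phylum[1L])
      r <- p[1L, , drop = FALSE]
      r$method <- "prophage+crispr"
      if (!agree) r$method <- "prophage"      # prophage takes priority
      else r$support <- p$support[1L] + c_$support[1L]
      r
    } else if (nrow(p) > 0L) p[1L, , drop = FALSE]
    else c_[1L, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (!is.null(coabundance) && !is.null(out)) {
    m <- match(out$votu, coabundance$votu)
    out$coabundance_taxon <- coabundance$taxon[m]
    out$coabundance_agrees <- ifelse(
      is.na(m) | is.na(coabundance$phylum[m]) | is.na(out$phylum),
      NA, coabundance$phylum[m] == out$phylum)
  }
  if (is.null(out)) out <- .empty_prediction()
  rownames(out) <- NULL
  out
}
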