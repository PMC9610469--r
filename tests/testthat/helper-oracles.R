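# Independent oracles and small fixtures, built in code. These
# re-derive expected results by brute force, along paths separate from
# the package implementation they check.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_str <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Brute-force terminal-repeat oracle: compare every prefix length to the
# suffix (and to the reverse-complemented prefix) via substring equality.
oracle_terminal_repeats <- function(s, min_len = 20L) {
  L <- nchar(s)
  kmax <- L %/% 2L
  if (kmax < min_len) return(list(kind = "none", length = 0L))
  ks <- min_len:kmax
  pre <- substring(s, 1L, ks)
  suf <- substring(s, L - ks + 1L, L)
  dtr_k <- ks[pre == suf]
  dtr <- if (length(dtr_k) > 0L) max(dtr_k) else 0L
  rcs <- rc_str(s)
  itr_k <- ks[suf == substring(rcs, L - ks + 1L, L)]
  itr <- if (length(itr_k) > 0L) max(itr_k) else 0L
  if (dtr == 0L && itr == 0L) return(list(kind = "none", length = 0L))
  if (dtr >= itr) list(kind = "DTR", length = dtr)
  else list(kind = "ITR", length = itr)
}

# Brute-force greedy vOTU clustering: an independent re-execution of the
# rule using a dense pair lookup matrix.
oracle_cluster <- function(ani_records, lengths, min_ani = 95, min_cov = 85) {
  ids <- names(lengths)
  ord <- ids[order(-as.numeric(lengths), ids)]
  ani_m <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
  cov_m <- ani_m
  for (i in seq_len(nrow(ani_records))) {
    q <- ani_records$query_id[i]; t <- ani_records$target_id[i]
    ani_m[q, t] <- ani_m[t, q] <- ani_records$ani[i]
    cov_m[q, t] <- ani_records$query_cov[i]   # coverage of q in pair (q,t)
    cov_m[t, q] <- ani_records$target_cov[i]
  }
  centroids <- character()
  assign <- setNames(integer(length(ord)), ord)
  for (sq in ord) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      cen <- centroids[ci]
      if (!is.na(ani_m[sq, cen]) && ani_m[sq, cen] >= min_ani &&
          cov_m[sq, cen] >= min_cov) {
        assign[[sq]] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, sq)
      assign[[sq]] <- length(centroids)
    }
  }
  list(assign = assign, centroids = centroids)
}

# Random ANI-record instance for clustering tests.
random_ani_instance <- function(n_seq, seed) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n_seq))
  lengths <- setNames(sample(5000:50000, n_seq, replace = TRUE), ids)
  pairs <- t(combn(ids, 2L))
  keep <- runif(nrow(pairs)) < 0.4
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(query_id = pairs[, 1L], target_id = pairs[, 2L],
             ani = runif(nrow(pairs), 85, 100),
             query_cov = runif(nrow(pairs), 40, 100),
             target_cov = runif(nrow(pairs), 40, 100)) -> rec
  list(records = rec, lengths = lengths)
}

# Brute-force Benjamini-Hochberg via the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Independent transcription of the Fisher-z / Sidik-Jonkman pool.
oracle_meta <- function(r, n) {
  z <- atanh(r); v <- 1 / (n - 3); k <- length(r)
  if (k == 1L) return(list(pooled_r = r, tau2 = 0))
  t0 <- sum((z - mean(z))^2) / k
  if (t0 == 0) {
    w <- 1 / v
    return(list(pooled_r = tanh(sum(w * z) / sum(w)), tau2 = 0))
  }
  u <- 1 / (v / t0 + 1)
  mu <- sum(u * z) / sum(u)
  t2 <- sum(u * (z - mu)^2) / (k - 1)
  w <- 1 / (v + t2)
  list(pooled_r = tanh(sum(w * z) / sum(w)), tau2 = t2)
}

# Brute-force logistic maximum likelihood (BFGS on the deviance).
oracle_logistic <- function(y, X) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(b) {
    eta <- as.vector(X %*% b)
    as.vector(t(X) %*% (plogis(eta) - y))
  }
  fit <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# Mini seven-rank taxonomy table for host-prediction tests.
toy_taxonomy <- function(ids, phyla, genera = NULL) {
  data.frame(target_id = ids, host_id = ids,
             kingdom = "Bacteria", phylum = phyla,
             class = paste0(phyla, "_c"), order = paste0(phyla, "_o"),
             family = paste0(phyla, "_f"),
             genus = if (is.null(genera)) paste0(phyla, "_g") else genera,
             species = NA_character_)
}

# Independent re-derivation of the representative-selection rule.
oracle_representative <- function(members) {
  tr <- members[members$has_tr, , drop = FALSE]
  if (nrow(tr) > 0L) {
    med <- stats::median(tr$length)
    d <- abs(tr$length - med)
    cand <- tr[d == min(d), , drop = FALSE]
    cand <- cand[cand$length == min(cand$length), , drop = FALSE]
    return(sort(cand$seq_id)[1L])
  }
  pool <- if (any(members$has_terl))
    members[members$has_terl, , drop = FALSE] else members
  pool <- pool[pool$length == max(pool$length), , drop = FALSE]
  sort(pool$seq_id)[1L]
}
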