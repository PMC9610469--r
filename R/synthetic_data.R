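# Synthetic-data generators with planted ground truth. Every downstream
# stage of the pipeline can be exercised on these outputs: genomes with
# planted terminal repeats, recoded genes, DGR structures and
# protospacers; community abundance matrices with controlled
# taxon-phage rank correlation, longitudinal stability and phenotype
# effects; and per-position read-depth tracks with optional coverage
# dropout.

# spacer block carrying a TAA stop codon in all three frames on both
# strands (the string is its own reverse complement); placed between
# planted genes so open reading frames never run across gene boundaries
# under any of the candidate genetic codes
.STOP_WALL <- "TTAATTAATTAA"

.ALL_CODONS <- as.vector(outer(as.vector(outer(c("A","C","G","T"),
                                               c("A","C","G","T"), paste0)),
                               c("A","C","G","T"),
                               function(a, b) paste0(a, b)))

#' Specification of one synthetic phage genome
#'
#' @param length genome length (nt).
#' @param dtr_len,itr_len length of a planted direct / inverted terminal
#'   repeat (at most one may be set; `NULL` for none).
#' @param genetic_code 11, 4 or 15; planted genes use this code's stop
#'   reassignment (codes 4/15 place the reassigned codon internally as a
#'   sense codon, so the genes fragment under code 11).
#' @param n_genes number of planted protein-coding genes.
#' @param rt_gene plant a reverse-transcriptase gene (for DGR tests).
#' @param dgr_repeat_len length of a planted repeat pair; one copy lands
#'   close to the RT gene, the other far from it (requires `rt_gene`).
#' @param protospacers optional data.frame with columns `sequence` and
#'   `position` (1-based insertion start) of planted protospacers.
#' @param gc_fraction GC content of the background sequence.
#' @param seed RNG seed; identical specs give byte-identical genomes.
#' @return validated spec object (class `genome_sim_spec`).
#' @export
genome_sim_spec <- function(length, dtr_len = NULL, itr_len = NULL,
                            genetic_code = 11, n_genes = 0L,
                            rt_gene = FALSE, dgr_repeat_len = NULL,
                            protospacers = NULL, gc_fraction = 0.5,
                            seed = 1L) {
  if (!is.null(dtr_len) && !is.null(itr_len))
    stop("at most one of `dtr_len` / `itr_len` may be set")
  if (!is.null(dtr_len) && dtr_len < 0) stop("`dtr_len` must be >= 0")
  if (!is.null(itr_len) && itr_len < 0) stop("`itr_len` must be >= 0")
  if (!genetic_code %in% c(11, 4, 15))
    stop("`genetic_code` must be 11, 4 or 15")
  if (!is.null(dgr_repeat_len) && !rt_gene)
    stop("a DGR repeat pair requires `rt_gene = TRUE`")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("`gc_fraction` must lie in [0, 1]")
  structure(list(length = as.integer(length),
                 dtr_len = if (is.null(dtr_len)) NULL else as.integer(dtr_len),
                 itr_len = if (is.null(itr_len)) NULL else as.integer(itr_len),
                 genetic_code = as.integer(genetic_code),
                 n_genes = as.integer(n_genes),
                 rt_gene = isTRUE(rt_gene),
                 dgr_repeat_len = if (is.null(dgr_repeat_len)) NULL
                                  else as.integer(dgr_repeat_len),
                 protospacers = protospacers,
                 gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

.bg <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# One planted gene: ATG + sense codons + TAA. Sense codons exclude all
# three stop codons; under codes 4/15 the reassigned stop codon is
# sprinkled in as a sense codon at `recode_rate` so the gene fragments
# under code 11.
.sim_gene <- function(n_codons, code, recode_rate = 0.06) {
  sense <- setdiff(.ALL_CODONS, c("TAA", "TAG", "TGA"))
  codons <- sample(sense, n_codons, replace = TRUE)
  if (code == 15) {
    hit <- runif(n_codons) < recode_rate
    codons[hit] <- "TAG"
  } else if (code == 4) {
    hit <- runif(n_codons) < recode_rate
    codons[hit] <- "TGA"
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Generate a synthetic phage genome with planted ground truth
#'
#' The genome is i.i.d. background sequence at the requested GC fraction
#' into which the spec's elements are planted: terminal repeats copied
#' (or reverse-complemented) to both ends, genes laid out left to right
#' separated by stop-codon walls, an optional RT gene with a DGR repeat
#' pair (one copy ~100 nt from the RT gene, one far away), and
#' protospacers overwritten at their requested positions. An infeasible
#' spec (elements that do not fit, or protospacers colliding with
#' planted elements) is rejected.
#'
#' @param spec a [genome_sim_spec()].
#' @return list with `sequence` (nucleotide string), `truth` (data.frame
#'   of planted elements: `element`, `start`, `end`, `note`) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  .with_seed(spec$seed, {
    L <- spec$length
    gc <- spec$gc_fraction
    tr_len <- 0L
    tr_kind <- "none"
    if (!is.null(spec$dtr_len) && spec$dtr_len > 0L) {
      tr_len <- spec$dtr_len; tr_kind <- "DTR"
    } else if (!is.null(spec$itr_len) && spec$itr_len > 0L) {
      tr_len <- spec$itr_len; tr_kind <- "ITR"
    }
    interior_start <- tr_len + 1L
    interior_end <- L - tr_len
    if (interior_end - interior_start + 1L < 0L)
      stop("terminal repeats do not fit inside the genome")

    truth <- list()
    note_tr <- tolower(tr_kind)
    tr <- if (tr_len > 0L) .bg(tr_len, gc) else ""
    if (tr_len > 0L) {
      truth[[length(truth) + 1L]] <-
        data.frame(element = note_tr, start = 1L, end = tr_len, note = "5prime")
      truth[[length(truth) + 1L]] <-
        data.frame(element = note_tr, start = L - tr_len + 1L, end = L,
                   note = "3prime")
    }

    # lay out interior elements left to right
    pieces <- character()
    cursor <- interior_start
    emit <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      cursor <<- cursor + nchar(s)
    }
    emit(.bg(min(60L, max(0L, interior_end - cursor)), gc))

    n_genes <- spec$n_genes
    gene_codes <- rep(11L, n_genes)
    if (spec$genetic_code != 11L && n_genes > 0L)
      gene_codes[] <- spec$genetic_code
    for (i in seq_len(n_genes)) {
      emit(.STOP_WALL)
      g <- .sim_gene(sample(330:370, 1L), gene_codes[i])
      gs <- cursor
      emit(g)
      truth[[length(truth) + 1L]] <-
        data.frame(element = "gene", start = gs, end = cursor - 1L,
                   note = as.character(gene_codes[i]))
      emit(.STOP_WALL)
    }

    if (spec$rt_gene) {
      emit(.STOP_WALL)
      g <- .sim_gene(300L, 11L)
      gs <- cursor
      emit(g)
      truth[[length(truth) + 1L]] <-
        data.frame(element = "rt_gene", start = gs, end = cursor - 1L,
                   note = "RT")
      emit(.STOP_WALL)
      if (!is.null(spec$dgr_repeat_len)) {
        rep_seq <- .bg(spec$dgr_repeat_len, gc)
        emit(.bg(100L, gc))                     # proximal copy, gap ~100 nt
        rs <- cursor
        emit(rep_seq)
        truth[[length(truth) + 1L]] <-
          data.frame(element = "dgr_repeat", start = rs, end = cursor - 1L,
                     note = "proximal")
        gap_far <- min(3000L, max(200L, interior_end - cursor -
                                    spec$dgr_repeat_len - 300L))
        emit(.bg(gap_far, gc))                  # distal copy
        rs <- cursor
        emit(rep_seq)
        truth[[length(truth) + 1L]] <-
          data.frame(element = "dgr_repeat", start = rs, end = cursor - 1L,
                     note = "distal")
      }
    }

    if (cursor > interior_end + 1L)
      stop("infeasible spec: planted elements exceed the genome length")
    emit(.bg(interior_end - cursor + 1L, gc))

    suffix <- if (tr_kind == "DTR") tr
              else if (tr_kind == "ITR") revcomp(tr)
              else ""
    sequence <- paste0(tr, paste(pieces, collapse = ""), suffix)
    stopifnot(nchar(sequence) == L)

    truth_df <- if (length(truth) > 0L) do.call(rbind, truth)
                else data.frame(element = character(), start = integer(),
                                end = integer(), note = character())

    if (!is.null(spec$protospacers) && nrow(spec$protospacers) > 0L) {
      occupied <- truth_df[truth_df$element != "none", , drop = FALSE]
      for (i in seq_len(nrow(spec$protospacers))) {
        ps <- spec$protospacers$sequence[i]
        pos <- spec$protospacers$position[i]
        pe <- pos + nchar(ps) - 1L
        if (pos < 1L || pe > L)
          stop("infeasible spec: protospacer outside the genome")
        clash <- any(pmax(occupied$start, pos) <= pmin(occupied$end, pe))
        if (clash)
          stop("infeasible spec: protospacer overlaps a planted element")
        substr(sequence, pos, pe) <- toupper(ps)
        truth_df <- rbind(truth_df,
                          data.frame(element = "protospacer", start = pos,
                                     end = pe, note = as.character(i)))
        occupied <- rbind(occupied, truth_df[nrow(truth_df), ])
      }
    }
    list(sequence = sequence, truth = truth_df, spec = spec)
  })
}

#' Specification of a synthetic phage-host community
#'
#' @param n_individuals number of individuals.
#' @param n_timepoints 1 or 2 (2 gives longitudinal pairs).
#' @param n_votus,n_taxa numbers of phage vOTUs and microbial taxa.
#' @param coupling optional data.frame with columns `taxon`, `votu`
#'   (names or indices) and `rho` (target Spearman correlation between
#'   the pair's abundances); each vOTU may appear at most once.
#' @param stability_sigma SD of the multiplicative log-normal noise
#'   between the two timepoints (0 = identical profiles).
#' @param phenotype_effects optional data.frame with columns `phenotype`,
#'   `target_type` (`"taxon"` or `"votu"`), `target`, `effect` (log-odds
#'   or linear slope) and `type` (`"binary"` or `"continuous"`).
#' @param seed RNG seed.
#' @return validated spec object (class `community_sim_spec`).
#' @export
community_sim_spec <- function(n_individuals, n_timepoints = 1L, n_votus,
                               n_taxa, coupling = NULL,
                               stability_sigma = 0,
                               phenotype_effects = NULL, seed = 1L) {
  if (!n_timepoints %in% c(1L, 2L)) stop("`n_timepoints` must be 1 or 2")
  if (stability_sigma < 0) stop("`stability_sigma` must be >= 0")
  if (!is.null(coupling)) {
    if (any(abs(coupling$rho) > 1)) stop("target rho must lie in [-1, 1]")
    if (anyDuplicated(coupling$votu))
      stop("each vOTU may be coupled to at most one taxon")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_timepoints = as.integer(n_timepoints),
                 n_votus = as.integer(n_votus),
                 n_taxa = as.integer(n_taxa),
                 coupling = coupling,
                 stability_sigma = stability_sigma,
                 phenotype_effects = phenotype_effects,
                 seed = as.integer(seed)),
            class = "community_sim_spec")
}

#' Generate a synthetic phage-host community
#'
#' Log-abundances are standard normal latent variables per individual;
#' coupled (taxon, vOTU) pairs share a Gaussian copula whose Pearson
#' correlation `2*sin(pi*rho/6)` yields the target Spearman `rho` in the
#' large-sample limit. The second timepoint adds N(0, stability_sigma)
#' noise on the log scale to every feature. vOTU detection is defined as
#' a positive latent (about 50% prevalence). Phenotypes are built from
#' linear predictors on the latent log host abundance (host-mediated
#' effects) or on phage detection (direct effects); binary phenotypes
#' are Bernoulli draws through the logistic link, continuous ones add
#' unit normal noise.
#'
#' @param spec a [community_sim_spec()].
#' @return list with matrices `taxa`, `votus` (abundances, samples x
#'   features), `detection` (logical), `metadata` (sample_id,
#'   individual, timepoint, age, sex), `phenotypes` (data.frame, one row
#'   per sample) and `spec`.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_sim_spec"))
  .with_seed(spec$seed, {
    ni <- spec$n_individuals; nt <- spec$n_timepoints
    nv <- spec$n_votus; nx <- spec$n_taxa
    taxa_names <- sprintf("taxon_%03d", seq_len(nx))
    votu_names <- sprintf("vOTU_%03d", seq_len(nv))

    zt <- matrix(rnorm(ni * nx), ni, nx, dimnames = list(NULL, taxa_names))
    zv <- matrix(rnorm(ni * nv), ni, nv, dimnames = list(NULL, votu_names))
    if (!is.null(spec$coupling) && nrow(spec$coupling) > 0L) {
      for (i in seq_len(nrow(spec$coupling))) {
        tx <- spec$coupling$taxon[i]; vt <- spec$coupling$votu[i]
        if (is.numeric(tx)) tx <- taxa_names[tx]
        if (is.numeric(vt)) vt <- votu_names[vt]
        rho_l <- 2 * sin(pi * spec$coupling$rho[i] / 6)
        zv[, vt] <- rho_l * zt[, tx] + sqrt(1 - rho_l^2) * zv[, vt]
      }
    }

    mk_tp <- function(z, sigma) z + matrix(rnorm(length(z), sd = sigma),
                                           nrow(z), ncol(z))
    z_taxa <- list(zt); z_votu <- list(zv)
    if (nt == 2L) {
      z_taxa[[2L]] <- mk_tp(zt, spec$stability_sigma)
      z_votu[[2L]] <- mk_tp(zv, spec$stability_sigma)
    }
    taxa <- exp(do.call(rbind, z_taxa))
    votus <- exp(do.call(rbind, z_votu))
    detection <- do.call(rbind, z_votu) > 0
    sample_id <- unlist(lapply(seq_len(nt), function(tp)
      sprintf("I%04d_T%d", seq_len(ni), tp)))
    rownames(taxa) <- rownames(votus) <- rownames(detection) <- sample_id

    age <- round(rnorm(ni, 45, 12))
    sex <- rbinom(ni, 1L, 0.5)
    metadata <- data.frame(sample_id = sample_id,
                           individual = rep(seq_len(ni), nt),
                           timepoint = rep(seq_len(nt), each = ni),
                           age = rep(age, nt), sex = rep(sex, nt))

    phen <- data.frame(row.names = sample_id)
    pe <- spec$phenotype_effects
    if (!is.null(pe) && nrow(pe) > 0L) {
      for (ph in unique(pe$phenotype)) {
        rowsp <- pe[pe$phenotype == ph, , drop = FALSE]
        lp <- numeric(ni)
        for (j in seq_len(nrow(rowsp))) {
          tg <- rowsp$target[j]
          pred <- if (rowsp$target_type[j] == "taxon") {
            if (is.numeric(tg)) tg <- taxa_names[as.integer(tg)]
            zt[, tg]
          } else {
            if (is.numeric(tg)) tg <- votu_names[as.integer(tg)]
            as.numeric(zv[, tg] > 0) - 0.5   # centered detection
          }
          lp <- lp + rowsp$effect[j] * pred
        }
        val <- if (rowsp$type[1L] == "continuous") lp + rnorm(ni)
               else rbinom(ni, 1L, plogis(lp))
        phen[[ph]] <- rep(val, nt)
      }
    }
    list(taxa = taxa, votus = votus, detection = detection,
         metadata = metadata, phenotypes = phen, spec = spec)
  })
}

#' Specification of a synthetic read-depth track
#'
#' @param genome_length genome length (nt).
#' @param n_reads number of reads to place.
#' @param read_length read length (nt); must not exceed the genome.
#' @param dropout_interval optional `c(start, end)` region receiving no
#'   coverage (emulating the recombination-associated coverage anomaly
#'   seen in some prevalent phage genomes).
#' @param seed RNG seed.
#' @return validated spec object (class `depth_sim_spec`).
#' @export
depth_sim_spec <- function(genome_length, n_reads, read_length,
                           dropout_interval = NULL, seed = 1L) {
  if (read_length > genome_length)
    stop("`read_length` must not exceed `genome_length`")
  if (n_reads < 0L) stop("`n_reads` must be >= 0")
  structure(list(genome_length = as.integer(genome_length),
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 dropout_interval = dropout_interval,
                 seed = as.integer(seed)),
            class = "depth_sim_spec")
}

#' Generate a per-position read-depth track
#'
#' Read start positions are uniform on the genome; reads are truncated at
#' the 3' end. Without dropout the total depth mass equals
#' `n_reads * read_length` minus that truncation. Positions inside the
#' dropout interval are zeroed after accumulation (an unmappable
#' region).
#'
#' @param spec a [depth_sim_spec()].
#' @return list with `depth` (data.frame `pos`, `depth`, covered
#'   positions only), `n_reads`, and `genome_length`.
#' @export
generate_depth <- function(spec) {
  stopifnot(inherits(spec, "depth_sim_spec"))
  .with_seed(spec$seed, {
    L <- spec$genome_length
    depth <- integer(L)
    if (spec$n_reads > 0L) {
      starts <- sample.int(L, spec$n_reads, replace = TRUE)
      ends <- pmin(starts + spec$read_length - 1L, L)
      inc <- tabulate(starts, L)
      dec <- tabulate(ends + 1L, L + 1L)   # reads ending just before p
      depth <- cumsum(inc - dec[seq_len(L)])
    }
    if (!is.null(spec$dropout_interval)) {
      di <- spec$dropout_interval
      depth[di[1L]:di[2L]] <- 0L
    }
    covered <- which(depth > 0L)
    list(depth = data.frame(pos = covered, depth = depth[covered]),
         n_reads = spec$n_reads, genome_length = L)
  })
}
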