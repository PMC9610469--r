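# End-to-end orchestration of the pipeline stages on synthetic inputs,
# with a single configuration object holding every stage threshold at
# its standard default, per-stage output tables, and a JSON run manifest
# recording parameters, seeds and output digests.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' terminal repeats >= 20 nt; self-repeats >= 100 nt at >= 80% identity;
#' DGR proximity 1000 nt; alternative genetic codes only for sequences
#' >= 20 kb whose score exceeds the standard code by > 10%; protein
#' annotation coverage >= 100 aa at E-value <= 0.001; vOTU clustering at
#' ANI >= 95% with >= 85% member coverage; detection at breadth >= 75%;
#' high prevalence > 5%; stability test with 10,000 permutations; CRISPR
#' linking at 95% single- / 80% multi-match identity; prophage fragments
#' >= 1000 nt at >= 95% identity; significance at FDR < 0.05.
#'
#' @param ... named overrides of any default.
#' @return list of parameters (class `phagetr_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_tr_len = 20L,
    skew_window = 1001L, skew_step = 200L,
    repeat_min_len = 100L, repeat_min_identity = 80,
    dgr_proximity = 1000L,
    code_margin = 0.10, code_min_len = 20000L, orf_min_len = 300L,
    annot_min_cov = 100L, max_evalue = 0.001,
    min_ani = 95, min_cov = 85,
    min_breadth = 75, min_prevalence = 5,
    stability_iterations = 10000L,
    crispr_high_identity = 95, crispr_low_identity = 80, crispr_min_multi = 2L,
    fragment_min_len = 1000L, fragment_min_identity = 95,
    fdr_threshold = 0.05,
    # synthetic-scenario sizes used by run_pipeline()
    n_genomes = 6L, genome_length = 25000L,
    n_individuals = 60L, n_timepoints = 2L, n_votus = 40L, n_taxa = 12L,
    stability_sigma = 0.3,
    seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("phagetr_config", "list"))
}

#' Run the pipeline end to end on synthetic data
#'
#' Simulates a set of phage genomes (with planted terminal repeats,
#' alternative-code genes and a DGR structure) and a longitudinal
#' community, then runs every stage in dependency order: genome features
#' (terminal repeats, skew, self-repeats, DGR candidates), genetic-code
#' assignment, pairwise-ANI vOTU clustering, abundance simulation with
#' the breadth gate, prevalence, the stability permutation test,
#' co-abundance host prediction, and the phage-phenotype association
#' scan. Per-stage TSV outputs and a JSON manifest (parameters, seed,
#' file digests, session versions) are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(config, "phagetr_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- simulate genomes -------------------------------------------------
  # phage genomes are coding-dense; pack genes to ~85% of the length
  gl <- config$genome_length
  ng <- as.integer((gl - 1500L) %/% 1150L)
  specs <- list(
    genome_sim_spec(gl, dtr_len = 150L, n_genes = ng, seed = seed + 1L),
    genome_sim_spec(gl, itr_len = 120L, n_genes = ng, seed = seed + 2L),
    genome_sim_spec(gl, dtr_len = 100L, genetic_code = 15L,
                    n_genes = ng, seed = seed + 3L),
    genome_sim_spec(gl, dtr_len = 100L, genetic_code = 4L,
                    n_genes = ng, seed = seed + 4L),
    genome_sim_spec(gl, dtr_len = 80L, n_genes = ng - 2L,
                    rt_gene = TRUE, dgr_repeat_len = 140L, seed = seed + 5L),
    genome_sim_spec(gl, n_genes = ng, seed = seed + 6L))
  specs <- specs[seq_len(min(config$n_genomes, length(specs)))]
  genomes <- lapply(specs, generate_genome)
  names(genomes) <- sprintf("genome_%02d", seq_along(genomes))
  seqs <- vapply(genomes, `[[`, character(1), "sequence")
  write_genome_fasta(seqs, file.path(out_dir, "genomes.fasta"))

  # --- genome features --------------------------------------------------
  feats <- lapply(names(genomes), function(id) {
    s <- genomes[[id]]$sequence
    tr <- detect_terminal_repeats(s, config$min_tr_len)
    reps <- find_self_repeats(s, config$repeat_min_len,
                              config$repeat_min_identity)
    rt <- genomes[[id]]$truth
    rt <- rt[rt$element == "rt_gene", c("start", "end"), drop = FALSE]
    dgr <- detect_dgr_candidates(reps, rt, config$dgr_proximity,
                                 terminal_repeat = tr,
                                 genome_length = nchar(s))
    list(id = id, tr = tr, repeats = reps, dgr = dgr)
  })
  tr_tab <- do.call(rbind, lapply(feats, function(f)
    data.frame(genome = f$id, tr_kind = f$tr$kind, tr_length = f$tr$length)))
  write_tsv(tr_tab, file.path(out_dir, "terminal_repeats.tsv"))
  rep_tab <- do.call(rbind, lapply(feats, function(f)
    if (nrow(f$repeats) > 0L) cbind(genome = f$id, f$repeats) else NULL))
  if (!is.null(rep_tab))
    write_tsv(rep_tab, file.path(out_dir, "self_repeats.tsv"))
  dgr_tab <- do.call(rbind, lapply(feats, function(f)
    if (nrow(f$dgr) > 0L) cbind(genome = f$id, f$dgr) else NULL))
  if (!is.null(dgr_tab))
    write_tsv(dgr_tab, file.path(out_dir, "dgr_candidates.tsv"))
  skew_tab <- do.call(rbind, lapply(names(genomes), function(id)
    cbind(genome = id, skew_profile(genomes[[id]]$sequence,
                                    config$skew_window, config$skew_step))))
  write_tsv(skew_tab, file.path(out_dir, "skew.tsv"))

  # --- genetic code -----------------------------------------------------
  code_tab <- do.call(rbind, lapply(names(genomes), function(id) {
    a <- assign_genetic_code(genomes[[id]]$sequence,
                             margin = config$code_margin,
                             min_eligible_len = config$code_min_len,
                             min_orf_len = config$orf_min_len)
    data.frame(genome = id, s11 = a$scores[["11"]], s4 = a$scores[["4"]],
               s15 = a$scores[["15"]], assigned_code = a$assigned_code)
  }))
  write_tsv(code_tab, file.path(out_dir, "genetic_codes.tsv"))

  # --- vOTU clustering --------------------------------------------------
  ids <- names(seqs)
  lens <- nchar(seqs); names(lens) <- ids
  ani_rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    al <- align_pair(seqs[[i]], seqs[[j]], min_len = config$repeat_min_len,
                     min_identity = config$repeat_min_identity)
    ani <- compute_ani(al, lens[[i]], lens[[j]])
    if (!is.na(ani$ani))
      ani_rows[[length(ani_rows) + 1L]] <- data.frame(
        query_id = ids[i], target_id = ids[j], ani = ani$ani,
        query_cov = ani$query_cov, target_cov = ani$target_cov)
  }
  ani_records <- if (length(ani_rows) > 0L) do.call(rbind, ani_rows)
                 else data.frame(query_id = character(), target_id = character(),
                                 ani = numeric(), query_cov = numeric(),
                                 target_cov = numeric())
  votus_tab <- cluster_votus(ani_records, lens, config$min_ani, config$min_cov)
  write_tsv(votus_tab, file.path(out_dir, "votus.tsv"))

  # --- community, quantification, stability -----------------------------
  nv <- config$n_votus
  coupling <- data.frame(taxon = 1L, votu = 1L, rho = 0.6)
  comm <- generate_community(community_sim_spec(
    config$n_individuals, config$n_timepoints, nv, config$n_taxa,
    coupling = coupling, stability_sigma = config$stability_sigma,
    phenotype_effects = data.frame(phenotype = "pheno_host",
                                   target_type = "taxon", target = 1L,
                                   effect = 1.0, type = "binary"),
    seed = seed + 10L))
  abund <- comm$votus * comm$detection       # breadth-gated analog
  write_tsv(data.frame(sample_id = rownames(abund), abund),
            file.path(out_dir, "abundance.tsv"))
  prev <- prevalence(comm$detection, rep("synthetic", nrow(comm$detection)),
                     config$min_prevalence)
  write_tsv(prev, file.path(out_dir, "prevalence.tsv"))

  stab <- NULL
  if (config$n_timepoints == 2L) {
    pairs <- pair_dissimilarities(abund, comm$metadata)
    stab <- stability_test(pairs, config$stability_iterations,
                           seed = seed + 20L)
    write_tsv(data.frame(observed_p = stab$observed_p,
                         empirical_p = stab$empirical_p,
                         iterations = stab$iterations,
                         n_intra = stab$n_intra, n_inter = stab$n_inter),
              file.path(out_dir, "stability.tsv"))
  }

  # --- host prediction (co-abundance) -----------------------------------
  cohorts <- rep(c("A", "B", "C"), length.out = nrow(comm$taxa))
  min_present <- min(10L, min(table(cohorts)) - 2L)
  cors <- cohort_spearman(comm$taxa, comm$votus, cohorts,
                          min_samples = min_present)
  coab <- predict_host_coabundance(cors)
  write_tsv(coab$predictions, file.path(out_dir, "host_coabundance.tsv"))

  # --- association scan -------------------------------------------------
  t1 <- comm$metadata$timepoint == 1L
  host_ab <- matrix(comm$taxa[t1, 1L], sum(t1), 1L,
                    dimnames = list(NULL, "vOTU_001"))
  assoc <- association_scan(comm$detection[t1, , drop = FALSE],
                            comm$phenotypes[t1, , drop = FALSE],
                            comm$metadata[t1, c("age", "sex")],
                            host_abundance = host_ab,
                            fdr_threshold = config$fdr_threshold)
  write_tsv(assoc, file.path(out_dir, "associations.tsv"))

  # --- manifest ---------------------------------------------------------
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "phagetr",
    version = as.character(utils::packageVersion("phagetr")),
    r_version = R.version.string,
    seed = seed,
    parameters = unclass(config),
    outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
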