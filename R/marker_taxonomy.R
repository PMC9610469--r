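# Decision rules over profile-search and nucleotide-search hit tables:
# protein annotation by envelope coverage, TerL-motif-anchored taxonomy
# with the Herpesviridae override, rRNA contamination screening, plasmid
# flagging, and reference-similarity coverage filtering.

# Marker groups recognized by assign_taxon(); `group` values of the
# taxonomy call. TerL is the Caudoviricetes marker and the only one whose
# hits carry motif-column flags.
.MARKER_GROUPS <- c("TerL", "Herpesviridae_MCP", "Papillomaviridae_L1",
                    "Polyomaviridae_coat", "Adenoviridae_hexon",
                    "Tectiliviricetes_MCP", "Nucleocytoviricota_marker")

#' Merged residue coverage of a set of intervals
#'
#' Length of the union of 1-based inclusive intervals (overlaps combined),
#' as used to measure how much of a protein is covered by hits to one
#' profile (HMMER envelope coordinates).
#'
#' @param from,to integer vectors of interval bounds.
#' @return covered residue count.
#' @export
merged_coverage <- function(from, to) {
  if (length(from) != length(to)) stop("`from` and `to` differ in length")
  if (any(from > to)) stop("intervals must satisfy from <= to")
  .merged_width(as.integer(from), as.integer(to))
}

#' Annotate a protein with its best-covering profile
#'
#' Among profiles whose hits cover at least `min_cov` residues of the
#' protein (merged envelope coordinates), the profile with maximal
#' coverage wins; ties break by lowest E-value, then lexicographic
#' profile id. Hits above the E-value threshold are ignored.
#'
#' @param hits data.frame with columns `profile_id`, `env_from`, `env_to`,
#'   `evalue`, all for one protein.
#' @param min_cov minimum merged coverage (aa residues).
#' @param max_evalue retention threshold on hit E-values.
#' @return profile id (character) or `NA_character_` when no profile
#'   qualifies.
#' @export
annotate_protein <- function(hits, min_cov = 100L, max_evalue = 0.001) {
  if (is.null(hits) || nrow(hits) == 0L) return(NA_character_)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(NA_character_)
  prof <- split(hits, hits$profile_id)
  cov <- vapply(prof, function(h) merged_coverage(h$env_from, h$env_to), 0)
  best_e <- vapply(prof, function(h) min(h$evalue), 0)
  ok <- cov >= min_cov
  if (!any(ok)) return(NA_character_)
  ids <- names(prof)[ok]; cov <- cov[ok]; best_e <- best_e[ok]
  o <- order(-cov, best_e, ids)
  ids[o[1L]]
}

#' Taxonomic assignment from marker-protein hits
#'
#' Applies the marker decision logic for seven dsDNA virus groups.
#' Caudoviricetes requires a TerL hit whose alignment spans all three
#' diagnostic motif columns (second acidic residue of the Walker B motif,
#' first acidic residue of nuclease motif I, the acidic residue of
#' nuclease motif II). A Herpesviridae MCP hit on the same sequence
#' overrides TerL, herpesviruses carrying an evolutionarily related
#' terminase. Papillomaviridae, Polyomaviridae, Adenoviridae and
#' Tectiliviricetes are called from their single markers.
#' Nucleocytoviricota additionally requires an external validation score
#' > 2 with at least one marker recovered by the validator. Conflicting
#' non-TerL markers yield `"unassigned"` with a warning.
#'
#' @param sequence_id sequence identifier.
#' @param hits data.frame with columns `marker_group` (one of `TerL`,
#'   `Herpesviridae_MCP`, `Papillomaviridae_L1`, `Polyomaviridae_coat`,
#'   `Adenoviridae_hexon`, `Tectiliviricetes_MCP`,
#'   `Nucleocytoviricota_marker`), `evalue`, and for TerL hits the
#'   logical motif flags `walkerb_acidic2`, `nuc1_acidic1`,
#'   `nuc2_acidic`.
#' @param ncv_score optional external whole-contig validation score used
#'   to gate Nucleocytoviricota calls.
#' @param ncv_markers_recovered number of markers the external validator
#'   recovered.
#' @param max_evalue retention threshold on hit E-values.
#' @return list with `sequence_id`, `group`, and `evidence` (the retained
#'   hits supporting the call).
#' @export
assign_taxon <- function(sequence_id, hits, ncv_score = NA_real_,
                         ncv_markers_recovered = 0L, max_evalue = 0.001) {
  group <- "unassigned"
  evidence <- hits[0, , drop = FALSE]
  if (!is.null(hits) && nrow(hits) > 0L) {
    bad <- setdiff(unique(hits$marker_group), .MARKER_GROUPS)
    if (length(bad) > 0L)
      stop("unknown marker group(s): ", paste(bad, collapse = ", "))
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  }
  if (!is.null(hits) && nrow(hits) > 0L) {
    terl <- hits[hits$marker_group == "TerL", , drop = FALSE]
    terl_complete <- FALSE
    if (nrow(terl) > 0L) {
      fl <- c("walkerb_acidic2", "nuc1_acidic1", "nuc2_acidic")
      if (!all(fl %in% names(terl)) ||
          any(is.na(terl[, fl])))
        stop("TerL hits must carry the three motif flags")
      terl_complete <- any(terl$walkerb_acidic2 & terl$nuc1_acidic1 &
                             terl$nuc2_acidic)
    }
    present <- function(g) any(hits$marker_group == g)
    others <- character()
    if (present("Herpesviridae_MCP")) others <- c(others, "Herpesviridae")
    if (present("Papillomaviridae_L1")) others <- c(others, "Papillomaviridae")
    if (present("Polyomaviridae_coat")) others <- c(others, "Polyomaviridae")
    if (present("Adenoviridae_hexon")) others <- c(others, "Adenoviridae")
    if (present("Tectiliviricetes_MCP")) others <- c(others, "Tectiliviricetes")
    if (present("Nucleocytoviricota_marker") && !is.na(ncv_score) &&
        ncv_score > 2 && ncv_markers_recovered >= 1L)
      others <- c(others, "Nucleocytoviricota")
    if (length(others) > 1L) {
      warning(sprintf("sequence %s: conflicting non-TerL markers (%s); unassigned",
                      sequence_id, paste(others, collapse = ", ")))
      group <- "unassigned"
    } else if (length(others) == 1L) {
      group <- others
      evidence <- hits[hits$marker_group != "TerL", , drop = FALSE]
    } else if (terl_complete) {
      group <- "Caudoviricetes"
      evidence <- terl
    }
  }
  list(sequence_id = sequence_id, group = group, evidence = evidence)
}

#' Screen a sequence for rRNA contamination and plasmid character
#'
#' A sequence is flagged rRNA-contaminated if hits to any rRNA gene cover
#' more than half of that gene's length (merged intervals), and flagged a
#' potential plasmid if its external plasmid classifier score strictly
#' exceeds 0.9. The two flags are independent.
#'
#' @param sequence_id sequence identifier.
#' @param rrna_hits data.frame with columns `gene_id`, `from`, `to`
#'   (coordinates on the rRNA gene) and `gene_length`; may be empty.
#' @param plasx_score optional plasmid classifier score.
#' @param min_gene_fraction fraction of the gene length that must be
#'   covered to call contamination (strictly exceeded).
#' @param min_plasx plasmid score threshold (strictly exceeded).
#' @return list with `sequence_id`, `rrna_contaminated`, `plasmid_flag`.
#' @export
screen_sequence <- function(sequence_id, rrna_hits = NULL,
                            plasx_score = NA_real_,
                            min_gene_fraction = 0.5, min_plasx = 0.9) {
  contaminated <- FALSE
  if (!is.null(rrna_hits) && nrow(rrna_hits) > 0L) {
    per_gene <- split(rrna_hits, rrna_hits$gene_id)
    contaminated <- any(vapply(per_gene, function(h)
      merged_coverage(h$from, h$to) > min_gene_fraction * h$gene_length[1L],
      logical(1)))
  }
  plasmid <- !is.na(plasx_score) && plasx_score > min_plasx
  list(sequence_id = sequence_id, rrna_contaminated = contaminated,
       plasmid_flag = plasmid)
}

#' Filter query-target pairs by reciprocal alignment coverage
#'
#' Retains query-target pairs whose merged alignments cover at least
#' `min_query_frac` of the query length and `min_target_frac` of the
#' target length, the coverage filter used when relating novel genomes to
#' extensively characterized reference phages.
#'
#' @param hits data.frame with columns `query_id`, `target_id`, `q_from`,
#'   `q_to`, `t_from`, `t_to`.
#' @param query_lengths,target_lengths named numeric vectors mapping
#'   sequence ids to lengths.
#' @param min_query_frac,min_target_frac minimum coverage fractions.
#' @return data.frame of retained pairs with columns `query_id`,
#'   `target_id`, `query_cov`, `target_cov` (percent).
#' @export
filter_reference_matches <- function(hits, query_lengths, target_lengths,
                                     min_query_frac = 0.10,
                                     min_target_frac = 0.50) {
  empty <- data.frame(query_id = character(), target_id = character(),
                      query_cov = numeric(), target_cov = numeric())
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  key <- paste(hits$query_id, hits$target_id, sep = "\r")
  per_pair <- split(hits, key)
  rows <- lapply(per_pair, function(h) {
    qid <- h$query_id[1L]; tid <- h$target_id[1L]
    qcov <- merged_coverage(h$q_from, h$q_to) / query_lengths[[qid]]
    tcov <- merged_coverage(h$t_from, h$t_to) / target_lengths[[tid]]
    data.frame(query_id = qid, target_id = tid,
               query_cov = 100 * qcov, target_cov = 100 * tcov)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$query_cov >= 100 * min_query_frac &
        out$target_cov >= 100 * min_target_frac, , drop = FALSE]
}
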