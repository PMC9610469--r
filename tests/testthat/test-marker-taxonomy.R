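test_that("merged coverage unions intervals", {
  expect_equal(merged_coverage(c(1L, 50L), c(60L, 120L)), 120L)
  expect_equal(merged_coverage(c(1L, 200L), c(50L, 248L)), 99L)
  expect_equal(merged_coverage(10L, 110L), 101L)
})

test_that("merged coverage equals brute-force position counting", {
  set.seed(15)
  for (i in 1:1000) {
    n <- sample(1:6, 1L)
    from <- sample(1:300, n, replace = TRUE)
    to <- from + sample(0:80, n, replace = TRUE)
    brute <- length(unique(unlist(mapply(seq, from, to, SIMPLIFY = FALSE))))
    expect_identical(merged_coverage(from, to), brute)
  }
})

test_that("protein annotation picks the maximal-coverage profile", {
  hits <- data.frame(
    profile_id = c("A", "B", "B"),
    env_from = c(1L, 1L, 100L), env_to = c(120L, 80L, 169L),
    evalue = 1e-10)
  expect_equal(annotate_protein(hits), "B")   # 150 vs 120

  one <- data.frame(profile_id = "A", env_from = 1L, env_to = 99L,
                    evalue = 1e-10)
  expect_true(is.na(annotate_protein(one)))   # 99 aa misses the floor
  expect_true(is.na(annotate_protein(one[0, ])))

  # coverage tie broken by E-value, then id
  tie <- data.frame(profile_id = c("B", "A"),
                    env_from = 1L, env_to = 150L,
                    evalue = c(1e-5, 1e-9))
  expect_equal(annotate_protein(tie), "A")
  tie$evalue <- 1e-7
  expect_equal(annotate_protein(tie), "A")
  # hits above the E-value threshold are discarded at parse time
  late <- data.frame(profile_id = "A", env_from = 1L, env_to = 150L,
                     evalue = 0.01)
  expect_true(is.na(annotate_protein(late)))
})

terl_hit <- function(w = TRUE, n1 = TRUE, n2 = TRUE)
  data.frame(marker_group = "TerL", evalue = 1e-10,
             walkerb_acidic2 = w, nuc1_acidic1 = n1, nuc2_acidic = n2)

other_hit <- function(group)
  data.frame(marker_group = group, evalue = 1e-10,
             walkerb_acidic2 = NA, nuc1_acidic1 = NA, nuc2_acidic = NA)

test_that("TerL three-motif rule and the Herpesviridae override", {
  expect_equal(assign_taxon("s1", terl_hit())$group, "Caudoviricetes")
  expect_equal(assign_taxon("s2", terl_hit(n2 = FALSE))$group, "unassigned")
  both <- rbind(terl_hit(), other_hit("Herpesviridae_MCP"))
  expect_equal(assign_taxon("s3", both)$group, "Herpesviridae")
  # override is independent of hit order
  expect_equal(assign_taxon("s3", both[2:1, ])$group, "Herpesviridae")
})

test_that("single-marker families and the NCV gate", {
  expect_equal(assign_taxon("s", other_hit("Papillomaviridae_L1"))$group,
               "Papillomaviridae")
  expect_equal(assign_taxon("s", other_hit("Adenoviridae_hexon"))$group,
               "Adenoviridae")
  expect_equal(assign_taxon("s", other_hit("Tectiliviricetes_MCP"))$group,
               "Tectiliviricetes")
  ncv <- other_hit("Nucleocytoviricota_marker")
  expect_equal(assign_taxon("s", ncv)$group, "unassigned")
  expect_equal(assign_taxon("s", ncv, ncv_score = 1.5,
                            ncv_markers_recovered = 3L)$group, "unassigned")
  expect_equal(assign_taxon("s", ncv, ncv_score = 2.5,
                            ncv_markers_recovered = 0L)$group, "unassigned")
  expect_equal(assign_taxon("s", ncv, ncv_score = 2.5,
                            ncv_markers_recovered = 1L)$group,
               "Nucleocytoviricota")
})

test_that("all combinations of the decision table are defined", {
  for (terl_ok in c(TRUE, FALSE)) {
    for (herpes in c(TRUE, FALSE)) {
      for (other in c(TRUE, FALSE)) {
        hits <- terl_hit(n1 = terl_ok)
        if (herpes) hits <- rbind(hits, other_hit("Herpesviridae_MCP"))
        if (other) hits <- rbind(hits, other_hit("Polyomaviridae_coat"))
        res <- if (herpes && other)
          suppressWarnings(assign_taxon("s", hits))
        else assign_taxon("s", hits)
        expected <- if (herpes && other) "unassigned"
          else if (herpes) "Herpesviridae"
          else if (other) "Polyomaviridae"
          else if (terl_ok) "Caudoviricetes"
          else "unassigned"
        expect_equal(res$group, expected,
                     info = paste(terl_ok, herpes, other))
      }
    }
  }
  expect_warning(
    assign_taxon("s", rbind(other_hit("Papillomaviridae_L1"),
                            other_hit("Polyomaviridae_coat"))),
    "conflicting")
})

test_that("missing TerL motif flags are rejected", {
  h <- terl_hit(); h$nuc1_acidic1 <- NA
  expect_error(assign_taxon("s", h), "motif flags")
})

test_that("rRNA and plasmid screening thresholds are strict", {
  hit60 <- data.frame(gene_id = "g1", from = 1L, to = 900L,
                      gene_length = 1500L)
  expect_true(screen_sequence("c1", hit60)$rrna_contaminated)
  hit50 <- data.frame(gene_id = "g1", from = 1L, to = 750L,
                      gene_length = 1500L)
  expect_false(screen_sequence("c1", hit50)$rrna_contaminated)
  expect_false(screen_sequence("c2", plasx_score = 0.9)$plasmid_flag)
  expect_true(screen_sequence("c2", plasx_score = 0.91)$plasmid_flag)
  res <- screen_sequence("c3")
  expect_false(res$rrna_contaminated)
  expect_false(res$plasmid_flag)
})

test_that("reference-match filtering requires 10%/50% reciprocal coverage", {
  mk <- function(qcov, tcov, qlen = 1000L, tlen = 1000L)
    data.frame(query_id = "q", target_id = "t",
               q_from = 1L, q_to = as.integer(qcov * qlen / 100),
               t_from = 1L, t_to = as.integer(tcov * tlen / 100))
  lens <- c(q = 1000, t = 1000)
  expect_equal(nrow(filter_reference_matches(mk(12, 55), lens, lens)), 1L)
  expect_equal(nrow(filter_reference_matches(mk(9, 80), lens, lens)), 0L)
  expect_equal(nrow(filter_reference_matches(mk(50, 49), lens, lens)), 0L)
})
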