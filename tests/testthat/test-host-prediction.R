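test_that("prophage host prediction applies identity/length thresholds", {
  frags <- data.frame(votu = "v1", fragment_id = "f1", length = 5000L)
  tax <- toy_taxonomy("bact1", "Bacteroidetes")
  hit <- data.frame(fragment_id = "f1", target_id = "bact1",
                    identity = 96, length = 1200L, q_from = 1L, q_to = 1200L)
  pred <- predict_host_prophage(frags, hit, tax)
  expect_equal(pred$phylum, "Bacteroidetes")
  expect_equal(pred$method, "prophage")

  hit94 <- hit; hit94$identity <- 94
  expect_equal(nrow(predict_host_prophage(frags, hit94, tax)), 0L)
  hit900 <- hit; hit900$length <- 900L
  expect_equal(nrow(predict_host_prophage(frags, hit900, tax)), 0L)
  # fragments below 1000 nt are not analyzed
  fr_short <- frags; fr_short$length <- 800L
  expect_equal(nrow(predict_host_prophage(fr_short, hit, tax)), 0L)
})

test_that("phylum-conflicting fragments disqualify a vOTU prediction", {
  frags <- data.frame(votu = "v1", fragment_id = c("f1", "f2"),
                      length = 5000L)
  tax <- toy_taxonomy(c("firm1", "bact1"),
                      c("Firmicutes", "Bacteroidetes"))
  hits <- data.frame(fragment_id = c("f1", "f2"),
                     target_id = c("firm1", "bact1"),
                     identity = 97, length = 1500L,
                     q_from = 1L, q_to = 1500L)
  expect_equal(nrow(predict_host_prophage(frags, hits, tax)), 0L)

  # same phylum, different genera: consensus stops at the conflict rank
  tax2 <- toy_taxonomy(c("firm1", "firm2"), c("Firmicutes", "Firmicutes"),
                       genera = c("Roseburia", "Blautia"))
  hits$target_id <- c("firm1", "firm2")
  pred <- predict_host_prophage(frags, hits, tax2)
  expect_equal(pred$phylum, "Firmicutes")
  expect_true(is.na(pred$genus))
  expect_equal(pred$support, 2)
})

test_that("hits to targets without taxonomy are dropped with a warning", {
  frags <- data.frame(votu = "v1", fragment_id = "f1", length = 5000L)
  tax <- toy_taxonomy("bact1", "Bacteroidetes")
  hits <- data.frame(fragment_id = "f1", target_id = c("bact1", "mystery"),
                     identity = 97, length = 1500L, q_from = 1L, q_to = 1500L)
  expect_warning(pred <- predict_host_prophage(frags, hits, tax), "taxonomy")
  expect_equal(pred$phylum, "Bacteroidetes")
})

test_that("planted protospacers are recovered by the spacer matcher", {
  sp_seqs <- c(sp1 = rand_seq(32), sp2 = rand_seq(34))
  ps <- data.frame(sequence = unname(sp_seqs), position = c(3000L, 9000L))
  sim <- generate_genome(genome_sim_spec(12000, protospacers = ps, seed = 55L))
  m <- match_spacers(sp_seqs, sim$sequence)
  expect_true(all(c("sp1", "sp2") %in% m$spacer_id))
  m1 <- m[m$spacer_id == "sp1", ]
  expect_equal(m1$start, 3000L)
  expect_equal(m1$identity_over_spacer, 100)
  expect_true(all(m$full_length))
  # reverse-strand protospacer
  ps_rc <- data.frame(sequence = rc_str(sp_seqs[["sp1"]]), position = 5000L)
  sim2 <- generate_genome(genome_sim_spec(12000, protospacers = ps_rc,
                                          seed = 56L))
  m2 <- match_spacers(sp_seqs["sp1"], sim2$sequence)
  expect_true(any(m2$start == 5000L & m2$strand == "-"))
})

test_that("CRISPR linking follows the enumerated decision table", {
  tax <- toy_taxonomy(c("hostA", "hostB"), c("Firmicutes", "Bacteroidetes"))
  mk <- function(host, spacer, start, ident, bits, full = TRUE, votu = "v1")
    data.frame(votu = votu, host_id = host, spacer_id = spacer,
               start = start, end = start + 31L,
               identity_over_spacer = ident, bitscore = bits,
               full_length = full)

  # single full-length match at 96.9% links
  expect_equal(predict_host_crispr(mk("hostA", "s1", 100L, 31 / 32 * 100, 50),
                                   tax)$phylum, "Firmicutes")
  # single 85% match does not link; two distinct 85% spacers do
  expect_equal(nrow(predict_host_crispr(mk("hostA", "s1", 100L, 85, 40),
                                        tax)), 0L)
  two <- rbind(mk("hostA", "s1", 100L, 85, 40),
               mk("hostA", "s2", 900L, 85, 42))
  expect_equal(predict_host_crispr(two, tax)$phylum, "Firmicutes")
  # two spacers of one host on the same region collapse to one -> no link
  same_region <- rbind(mk("hostA", "s1", 100L, 85, 40),
                       mk("hostA", "s2", 100L, 85, 42))
  expect_equal(nrow(predict_host_crispr(same_region, tax)), 0L)
  # one spacer hitting two regions collapses to one -> no link
  same_spacer <- rbind(mk("hostA", "s1", 100L, 85, 40),
                       mk("hostA", "s1", 900L, 85, 42))
  expect_equal(nrow(predict_host_crispr(same_spacer, tax)), 0L)
  # matches below 80% never count
  weak <- rbind(mk("hostA", "s1", 100L, 75, 40),
                mk("hostA", "s2", 900L, 75, 42))
  expect_equal(nrow(predict_host_crispr(weak, tax)), 0L)
  # conflicting phyla disqualify the vOTU
  conflict <- rbind(mk("hostA", "s1", 100L, 97, 60),
                    mk("hostB", "s2", 900L, 97, 58))
  expect_equal(nrow(predict_host_crispr(conflict, tax)), 0L)
})

test_that("meta-analysis reduces correctly and matches the reference", {
  # single study: identity
  m <- meta_correlation(0.5, 50)
  expect_equal(m$pooled_r, 0.5)
  expect_equal(m$p, 2 * pnorm(-abs(atanh(0.5) * sqrt(47))))

  # homogeneous inputs: pooled r equals the common value, tau2 = 0
  m <- meta_correlation(c(0.3, 0.3, 0.3), c(40, 40, 40))
  expect_equal(m$pooled_r, 0.3, tolerance = 1e-12)
  expect_equal(m$tau2, 0)

  # random instances against the independent reference implementation
  set.seed(31)
  for (i in 1:200) {
    k <- sample(2:5, 1L)
    r <- runif(k, -0.8, 0.8)
    n <- sample(15:200, k, replace = TRUE)
    mine <- meta_correlation(r, n)
    ref <- oracle_meta(r, n)
    expect_equal(mine$pooled_r, ref$pooled_r, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
  }
  expect_warning(meta_correlation(c(0.2, 0.4), c(3, 50)), "dropped")
})

test_that("meta-analysis agrees with metafor's ZCOR + SJ estimator", {
  skip_if_not_installed("metafor")
  set.seed(41)
  for (i in 1:20) {
    k <- sample(3:6, 1L)
    r <- runif(k, -0.7, 0.7)
    n <- sample(20:300, k, replace = TRUE)
    mine <- meta_correlation(r, n)
    ref <- metafor::rma(yi = atanh(r), vi = 1 / (n - 3), method = "SJ")
    expect_equal(mine$tau2, as.numeric(ref$tau2), tolerance = 1e-8)
    expect_equal(mine$z, as.numeric(ref$beta), tolerance = 1e-8)
  }
})

test_that("co-abundance prediction takes the minimal-FDR taxon", {
  cors <- data.frame(
    taxon = rep(c("tA", "tB"), each = 3),
    votu = "v1",
    cohort = rep(c("c1", "c2", "c3"), 2),
    r = c(0.6, 0.55, 0.62, 0.1, 0.05, 0.12),
    n = 120)
  res <- predict_host_coabundance(cors)
  expect_equal(res$predictions$taxon, "tA")
  expect_true(all(res$table$fdr >= res$table$p))

  single <- cors[cors$taxon == "tB", ]
  expect_equal(predict_host_coabundance(single)$predictions$taxon, "tB")
})

test_that("a planted host coupling is recovered from synthetic communities", {
  hits <- vapply(1:20, function(i) {
    comm <- generate_community(community_sim_spec(
      300, 1, n_votus = 8, n_taxa = 6,
      coupling = data.frame(taxon = 2L, votu = 3L, rho = 0.6),
      seed = 700L + i))
    cohorts <- rep(c("cohortA", "cohortB", "cohortC"), length.out = 300)
    cors <- cohort_spearman(comm$taxa, comm$votus, cohorts)
    pred <- predict_host_coabundance(cors)$predictions
    pred$taxon[pred$votu == "vOTU_003"] == "taxon_002"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("reconciliation prioritizes prophage evidence on conflict", {
  pro <- data.frame(votu = "v1", method = "prophage", kingdom = "Bacteria",
                    phylum = "Firmicutes", class = NA, order = NA,
                    family = NA, genus = NA, species = NA, support = 3)
  cri_agree <- pro; cri_agree$method <- "crispr"; cri_agree$support <- 2
  rec <- reconcile_hosts(pro, cri_agree)
  expect_equal(rec$method, "prophage+crispr")
  expect_equal(rec$support, 5)

  cri_conflict <- cri_agree; cri_conflict$phylum <- "Bacteroidetes"
  rec <- reconcile_hosts(pro, cri_conflict)
  expect_equal(rec$method, "prophage")
  expect_equal(rec$phylum, "Firmicutes")

  only_crispr <- reconcile_hosts(pro[0, ], cri_agree)
  expect_equal(only_crispr$method, "crispr")

  coab <- data.frame(votu = "v1", taxon = "tX", phylum = "Firmicutes")
  rec <- reconcile_hosts(pro, cri_agree, coab)
  expect_true(rec$coabundance_agrees)
  coab$phylum <- "Actinobacteria"
  rec <- reconcile_hosts(pro, cri_agree, coab)
  expect_false(rec$coabundance_agrees)
})
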