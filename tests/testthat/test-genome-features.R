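test_that("terminal repeat detection matches construction and the oracle", {
  set.seed(101)
  core <- rand_seq(30)
  blk <- rand_seq(25)
  dtr_seq <- paste0(blk, core, blk)
  expect_equal(detect_terminal_repeats(dtr_seq, min_len = 20L),
               list(kind = "DTR", length = 25L))

  itr_seq <- paste0(blk, core, rc_str(blk))
  expect_equal(detect_terminal_repeats(itr_seq, min_len = 20L),
               list(kind = "ITR", length = 25L))

  # identical 19-nt termini stay below the threshold
  blk19 <- rand_seq(19)
  short_seq <- paste0(blk19, rand_seq(200), blk19)
  res <- detect_terminal_repeats(short_seq)
  expect_equal(res$kind, "none")
  expect_equal(res$length, 0L)
})

test_that("terminal repeat detector equals the brute-force oracle", {
  set.seed(202)
  for (i in 1:60) {
    L <- sample(300:1500, 1L)
    s <- rand_seq(L)
    if (i %% 3 == 1) {          # plant a DTR or ITR of length 19..300
      k <- sample(19:min(300L, L %/% 3L), 1L)
      blk <- rand_seq(k)
      tail_blk <- if (i %% 2 == 0) blk else rc_str(blk)
      s <- paste0(blk, substr(s, k + 1L, L - k), tail_blk)
    }
    expect_equal(detect_terminal_repeats(s), oracle_terminal_repeats(s),
                 info = paste("case", i))
  }
})

test_that("non-IUPAC characters are rejected", {
  expect_error(detect_terminal_repeats(paste0(rand_seq(50), "X", rand_seq(50))),
               "non-IUPAC")
})

test_that("skew profile handles degenerate compositions and window placement", {
  g_only <- strrep("G", 1001)
  sp <- skew_profile(g_only)
  expect_equal(sp$gc_skew, 1)
  expect_true(is.na(sp$at_skew))

  a_only <- strrep("A", 1001)
  sp <- skew_profile(a_only)
  expect_equal(sp$at_skew, 1)
  expect_true(is.na(sp$gc_skew))

  sp <- skew_profile(rand_seq(1401))
  expect_equal(sp$window_start, c(1L, 201L, 401L))

  expect_warning(out <- skew_profile(rand_seq(500)), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("skew values are bounded and the cumulative track sums them", {
  set.seed(7)
  for (i in 1:10) {
    sp <- skew_profile(rand_seq(sample(2000:9000, 1L), gc = runif(1, 0.3, 0.7)))
    expect_true(all(abs(sp$gc_skew) <= 1, na.rm = TRUE))
    expect_true(all(abs(sp$at_skew) <= 1, na.rm = TRUE))
    expect_equal(sp$cumulative_gc_skew[nrow(sp)],
                 sum(sp$gc_skew, na.rm = TRUE))
  }
})

test_that("planted duplications are found; sub-threshold ones are not", {
  set.seed(33)
  bg <- rand_seq(8000)
  blk <- rand_seq(150)
  s <- paste0(substr(bg, 1, 999), blk, substr(bg, 1150, 4999), blk,
              substr(bg, 5150, 8000))
  rep_hits <- find_self_repeats(s)
  expect_equal(nrow(rep_hits), 1L)
  expect_true(rep_hits$length >= 150)
  expect_equal(rep_hits$identity, 100)
  expect_equal(rep_hits$orientation, "direct")
  expect_true(rep_hits$start_a < rep_hits$start_b)

  # inverted copy
  s_inv <- paste0(substr(bg, 1, 999), blk, substr(bg, 1150, 4999),
                  rc_str(blk), substr(bg, 5150, 8000))
  inv_hits <- find_self_repeats(s_inv)
  expect_equal(nrow(inv_hits), 1L)
  expect_equal(inv_hits$orientation, "inverted")

  # 75% identity copy is below the identity threshold
  blk75 <- strsplit(blk, "")[[1]]
  flip <- seq(1, 150, by = 4)
  blk75[flip] <- vapply(blk75[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
  s75 <- paste0(substr(bg, 1, 999), blk, substr(bg, 1150, 4999),
                paste(blk75, collapse = ""), substr(bg, 5150, 8000))
  expect_equal(nrow(find_self_repeats(s75)), 0L)

  # 90-nt duplicate is below the length threshold
  blk90 <- substr(blk, 1, 90)
  s90 <- paste0(substr(bg, 1, 999), blk90, substr(bg, 1090, 4999), blk90,
                substr(bg, 5090, 8000))
  expect_equal(nrow(find_self_repeats(s90)), 0L)
})

test_that("repeat-free random sequences yield no repeat calls", {
  set.seed(44)
  for (i in 1:10) {
    s <- rand_seq(20000)
    expect_equal(detect_terminal_repeats(s)$kind, "none")
    expect_equal(nrow(find_self_repeats(s)), 0L)
  }
})

test_that("DGR candidates obey the proximity rule", {
  reps <- data.frame(start_a = 11200L, end_a = 11350L,
                     start_b = 30000L, end_b = 30150L,
                     length = 151L, identity = 100, orientation = "direct")
  rt <- data.frame(start = 10000L, end = 11000L)
  cand <- detect_dgr_candidates(reps, rt, proximity = 1000L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$min_distance_to_rt, 199L)

  far <- data.frame(start_a = 20000L, end_a = 20150L,
                    start_b = 30000L, end_b = 30150L,
                    length = 151L, identity = 100, orientation = "direct")
  expect_equal(nrow(detect_dgr_candidates(far, rt, 1000L)), 0L)
  expect_equal(nrow(detect_dgr_candidates(reps, rt[0, ], 1000L)), 0L)
})

test_that("terminal-repeat-derived pairs are excluded from DGR calls", {
  tr_pair <- data.frame(start_a = 1L, end_a = 150L,
                        start_b = 24851L, end_b = 25000L,
                        length = 150L, identity = 100, orientation = "direct")
  rt <- data.frame(start = 200L, end = 1100L)
  cand <- detect_dgr_candidates(tr_pair, rt, proximity = 1000L,
                                terminal_repeat = list(kind = "DTR",
                                                       length = 150L),
                                genome_length = 25000L)
  expect_equal(nrow(cand), 0L)
})

test_that("the genome generator's DGR structure is recovered end to end", {
  sim <- generate_genome(genome_sim_spec(25000, dtr_len = 80L, n_genes = 8L,
                                         rt_gene = TRUE,
                                         dgr_repeat_len = 140L, seed = 11L))
  reps <- find_self_repeats(sim$sequence)
  rt <- sim$truth[sim$truth$element == "rt_gene", c("start", "end")]
  tr <- detect_terminal_repeats(sim$sequence)
  cand <- detect_dgr_candidates(reps, rt, 1000L, terminal_repeat = tr,
                                genome_length = nchar(sim$sequence))
  expect_gte(nrow(cand), 1L)
  planted <- sim$truth[sim$truth$element == "dgr_repeat", ]
  expect_true(any(abs(cand$start_a - min(planted$start)) <= 5))
})
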