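test_that("random genomes are deterministic with the requested composition", {
  expect_identical(random_genome(500, seed = 3), random_genome(500, seed = 3))
  expect_false(random_genome(500, seed = 3) == random_genome(500, seed = 4))
  expect_equal(nchar(random_genome(10, seed = 1)), 10L)
  gc1 <- random_genome(2000, gc = 1, seed = 5)
  expect_false(grepl("[AT]", gc1))
  gcs <- strsplit(random_genome(20000, gc = 0.3, seed = 6), "")[[1]]
  expect_lt(abs(mean(gcs %in% c("G", "C")) - 0.3), 0.02)
})

test_that("simulated cells honor the blackout construction exactly", {
  gen <- random_genome(100000, seed = 12)
  prof <- mda_profile(seed = 42)  # b = 0.02 in 4 intervals
  cell <- simulate_cell(gen, prof)
  tr <- cell$truth
  expect_equal(nrow(tr), 4L)
  expect_equal(sum(tr[, 2] - tr[, 1]), 2000)           # floor(b * len) exactly
  expect_true(all(tr[-1, 1] >= tr[-nrow(tr), 2]))      # non-overlapping
  # no read starts inside any blackout interval
  inside <- vapply(cell$starts, function(s)
    any(s >= tr[, 1] & s < tr[, 2]), logical(1))
  expect_false(any(inside))
  # realized coverage is 0 on blackout interiors beyond read overhang
  rl <- prof$read_len
  for (b in seq_len(nrow(tr))) {
    lo <- tr[b, 1] + rl
    if (lo < tr[b, 2]) expect_true(all(cell$coverage[(lo + 1):tr[b, 2]] == 0))
  }
  # windows fully inside a blackout have zero amplification weight
  wb <- prof$window_bp
  win_start <- (seq_along(cell$weight_track) - 1L) * wb
  full_in <- vapply(win_start, function(ws)
    any(ws >= tr[, 1] & ws + wb <= tr[, 2]), logical(1))
  if (any(full_in)) expect_true(all(cell$weight_track[full_in] == 0))

  expect_error(simulate_cell(random_genome(100, seed = 1),
                             mda_profile(blackout_fraction = 0.01,
                                         num_blackout_intervals = 3)),
               "cannot place")
})

test_that("simulation is byte-deterministic under the profile seed", {
  gen <- random_genome(5000, seed = 2)
  a <- simulate_cell(gen, mda_profile(seed = 7, error_rate = 0.01))
  b <- simulate_cell(gen, mda_profile(seed = 7, error_rate = 0.01))
  expect_identical(a, b)
  c2 <- simulate_cell(gen, mda_profile(seed = 8, error_rate = 0.01))
  expect_false(identical(a$reads$sequence, c2$reads$sequence))
})

test_that("error-free reads contain only genome k-mers; errors add novel ones", {
  gen <- random_genome(3000, seed = 14)
  prof <- mda_profile(blackout_fraction = 0, gain_sigma = 0, mean_depth = 20,
                      seed = 9)
  cell <- simulate_cell(gen, prof)
  genk <- coasm:::cpp_kmer_windows(gen, 15L)
  rk <- count_kmers(kmer_table(15L, 1L), cell$reads$sequence, 0L)$kmers
  expect_true(all(rk %in% genk))

  prof_e <- mda_profile(blackout_fraction = 0, gain_sigma = 0, mean_depth = 20,
                        error_rate = 0.05, seed = 9)
  cell_e <- simulate_cell(gen, prof_e)
  rk_e <- count_kmers(kmer_table(15L, 1L), cell_e$reads$sequence, 0L)$kmers
  expect_gt(sum(!(rk_e %in% genk)), 0)
})

test_that("a bias-free deep cell reconstructs a repeat-free genome", {
  gen <- repeat_free_genome(1500L, 15L, seed = 55)
  prof <- mda_profile(blackout_fraction = 0, gain_sigma = 0, mean_depth = 60,
                      seed = 11)
  cell <- simulate_cell(gen, prof)
  cfg <- assembly_config(k = 15, coverage_cutoff = 5, num_colors = 1)
  ctg <- assemble_reads(list(cell$reads$sequence), cfg)
  ev <- reference_kmer_eval(ctg, gen, 15)
  expect_equal(ev$missing_fraction, 0)
})

test_that("coverage dispersion increases with the gain sigma", {
  gen <- random_genome(20000, seed = 16)
  cv <- vapply(c(0, 1, 2), function(sg) {
    cvs <- vapply(1:3, function(s) {
      cell <- simulate_cell(gen, mda_profile(blackout_fraction = 0,
                                             gain_sigma = sg, mean_depth = 30,
                                             seed = 100 + s))
      sd(cell$coverage) / mean(cell$coverage)
    }, numeric(1))
    mean(cvs)
  }, numeric(1))
  expect_true(all(diff(cv) > 0))
})

test_that("replicate cells differ and derive seeds per cell", {
  gen <- random_genome(20000, seed = 18)
  cells <- make_replicate_cells(gen, 2, mda_profile(seed = 21))
  expect_false(identical(cells[[1]]$truth, cells[[2]]$truth))
  expect_false(identical(cells[[1]]$reads$sequence, cells[[2]]$reads$sequence))
  one <- make_replicate_cells(gen, 1, mda_profile(seed = 21))
  direct <- simulate_cell(gen, mda_profile(seed = 21), genome_id = one[[1]]$genome_id)
  expect_identical(one[[1]], direct)
})

test_that("circular genomes allow wrapping reads", {
  gen <- random_genome(300, seed = 77)
  prof <- mda_profile(blackout_fraction = 0, gain_sigma = 0, mean_depth = 50,
                      read_len = 50L, circular = TRUE, seed = 3)
  cell <- simulate_cell(gen, prof)
  expect_true(any(cell$starts > 300 - 50))
  expect_true(all(nchar(cell$reads$sequence) == 50))
  expect_equal(length(cell$coverage), 300L)
  expect_equal(sum(cell$coverage), length(cell$starts) * 50)
})
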