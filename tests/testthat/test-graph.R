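# count a set of (read, multiplicity, color) triples into a table
count_multi <- function(k, m, ...) {
  tb <- kmer_table(k, m)
  for (spec in list(...))
    tb <- count_kmers(tb, rep(spec$read, spec$times), spec$color)
  tb
}

test_that("graph construction follows the edge-witness semantics", {
  # single palindromic witness: one node, one self-adjacency across strands
  tb <- count_kmers(kmer_table(3L, 2L), "ACGT", 0L)
  g <- build_graph(tb)
  adj <- coasm:::cpp_adjacency(g$kmers, g$edges, g$k, g$keep)
  expect_equal(nrow(adj), 1L)
  expect_equal(adj$from, "ACG")
  expect_equal(adj$to, "ACG")
  expect_equal(adj$to_strand, 1L)

  # empty table -> empty graph
  g0 <- build_graph(kmer_table(5L, 1L))
  expect_equal(length(condense(g0)), 0L)

  # two k-mers overlapping by k-1 but with no witness: no edge
  tb2 <- kmer_table(5L, 1L)
  tb2 <- count_kmers(tb2, "AACCG", 0L)
  tb2 <- count_kmers(tb2, "ACCGT", 0L)
  tb2$edges <- character()  # drop any witnesses
  g2 <- build_graph(tb2)
  expect_equal(nrow(coasm:::cpp_adjacency(g2$kmers, g2$edges, g2$k, g2$keep)), 0L)
  expect_equal(length(condense(g2)), 2L)
})

test_that("condensation returns maximal non-branching paths", {
  # linear chain of 5 k-mers -> one unitig containing all 5
  g5 <- repeat_free_genome(9L, 5L, seed = 21)
  tb <- count_kmers(kmer_table(5L, 1L), g5, 0L)
  ctg <- condense(build_graph(tb))
  expect_equal(length(ctg), 1L)
  expect_equal(ctg$kmer_count, 5L)
  expect_true(ctg$sequence %in% c(g5, o_rc(g5)))

  # perfect tiling of a 300 bp repeat-free genome, k=15 -> the genome back
  gen <- repeat_free_genome(300L, 15L, seed = 33)
  tb2 <- count_kmers(kmer_table(15L, 1L), tile_reads(gen), 0L)
  ctg2 <- condense(build_graph(tb2))
  expect_equal(length(ctg2), 1L)
  expect_true(ctg2$sequence %in% c(gen, o_rc(gen)))

  # a branching vertex terminates its unitig; both branches start new ones
  stem <- repeat_free_genome(40L, 7L, seed = 55)
  b1 <- paste0(stem, "A")
  b2 <- paste0(stem, "C")
  tb3 <- count_multi(7L, 1L, list(read = b1, times = 1, color = 0),
                     list(read = b2, times = 1, color = 0))
  ctg3 <- condense(build_graph(tb3))
  o3 <- o_unitigs(tb3$kmers, tb3$edges, 7L)
  expect_equal(sort(ctg3$sequence, method = "radix"), o3)
  expect_gte(length(ctg3), 3L)
})

test_that("unitigs partition the vertex set before any trimming", {
  set.seed(12)
  for (rep in 1:5) {
    gen <- random_genome(sample(200:600, 1), seed = 100 + rep)
    tb <- count_kmers(kmer_table(9L, 1L), tile_reads(gen), 0L)
    ctg <- condense(build_graph(tb))
    got <- sort(unlist(lapply(ctg$sequence, function(s)
      coasm:::cpp_kmer_windows(s, 9L))), method = "radix")
    expect_equal(got, tb$kmers)
  }
})

test_that("condensation agrees with the brute-force oracle on random genomes", {
  for (rep in 1:8) {
    for (k in c(7L, 15L)) {
      gen <- random_genome(sample(200:1500, 1), seed = 7000 + 13 * rep + k)
      tb <- count_kmers(kmer_table(k, 1L), tile_reads(gen), 0L)
      ctg <- condense(build_graph(tb))
      expect_equal(sort(ctg$sequence, method = "radix"),
                   o_unitigs(tb$kmers, tb$edges, k))
    }
  }
})

test_that("dominated short tips are clipped; strong or isolated ones stay", {
  k <- 9L
  main <- repeat_free_genome(60L, k, seed = 77)
  t0 <- 20L
  spur_base <- setdiff(c("A", "C", "G", "T"),
                       substr(main, t0 + k, t0 + k))[1]
  spur <- paste0(substr(main, t0, t0 + k - 1L), spur_base)

  cfg <- assembly_config(k = k, coverage_cutoff = 0, min_contig_len = 1,
                         num_colors = 2)

  # dominated 1-node spur off a (200,150) path -> removed
  tb <- count_multi(k, 2L,
                    list(read = main, times = 200, color = 0),
                    list(read = main, times = 150, color = 1),
                    list(read = spur, times = 1, color = 0))
  g <- clip_tips(build_graph(tb), cfg)
  ctg <- condense(g)
  expect_equal(ctg$sequence, canonicalize_seq(main))

  # spur stronger than the through-path -> retained
  tb2 <- count_multi(k, 2L,
                     list(read = main, times = 200, color = 0),
                     list(read = main, times = 150, color = 1),
                     list(read = spur, times = 300, color = 0))
  g2 <- clip_tips(build_graph(tb2), cfg)
  expect_equal(sum(g2$keep), length(g2$kmers))

  # isolated linear component is never a tip
  iso <- repeat_free_genome(20L, k, seed = 99)
  tb3 <- count_multi(k, 2L,
                     list(read = main, times = 200, color = 0),
                     list(read = iso, times = 1, color = 1))
  g3 <- clip_tips(build_graph(tb3), cfg)
  expect_equal(sum(g3$keep), length(g3$kmers))
})

test_that("progressive trimming condemns on the max over colors (rescue)", {
  k <- 9L
  x <- repeat_free_genome(40L, k, seed = 111)
  y <- repeat_free_genome(40L, k, seed = 222)
  cfg <- assembly_config(k = k, coverage_cutoff = 100, min_contig_len = 1,
                         num_colors = 2)
  tb <- count_multi(k, 2L,
                    list(read = x, times = 150, color = 0),      # (150, 0)
                    list(read = y, times = 50, color = 0),       # (50, 40)
                    list(read = y, times = 40, color = 1))
  g <- trim_low_coverage(build_graph(tb), cfg)
  ctg <- condense(g)
  # x rescued by color 0 alone; y removed: max(50,40) < 100
  expect_equal(ctg$sequence, canonicalize_seq(x))

  # cutoff 0 leaves the graph unchanged
  g0 <- trim_low_coverage(build_graph(tb), assembly_config(
    k = k, coverage_cutoff = 0, num_colors = 2))
  expect_true(all(g0$keep))
})

test_that("an empty extra color changes nothing and the assembly is deterministic", {
  gen <- random_genome(3000, seed = 5)
  cells <- make_replicate_cells(gen, 1, mda_profile(mean_depth = 30, seed = 17))
  dir <- tempfile()
  empty_fa <- tempfile(fileext = ".fa")
  writeLines(character(), empty_fa)
  write_simulated_cells(cells, dir)
  man1 <- read_manifest(file.path(dir, "manifest.tsv"))
  man2 <- color_manifest(c(man1$label, "empty"), c(man1$paths, list(empty_fa)))
  cfg1 <- assembly_config(k = 15, coverage_cutoff = 3, num_colors = 1)
  cfg2 <- assembly_config(k = 15, coverage_cutoff = 3, num_colors = 2)
  a1 <- assemble(man1, cfg1)
  a2 <- assemble(man2, cfg2)
  expect_equal(a1$sequence, a2$sequence)
  expect_equal(a2$coverage[, 2], rep(0, length(a2)))

  # byte-identical output across reruns
  f1 <- tempfile(); f2 <- tempfile()
  write_contigs(a1, f1)
  write_contigs(assemble(man1, cfg1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("adding a color never removes surviving sequence (monotone rescue)", {
  gen <- random_genome(4000, seed = 31)
  prof <- mda_profile(blackout_fraction = 0.05, num_blackout_intervals = 2,
                      mean_depth = 40, seed = 61)
  cells <- make_replicate_cells(gen, 2, prof)
  cfg1 <- assembly_config(k = 15, coverage_cutoff = 5, num_colors = 1)
  cfg2 <- assembly_config(k = 15, coverage_cutoff = 5, num_colors = 2)
  a1 <- assemble_reads(list(cells[[1]]$reads$sequence), cfg1)
  a2 <- assemble_reads(list(cells[[1]]$reads$sequence,
                            cells[[2]]$reads$sequence), cfg2)
  joined <- paste(c(a2$sequence, o_rc(a2$sequence)), collapse = " ")
  for (s in a1$sequence)
    expect_true(grepl(s, joined, fixed = TRUE) ||
                  grepl(o_rc(s), joined, fixed = TRUE))
})

test_that("permuting colors permutes coverages but not contig sequences", {
  gen <- random_genome(3000, seed = 41)
  cells <- make_replicate_cells(gen, 2, mda_profile(mean_depth = 30, seed = 71))
  cfg <- assembly_config(k = 15, coverage_cutoff = 4, num_colors = 2)
  a <- assemble_reads(list(cells[[1]]$reads$sequence,
                           cells[[2]]$reads$sequence), cfg)
  b <- assemble_reads(list(cells[[2]]$reads$sequence,
                           cells[[1]]$reads$sequence), cfg)
  expect_equal(a$sequence, b$sequence)
  expect_equal(a$coverage, b$coverage[, c(2, 1), drop = FALSE])
})

test_that("iterative assembly resolves repeats between k1 and k2", {
  k1 <- 15L; k2 <- 25L
  # genome with one exact 18 bp repeat in otherwise unique sequence
  repeat_seq <- substr(repeat_free_genome(18L, k1, seed = 303), 1, 18)
  arms <- lapply(1:3, function(i) repeat_free_genome(60L, k1, seed = 404 + i))
  gen <- paste0(arms[[1]], repeat_seq, arms[[2]], repeat_seq, arms[[3]])
  reads <- tile_reads(gen, read_len = 40L, step = 5L)
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "reads.fa")
  writeLines(as.vector(rbind(paste0(">r", seq_along(reads)), reads)), fa)
  man <- color_manifest("cell", list(fa))
  cfg <- assembly_config(k = k1, coverage_cutoff = 0, min_contig_len = 1,
                         num_colors = 1)

  base <- assemble(man, cfg)
  # verify the repeat genuinely breaks the k1 assembly
  expect_gte(length(base), 3L)

  iter <- iterative_assemble(man, c(k1, k2), cfg)
  expect_equal(length(iter), 1L)
  expect_true(iter$sequence %in% c(gen, o_rc(gen)))

  # single-round identity
  single <- iterative_assemble(man, k1, cfg)
  expect_equal(single$sequence, base$sequence)
  expect_equal(single$coverage, base$coverage)
})

test_that("pseudo-read injection respects color presence", {
  k1 <- 15L
  gen <- repeat_free_genome(80L, k1, seed = 777)
  fa1 <- tempfile(fileext = ".fa")
  writeLines(c(">r1", gen), fa1)
  empty <- tempfile(fileext = ".fa")
  writeLines(character(), empty)
  man <- color_manifest(c("full", "empty"), list(fa1, empty))
  cfg <- assembly_config(k = k1, coverage_cutoff = 0, min_contig_len = 1,
                         num_colors = 2)
  out <- suppressWarnings(iterative_assemble(man, c(k1, 17L), cfg))
  # color 1 had nothing and no contig was present there: still zero
  expect_equal(out$coverage[, 2], rep(0, length(out)))
  expect_gte(sum(out$coverage[, 1]), 1)
})
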