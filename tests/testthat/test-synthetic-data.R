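test_that("degenerate configurations give empty panels and invalid ones are rejected", {
  cfg <- sim_config(seed = 1, n_degraders = 0, n_background = 0)
  out <- generate_reference_panel(cfg)
  expect_length(out$genomes, 0)
  expect_equal(nrow(out$truth$genomes), 0)
  expect_equal(nrow(out$truth$genes), 0)

  expect_error(sim_config(n_degraders = -1), "nonnegative")
  expect_error(sim_config(divergence = 1), "\\[0, 1\\)")
  expect_error(sim_config(fragment_length_mean = 0.5), ">= 1")
  expect_error(sim_config(n_degraders = 1, n_background = 1,
                          abundances = c(0, 0)), "not all zero")
  expect_error(sim_config(n_degraders = 1, n_background = 0,
                          abundances = c(1, 1)), "one weight per genome")
  expect_error(sim_config(families = c("KshA", "Foo")), "HsaC")
  expect_error(fragment_community(list(genomes = list()), sim_config()),
               "empty")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, n_degraders = 1, n_background = 1,
                    genome_length = 22000)
  p1 <- generate_reference_panel(cfg)
  p2 <- generate_reference_panel(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_panel_fasta(p1, f1); write_panel_fasta(p2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  fc1 <- fragment_community(p1, cfg)
  fc2 <- fragment_community(p2, cfg)
  expect_identical(as.character(fc1$contigs$seqs),
                   as.character(fc2$contigs$seqs))
  expect_identical(fc1$truth, fc2$truth)
})

test_that("planted genes are in frame, in bounds, non-overlapping and counted by construction", {
  cfg <- sim_config(seed = 5, n_degraders = 3, n_background = 0,
                    genome_length = 30000)
  out <- generate_reference_panel(cfg)
  fam_genes <- out$truth$genes[out$truth$genes$type == "family", ]
  expect_equal(nrow(fam_genes), 3 * 10)

  for (g in out$genomes) {
    pg <- g$planted_genes
    expect_true(all(pg$start >= 1 & pg$end <= nchar(g$sequence)))
    ord <- order(pg$start)
    expect_true(all(pg$start[ord][-1] > pg$end[ord][-nrow(pg)]))
    ## re-scan emitted coordinates: every gene translates exactly to its
    ## recorded protein plus the stop
    for (i in seq_len(nrow(pg))) {
      dna <- substring(g$sequence, pg$start[i], pg$end[i])
      if (pg$strand[i] == "-") dna <- secoscreen:::revcomp(dna)
      tr <- secoscreen:::translate_dna(dna)
      expect_identical(tr, paste0(pg$protein[i], "*"))
      expect_false(grepl("*", pg$protein[i], fixed = TRUE))
    }
  }
})

test_that("reverse-strand placement is exercised when requested", {
  cfg <- sim_config(seed = 9, n_degraders = 1, n_background = 0,
                    genome_length = 25000, reverse_strand_genes = TRUE)
  out <- generate_reference_panel(cfg)
  strands <- out$genomes[[1]]$planted_genes$strand
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("mutate_protein preserves length and hits the divergence target", {
  p <- secoscreen:::random_protein(1000)
  expect_identical(mutate_protein(p, 0, seed = 1), p)

  m <- mutate_protein(p, 0.10, seed = 7)
  expect_equal(nchar(m), 1000)
  ident <- mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
  ## binomial(1000, 0.9): P(identity in [0.87, 0.93]) > 0.99
  expect_gt(ident, 0.87)
  expect_lt(ident, 0.93)

  a <- mutate_protein(p, 0.5, seed = 1)
  b <- mutate_protein(p, 0.5, seed = 2)
  expect_false(identical(a, b))
  expect_error(mutate_protein(p, 1, seed = 1), "\\[0, 1\\)")
})

test_that("fragments are genome substrings with abundance-proportional mass", {
  cfg <- sim_config(seed = 13, n_degraders = 1, n_background = 1,
                    genome_length = 20000, abundances = c(1, 0))
  panel <- generate_reference_panel(cfg)
  fc <- fragment_community(panel, cfg)
  ## zero-abundance genome contributes nothing
  expect_setequal(unique(fc$truth$genome_id), panel$genomes[[1]]$genome_id)
  ## substring property, checked against the truth coordinates
  g <- panel$genomes[[1]]
  for (i in seq_len(nrow(fc$truth))) {
    expect_identical(
      as.character(fc$contigs$seqs[[fc$truth$contig_id[i]]]),
      substring(g$sequence, fc$truth$start[i], fc$truth$end[i]))
  }
  expect_lte(sum(Biostrings::width(fc$contigs$seqs)), 20000)
})

test_that("a zero-variance fragment length gives fixed-length tiles", {
  cfg <- sim_config(seed = 3, n_degraders = 1, n_background = 0,
                    genome_length = 23000, fragment_length_mean = 5000,
                    fragment_length_sd = 0)
  panel <- generate_reference_panel(cfg)
  fc <- fragment_community(panel, cfg)
  lens <- Biostrings::width(fc$contigs$seqs)
  expect_true(all(lens == 5000 | lens == 23000 %% 5000))
  expect_equal(sum(lens), 23000)
})
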