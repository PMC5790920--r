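test_that("six-frame ORF calling obeys the standard code and strand symmetry", {
  orfs <- call_orfs("ATGAAATAA", min_protein_len = 2)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$sequence, "MK")
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$frame, 1L)
  expect_equal(orfs$start, 1L)
  expect_equal(orfs$end, 6L)

  rc <- secoscreen:::revcomp("ATGAAATAA")
  orfs_rc <- call_orfs(rc, min_protein_len = 2)
  expect_equal(orfs_rc$sequence, "MK")
  expect_equal(orfs_rc$strand, "-")

  expect_equal(nrow(call_orfs(strrep("C", 300), min_protein_len = 2)), 0)

  ## coordinates map back to the contig exactly, both strands
  with_seed(33, {
    for (rep in 1:5) {
      contig <- secoscreen:::random_dna(3000, gc = 0.5)
      orfs <- call_orfs(contig, min_protein_len = 20)
      for (i in seq_len(nrow(orfs))) {
        dna <- substring(contig, orfs$start[i], orfs$end[i])
        if (orfs$strand[i] == "-") dna <- secoscreen:::revcomp(dna)
        expect_identical(secoscreen:::translate_dna(dna), orfs$sequence[i])
      }
    }
  })
})

test_that("profile HMM construction follows the match-column and smoothing rules", {
  aln <- c(a = "MKVDE", b = "MKVDE")
  m <- build_profile_hmm(aln)
  expect_equal(m$M, 5)
  expect_equal(m$consensus, "MKVDE")
  for (j in 1:5) {
    expect_equal(unname(which.max(m$match_emissions[j, ])),
                 which(secoscreen:::AA_ALPHABET ==
                         strsplit("MKVDE", "")[[1]][j]))
  }
  ## rows are probability simplexes
  expect_equal(unname(rowSums(m$match_emissions)), rep(1, 5))

  ## a column with 3/4 gaps is not a match column; one with 2/4 is
  aln2 <- c(a = "MK-DE", b = "M--DE", c = "M--DE", d = "MKVDE")
  m2 <- build_profile_hmm(aln2)
  expect_equal(m2$M, 4)   # column 2 (2/4 gaps) kept, column 3 (3/4) dropped
  aln3 <- c(a = "M-DE", b = "M-DE", c = "M-DE", d = "MKDE")
  expect_equal(build_profile_hmm(aln3)$M, 3)

  ## large pseudocount drives emissions to uniform
  mu <- build_profile_hmm(aln, pseudocount = 1e6)
  expect_true(all(abs(mu$match_emissions - 0.05) < 1e-3))

  expect_error(build_profile_hmm(c(a = "MKV", b = "MK")), "ragged")
  expect_error(build_profile_hmm(c(a = "MKV")), "at least 2")
})

test_that("Viterbi and forward scores match exhaustive path enumeration", {
  with_seed(44, {
    for (rep in 1:12) {
      m <- random_small_hmm(M = sample(2:4, 1))
      pep <- secoscreen:::random_protein(sample(2:6, 1))
      oracle <- hmm_enum_oracle(m, pep)
      expect_equal(viterbi_bits(m, pep), oracle$viterbi, tolerance = 1e-9)
      expect_equal(forward_bits(m, pep), oracle$forward, tolerance = 1e-9)
    }
  })
})

test_that("forward dominates Viterbi and scores ignore protein identity and order", {
  with_seed(45, {
    m <- random_small_hmm(M = 8, n_seq = 4)
    for (rep in 1:10) {
      pep <- secoscreen:::random_protein(sample(5:30, 1))
      expect_gte(forward_bits(m, pep), viterbi_bits(m, pep))
    }
  })
  expect_error(viterbi_bits(test_family_models()[["KshA"]], ""), "nonempty")
  ## nonstandard residues are background wildcards, scored finitely
  expect_message(s <- viterbi_bits(test_family_models()[["KshA"]], "MKXZV"),
                 "wildcard")
  expect_true(is.finite(s))
})

test_that("model-sampled proteins outscore random proteins of the same length", {
  m <- test_family_models()[["KshA"]]
  wins <- with_seed(46, {
    sum(vapply(1:100, function(i) {
      samp <- secoscreen:::sample_hmm(m, seed = i)
      rand <- secoscreen:::random_protein(nchar(samp))
      viterbi_bits(m, samp) > viterbi_bits(m, rand)
    }, logical(1)))
  })
  expect_gte(wins, 95)
})

test_that("scanning reports one hit per protein-family pair above threshold", {
  models <- test_family_models()
  empty <- scan_sample(call_orfs(strrep("C", 300), min_protein_len = 2),
                       models)
  expect_equal(nrow(empty$hits), 0)
  expect_equal(empty$profile$n_families, 0L)

  ## two models of the same family: only the best one is reported
  aln <- family_seed_alignments("KshA")[["KshA"]]
  m1 <- calibrate_hmm(build_profile_hmm(aln, family = "KshA",
                                        model_id = "KshA_a"),
                      n_decoys = 100, seed = 1)
  m2 <- calibrate_hmm(build_profile_hmm(aln[1:4], family = "KshA",
                                        model_id = "KshA_b"),
                      n_decoys = 100, seed = 2)
  anc <- family_ancestors("KshA")[[1]]
  res <- scan_sample(c(p1 = anc), list(m1, m2))
  expect_equal(nrow(res$hits), 1)
  expect_equal(res$hits$family, "KshA")
  expect_true(res$hits$e_value > 0)

  expect_error(scan_sample(c(p1 = anc), list()), "at least one family")
  uncal <- build_profile_hmm(aln, family = "KshA")
  expect_error(scan_sample(c(p1 = anc), list(uncal)), "uncalibrated")
  expect_equal(nrow(scan_sample(c(p1 = anc), list(uncal),
                                bit_threshold = 10)$hits), 1)
})

test_that("planted families are all detected at zero divergence with monotone decay", {
  models <- test_family_models()
  detected <- vapply(c(0, 0.3, 0.5, 0.7), function(d) {
    orfs <- test_degrader_orfs(d)$orfs
    scan_sample(orfs, models)$profile$n_families
  }, numeric(1))
  expect_equal(detected[1], 10)
  expect_true(all(diff(detected) <= 0))
})
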