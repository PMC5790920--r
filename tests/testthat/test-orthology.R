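sm <- scoring_matrix()

test_that("local alignment matches self-alignment identities and the brute DP oracle", {
  a <- "MKVLWAADFG"
  self <- smith_waterman(a, a, sm)
  diag_sum <- sum(vapply(strsplit(a, "")[[1]],
                         function(r) sm$matrix[r, r], numeric(1)))
  expect_equal(self$score, diag_sum)
  expect_equal(self$identity, 100)
  expect_equal(self$coverage, 100)

  ## disjoint residue sets with all-negative cross scores: empty local
  ## alignment, score floor 0
  none <- smith_waterman("WWWWW", "PPPPP", sm)
  expect_equal(none$score, 0)
  expect_equal(none$identity, 0)

  expect_error(smith_waterman("", "MKV"), "nonempty")

  with_seed(70, {
    for (rep in 1:30) {
      x <- secoscreen:::random_protein(sample(3:10, 1))
      y <- secoscreen:::random_protein(sample(3:10, 1))
      expect_equal(smith_waterman(x, y, sm)$score, sw_oracle(x, y, sm))
      ## symmetric matrix implies symmetric scores
      expect_equal(smith_waterman(x, y, sm)$score,
                   smith_waterman(y, x, sm)$score)
    }
  })
})

test_that("reciprocal best hits form a thresholded partial matching", {
  prot <- c(p1 = "MKVLWAADFGHKLMNPQRST",
            p2 = "MWYHCFDEAAGIKLRSTVNP",
            p3 = "MAAAGGGSSSTTTVVVLLLK")
  calls <- reciprocal_best_hits(prot, prot, sm)
  expect_equal(nrow(calls), 3)
  expect_identical(calls$query_id, calls$ref_id)
  expect_true(all(calls$identity == 100))

  ## q1's best hit is r2, but r2's best hit is q3: no (q1, r2) call
  base <- "MKVLWAADFGHKLMNPQRSTWYHCFDEA"
  q3 <- base
  q1 <- paste0(substring(base, 1, 20), "AAAAAAAA")   # weaker copy
  r2 <- base
  calls2 <- reciprocal_best_hits(c(q1 = q1, q3 = q3), c(r2 = r2), sm)
  expect_false(any(calls2$query_id == "q1"))
  expect_equal(calls2$query_id, "q3")

  ## nothing above thresholds: empty call set
  none <- reciprocal_best_hits(c(q = "MWWWWWWWWW"), c(r = "MPPPPPPPPP"), sm)
  expect_equal(nrow(none), 0)

  ## partial matching on random proteomes
  with_seed(71, {
    qs <- stats::setNames(vapply(1:5, function(i)
      secoscreen:::random_protein(30), character(1)), paste0("q", 1:5))
    rs <- stats::setNames(vapply(1:4, function(i)
      secoscreen:::random_protein(30), character(1)), paste0("r", 1:4))
    cc <- reciprocal_best_hits(qs, rs, sm, min_identity = 0,
                               min_coverage = 0)
    expect_lte(max(table(cc$query_id), 0), 1)
    expect_lte(max(table(cc$ref_id), 0), 1)
  })
})

test_that("pathway completeness counts distinct called families", {
  expect_equal(pathway_completeness(
    data.frame(family = c("KshA", "HsaC"))), 2)
  expect_equal(pathway_completeness(
    data.frame(family = steroid_families())), 10)
  expect_equal(pathway_completeness(data.frame(family = character())), 0)
  ## duplicate calls for one family count once
  expect_equal(pathway_completeness(
    data.frame(family = c("KshA", "KshA"))), 1)
})

test_that("the predicted-degrader rule needs five families including a key enzyme", {
  prof <- function(fams) mag_profile("m", fams)
  expect_true(prof(c("KshA", "KshB", "KstD", "HsaA", "HsaB"))$predicted_degrader)
  expect_false(prof(c("KshB", "KstD", "HsaA", "HsaB", "HsaD",
                      "HsaE"))$predicted_degrader)
  expect_false(prof(c("KshA", "HsaC", "KshB", "KstD"))$predicted_degrader)

  ## monotone in the family set
  with_seed(72, {
    for (rep in 1:15) {
      fams <- sample(steroid_families(), sample(1:9, 1))
      extra <- sample(setdiff(steroid_families(), fams), 1)
      expect_true(!prof(fams)$predicted_degrader ||
                    prof(c(fams, extra))$predicted_degrader)
    }
  })
})

test_that("the confirmation rule is ortholog-based and pluggable", {
  calls10 <- data.frame(family = steroid_families())
  p <- mag_profile("m", steroid_families(), ortholog_calls = calls10)
  expect_true(p$confirmed_degrader)
  p0 <- mag_profile("m", steroid_families(),
                    ortholog_calls = data.frame(family = character()))
  expect_false(p0$confirmed_degrader)
  ## no KshA/HsaC ortholog: not confirmed even at completeness 8
  calls_nokey <- data.frame(family = setdiff(steroid_families(),
                                             key_families()))
  pn <- mag_profile("m", steroid_families(), ortholog_calls = calls_nokey)
  expect_false(pn$confirmed_degrader)
  ## pluggable rule overrides the default
  expect_true(confirm_degrader(pn, rule = function(p) TRUE))
})

test_that("panel proteins planted verbatim give full pathway completeness", {
  panel <- synthetic_reference_panel()
  expect_named(panel, c("Mtu", "Rjo", "Cte", "Pch", "Pha"))
  for (st in panel) {
    expect_setequal(stats::setNames(st$annotation[!is.na(st$annotation)],
                                    NULL), steroid_families())
  }
  ## a MAG carrying the family ancestors calls orthologs for all 10
  mag <- family_ancestors()
  names(mag) <- paste0("mag_", names(mag))
  calls <- panel_ortholog_calls(mag, panel["Rjo"])
  expect_equal(pathway_completeness(calls), 10)
  prof <- mag_profile("mag", steroid_families(), ortholog_calls = calls)
  expect_true(prof$predicted_degrader)
  expect_true(prof$confirmed_degrader)
})
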