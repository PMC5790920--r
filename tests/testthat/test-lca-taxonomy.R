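tree <- load_taxonomy()

test_that("the bundled taxonomy is a valid single-rooted rank tree", {
  expect_s3_class(tree, "taxonomy_tree")
  expect_equal(tree$name_by_id[[as.character(tree$root)]], "d__Bacteria")
  ## every label used by the MAG catalogue resolves
  for (lbl in unique(load_table1()$lca_label)) {
    expect_silent(resolve_label(tree, lbl))
  }
  expect_error(resolve_label(tree, "g__Atlantis"), "g__Atlantis")
  bad <- data.frame(taxon_id = 1:2, parent_id = c(NA, 1),
                    rank = c("phylum", "domain"),
                    name = c("p__A", "d__B"))
  expect_error(taxonomy_tree(bad), "not deeper")
})

test_that("LCA assignment matches examples and the ancestor-intersection oracle", {
  expect_equal(assign_lca("g__Rhodococcus", tree),
               resolve_label(tree, "g__Rhodococcus"))
  expect_equal(assign_lca(c("g__Rhodococcus", "g__Mycobacterium"), tree),
               resolve_label(tree, "o__Corynebacteriales"))
  expect_equal(assign_lca(c("g__Rhodococcus", "g__Sphingomonas"), tree),
               resolve_label(tree, "d__Bacteria"))
  expect_true(is.na(assign_lca(character(0), tree)))
  expect_error(assign_lca(999L, tree), "not in tree")

  with_seed(55, {
    for (rep in 1:20) {
      rt <- random_taxonomy(sample(10:50, 1))
      ids <- sample(rt$nodes$taxon_id, sample(1:5, 1))
      expect_equal(assign_lca(ids, rt), unname(lca_oracle(ids, rt)))
    }
  })
})

test_that("LCA is idempotent, order-invariant and monotone upward", {
  with_seed(56, {
    for (rep in 1:15) {
      ids <- sample(tree$nodes$taxon_id, sample(2:5, 1))
      l <- assign_lca(ids, tree)
      expect_equal(assign_lca(l, tree), l)
      expect_equal(assign_lca(rev(ids), tree), l)
      extra <- sample(tree$nodes$taxon_id, 1)
      l2 <- assign_lca(c(ids, extra), tree)
      ## adding a taxon never yields a deeper node
      expect_true(l2 %in% secoscreen:::taxon_ancestors(tree, l))
    }
  })
})

test_that("report-rank rollup follows the class/phylum conventions", {
  expect_equal(rollup_report_rank("g__Rhodococcus", tree), "Actinobacteria")
  expect_equal(rollup_report_rank("c__Actinobacteria", tree), "Actinobacteria")
  expect_equal(rollup_report_rank("f__Rhodocyclaceae", tree),
               "Betaproteobacteria")
  expect_equal(rollup_report_rank("f__Sphingomonadaceae", tree),
               "Alphaproteobacteria")
  expect_equal(rollup_report_rank("g__Pseudomonas", tree),
               "Gammaproteobacteria")
  expect_equal(rollup_report_rank("p__Proteobacteria", tree),
               "Proteobacteria")
  expect_equal(rollup_report_rank("d__Bacteria", tree),
               "unclassified-Bacteria")
  expect_equal(rollup_report_rank("p__Firmicutes", tree), "other phylum")
  expect_equal(rollup_report_rank(NA, tree), "unassigned")
  expect_error(rollup_report_rank("g__Nonexistent", tree), "g__Nonexistent")
})

test_that("the top-hit window keeps ties and near-best references only", {
  ref <- list(
    seqs = c(r1 = "MKVLWAADFGHKLMNPQRST",
             r2 = "MKVLWAADFGHKLMNPQRSA",
             r3 = "MWWWWYYYYCCCCHHHHPPP"),
    taxa = c(r1 = "g__Rhodococcus", r2 = "g__Mycobacterium",
             r3 = "g__Pseudomonas"))
  q <- "MKVLWAADFGHKLMNPQRST"
  expect_equal(top_hit_window(q, ref, window = 0), "g__Rhodococcus")
  hits <- top_hit_window(q, ref, window = 0.2)
  expect_setequal(hits, c("g__Rhodococcus", "g__Mycobacterium"))

  ## exact ties in sister genera are both returned even at window 0
  ref2 <- list(seqs = c(r1 = q, r2 = q),
               taxa = c(r1 = "g__Rhodococcus", r2 = "g__Gordonia"))
  expect_setequal(top_hit_window(q, ref2, window = 0),
                  c("g__Rhodococcus", "g__Gordonia"))

  ## nothing above the floor: unassigned
  expect_length(top_hit_window("MKVL", list(
    seqs = c(r = "PPPP"), taxa = c(r = "g__Thauera")), score_floor = 5),
    0)
})

test_that("per-sample aggregation yields conservative percentages and family counts", {
  ht <- data.frame(protein_id = sprintf("p%d", 1:10),
                   family = c(rep("KshA", 5), "HsaC", "HsaA", "HsaB",
                              "KshB", "KstD"),
                   taxon = c(rep("g__Pseudomonas", 10)))
  agg <- aggregate_sample_taxonomy(ht, "s1")
  expect_equal(nrow(agg), 1)
  expect_equal(agg$pct_of_hits, 100)
  expect_equal(agg$n_families_for_taxon, 6)

  ht2 <- data.frame(protein_id = sprintf("p%d", 1:10),
                    family = "KshA",
                    taxon = c(rep("g__Rhodococcus", 5), rep(NA, 5)))
  agg2 <- aggregate_sample_taxonomy(ht2, "s1")
  expect_equal(sum(agg2$pct_of_hits), 100)
  expect_equal(agg2$pct_of_hits[agg2$taxon == "g__Rhodococcus"], 50)
  expect_equal(agg2$pct_of_hits[agg2$taxon == "unassigned"], 50)
})

test_that("KRONA export writes one lineage path per taxon with counts", {
  ht <- data.frame(protein_id = c("p1", "p2", "p3"),
                   family = "KshA",
                   taxon = c("g__Rhodococcus", "g__Rhodococcus", NA))
  path <- tempfile(fileext = ".txt")
  export_krona_text(ht, tree, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  rh <- grep("g__Rhodococcus", lines, value = TRUE)
  expect_match(rh, "^2\td__Bacteria\tp__Actinobacteria")
})
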