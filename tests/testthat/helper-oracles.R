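## Independent oracles used by the dynamic-programming equivalence suites.
## Each re-implements the mathematical definition directly (exhaustive
## enumeration or naive DP), sharing no code with the package internals it
## checks.

## N50: largest L such that contigs of length >= L hold half the total,
## found by scanning every candidate threshold.
n50_oracle <- function(lens) {
  if (length(lens) == 0) return(0L)
  total <- sum(lens)
  best <- 0L
  for (L in sort(unique(lens))) {
    if (sum(lens[lens >= L]) >= total / 2) best <- max(best, L)
  }
  as.integer(best)
}

## Local profile-HMM scores by exhaustive path enumeration under the same
## model definition: entry log2(1/M) into any match state, free exit from
## any match state, inserts emit background, no D<->I moves.
hmm_enum_oracle <- function(hmm, protein) {
  idx <- secoscreen:::encode_protein(protein)
  M <- hmm$M
  L <- length(idx)
  lod <- log2(20 * hmm$match_emissions)
  tr <- hmm$transitions
  emit <- function(j, i) if (idx[i] < 0) 0 else lod[j, idx[i] + 1]
  scores <- numeric(0)
  rec <- function(j, i, acc) {
    scores <<- c(scores, acc)          # exit after any match state
    if (j >= M) return()
    if (i < L) {                       # match -> match
      rec(j + 1, i + 1, acc + tr$MM[j] + emit(j + 1, i + 1))
    }
    ## match -> insert^n -> match (inserts consume residues, emit 0)
    n_max <- L - i - 1
    if (n_max >= 1) {
      for (n in seq_len(n_max)) {
        acc2 <- acc + tr$MI[j] + (n - 1) * tr$II[j] + tr$IM[j]
        rec(j + 1, i + n + 1, acc2 + emit(j + 1, i + n + 1))
      }
    }
    ## match -> delete^d -> match (deletes consume no residue)
    if (i < L && M - j - 1 >= 1) {
      for (d in seq_len(M - j - 1)) {
        acc2 <- acc + tr$MD[j] +
          (if (d > 1) sum(tr$DD[(j + 1):(j + d - 1)]) else 0) +
          tr$DM[j + d]
        rec(j + d + 1, i + 1, acc2 + emit(j + d + 1, i + 1))
      }
    }
  }
  for (i0 in seq_len(L)) {
    for (j0 in seq_len(M)) {
      rec(j0, i0, -log2(M) + emit(j0, i0))
    }
  }
  list(viterbi = max(scores), forward = log2(sum(2^scores)))
}

## Random small profile HMM built from a random gapless alignment.
random_small_hmm <- function(M, n_seq = 3) {
  aln <- vapply(seq_len(n_seq), function(i) {
    paste(sample(secoscreen:::AA_ALPHABET, M, replace = TRUE),
          collapse = "")
  }, character(1))
  names(aln) <- paste0("s", seq_len(n_seq))
  build_profile_hmm(aln, family = "toy")
}

## Smith-Waterman with affine gaps, naive three-matrix DP. A gap of
## length k costs gap_open + k * gap_extend.
sw_oracle <- function(a, b, sm) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- sm$gap_open; ge <- sm$gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      FF[i, j] <- max(H[i - 1, j] - go - ge, FF[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sm$matrix[A[i - 1], B[j - 1]],
                     E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

## LCA by brute-force ancestor-set intersection, deepest common node.
lca_oracle <- function(ids, tree) {
  paths <- lapply(ids, function(i) secoscreen:::taxon_ancestors(tree, i))
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(i) {
    length(secoscreen:::taxon_ancestors(tree, i))
  }, numeric(1))
  common[which.max(depth)]
}

## Random taxonomy tree with up to n nodes respecting rank ordering.
random_taxonomy <- function(n) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  nodes <- data.frame(taxon_id = 1L, parent_id = NA_integer_,
                      rank = "domain", name = "d__root",
                      stringsAsFactors = FALSE)
  for (i in 2:n) {
    ok <- which(match(nodes$rank, ranks) < length(ranks))
    p <- nodes$taxon_id[ok[sample.int(length(ok), 1)]]
    pr <- match(nodes$rank[nodes$taxon_id == p], ranks)
    deeper <- (pr + 1):length(ranks)
    r <- deeper[sample.int(length(deeper), 1)]
    nodes <- rbind(nodes, data.frame(
      taxon_id = i, parent_id = p, rank = ranks[r],
      name = sprintf("%s__n%d", substr(ranks[r], 1, 1), i),
      stringsAsFactors = FALSE))
  }
  taxonomy_tree(nodes)
}
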