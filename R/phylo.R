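#' Progressive multiple alignment (center star)
#'
#' The center sequence is the one maximizing the summed pairwise global
#' alignment scores (ties broken by lexicographic id); every other
#' sequence is aligned globally to the center and the pairwise alignments
#' are merged column-wise ("once a gap, always a gap"). Deterministic, and
#' column content does not depend on the input order of the non-center
#' sequences. Degapping any row restores the original sequence.
#'
#' @param sequences Named character vector of protein sequences (>= 1).
#' @param sm A [scoring_matrix()]; the gap penalties act as the global
#'   alignment gap costs.
#' @return Object of class `msa`: named character vector of aligned rows
#'   (equal lengths), in the input order.
#' @export
progressive_msa <- function(sequences, sm = scoring_matrix()) {
  ids <- names(sequences) %||% sprintf("s%03d", seq_along(sequences))
  names(sequences) <- ids
  if (length(sequences) == 1) {
    return(structure(sequences, class = "msa"))
  }
  n <- length(sequences)
  ## summed pairwise global scores -> center
  total <- stats::setNames(numeric(n), ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- .pa(sequences[[i]], sequences[[j]], sm, "global",
                score_only = TRUE)
      total[i] <- total[i] + sc
      total[j] <- total[j] + sc
    }
  }
  center <- ids[order(-total, ids)][1]
  others <- sort(setdiff(ids, center))

  rows <- list()
  rows[[center]] <- strsplit(sequences[[center]], "", fixed = TRUE)[[1]]
  for (id in others) {
    pa <- .pa(sequences[[id]], sequences[[center]], sm, "global")
    new_s <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                      "", fixed = TRUE)[[1]]
    new_c <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                      "", fixed = TRUE)[[1]]
    rows <- .merge_alignment(rows, center, new_c, new_s, id)
  }
  aligned <- vapply(rows, paste, character(1), collapse = "")
  structure(aligned[ids], class = "msa")
}

## Merge a new pairwise alignment (center row new_c, new sequence new_s)
## into the running set of aligned rows keyed by id; `center` names the
## master center row.
.merge_alignment <- function(rows, center, new_c, new_s, new_id) {
  master <- rows[[center]]
  out <- lapply(rows, function(r) character(0))
  out[[new_id]] <- character(0)
  i <- 1L; j <- 1L
  ni <- length(master); nj <- length(new_c)
  while (i <= ni || j <= nj) {
    mi <- if (i <= ni) master[i] else NULL
    cj <- if (j <= nj) new_c[j] else NULL
    if (!is.null(mi) && !is.null(cj) &&
        ((mi != "-" && cj != "-") || (mi == "-" && cj == "-"))) {
      for (id in names(rows)) out[[id]] <- c(out[[id]], rows[[id]][i])
      out[[new_id]] <- c(out[[new_id]], new_s[j])
      i <- i + 1L; j <- j + 1L
    } else if (!is.null(mi) && (is.null(cj) || mi == "-")) {
      ## master has a gap column the new alignment lacks
      for (id in names(rows)) out[[id]] <- c(out[[id]], rows[[id]][i])
      out[[new_id]] <- c(out[[new_id]], "-")
      i <- i + 1L
    } else {
      ## new alignment inserts a gap into the center
      for (id in names(rows)) out[[id]] <- c(out[[id]], "-")
      out[[new_id]] <- c(out[[new_id]], new_s[j])
      j <- j + 1L
    }
  }
  out
}

#' @export
as.character.msa <- function(x, ...) unclass(x)

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences, %d columns\n", length(x),
              nchar(x[[1]])))
  invisible(x)
}

#' Pairwise p-distance matrix of an alignment
#'
#' d(i, j) = 1 - identity over the columns where both rows are ungapped.
#' A pair with no comparable column has no defined distance and raises an
#' error.
#'
#' @param msa An [progressive_msa()] result (or named character vector of
#'   equal-length aligned sequences).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  seqs <- if (inherits(msa, "msa")) unclass(msa) else msa
  ids <- names(seqs) %||% sprintf("s%03d", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1) stop("ragged alignment")
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", ids[i], " and ", ids[j])
      }
      d[i, j] <- d[j, i] <- mean(chars[i, ok] != chars[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration. Negative branch lengths (a
#' known NJ artifact on non-additive matrices) are clamped to zero and the
#' total clamped deficit is reported via a message.
#'
#' @param matrix Symmetric distance matrix with at least 3 taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(matrix) {
  if (!isSymmetric(unname(as.matrix(matrix)), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  m <- as.matrix(matrix)
  if (nrow(m) < 3) stop("need at least 3 taxa")
  tree <- ape::nj(m)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch lengths (total deficit %.4g)",
                    sum(neg), -sum(tree$edge.length[neg])))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the full-data tree with
#' the percentage of replicates containing the same bipartition. Supports
#' land in `tree$node.label`; the conventional display layer shows only
#' supports above 70.
#'
#' @param msa An alignment with at least 4 sequences.
#' @param n_replicates Number of bootstrap replicates (default 100). With
#'   0 replicates the tree is returned without supports, with a warning.
#' @param seed Integer seed; same seed gives identical supports.
#' @param outgroup Optional leaf id used to root the returned tree for
#'   display (inference itself is unrooted).
#' @return A `phylo` tree with `node.label` holding support percentages
#'   (`NA` for the root node).
#' @export
bootstrap_supports <- function(msa, n_replicates = 100, seed = 1,
                               outgroup = NULL) {
  seqs <- if (inherits(msa, "msa")) unclass(msa) else msa
  if (length(seqs) < 4) stop("need at least 4 sequences")
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  main <- neighbor_joining(p_distance_matrix(stats::setNames(
    apply(chars, 1, paste, collapse = ""), names(seqs))))
  if (n_replicates == 0) {
    warning("no bootstrap replicates requested; tree has no supports")
    if (!is.null(outgroup)) main <- ape::root(main, outgroup)
    return(main)
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(ncol(chars), replace = TRUE)
      boot <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      tryCatch(suppressMessages(
        neighbor_joining(p_distance_matrix(boot))),
        error = function(e) NULL)
    })
  })
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / length(reps), 1)
  if (!is.null(outgroup)) main <- ape::root(main, outgroup)
  main
}

#' Internal supports above a display cutoff
#'
#' @param tree Tree from [bootstrap_supports()].
#' @param cutoff Display threshold (default 70, strict).
#' @return Numeric vector of the supports shown under the convention.
#' @export
supports_shown <- function(tree, cutoff = 70) {
  s <- suppressWarnings(as.numeric(tree$node.label))
  s[!is.na(s) & s > cutoff]
}

#' Best-hit novelty score against a reference database
#'
#' Computes the best global-alignment identity of a query protein over a
#' reference set and assigns the report band: `low` below 60.4% identity,
#' `high` above 80%, `intermediate` otherwise. The band edges are report
#' annotations reflecting the observed split between divergent (e.g.
#' sponge-derived) and well-represented homologs, not a fitted classifier.
#'
#' @param query Protein sequence.
#' @param ref_db Named character vector of reference proteins.
#' @param sm A [scoring_matrix()].
#' @param query_id Label for the query.
#' @return List with `query_id`, `best_ref`, `identity` (%), `band`.
#' @export
novelty_score <- function(query, ref_db, sm = scoring_matrix(),
                          query_id = NA_character_) {
  stopifnot(length(ref_db) > 0)
  ids <- names(ref_db) %||% sprintf("ref%03d", seq_along(ref_db))
  best_id <- NA_character_; best <- -Inf
  for (k in seq_along(ref_db)) {
    pa <- .pa(query, ref_db[[k]], sm, "global")
    ident <- 100 * Biostrings::nmatch(pa) /
      nchar(as.character(Biostrings::alignedPattern(pa)))
    if (ident > best) {
      best <- ident
      best_id <- ids[k]
    }
  }
  band <- if (best < 60.4) "low" else if (best > 80) "high" else "intermediate"
  list(query_id = query_id, best_ref = best_id, identity = best, band = band)
}

#' Write a tree with supports to Newick
#'
#' Support values are carried as internal node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
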