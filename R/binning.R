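## Canonical 4-mer classes: a 4-mer and its reverse complement share one
## coordinate; 136 classes (120 pairs + 16 palindromes).
.tnf_classes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      kmers <- apply(
        expand.grid(rep(list(c("A", "C", "G", "T")), 4))[, 4:1], 1,
        paste, collapse = "")
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
      canon <- ifelse(kmers <= rc, kmers, rc)
      cache <<- list(kmers = kmers, canon = canon,
                     classes = sort(unique(canon)))
    }
    cache
  }
})

#' Tetranucleotide frequency vector of a sequence
#'
#' Counts all 256 4-mer windows (windows containing N or other ambiguity
#' codes are skipped), collapses reverse-complement pairs onto 136
#' canonical classes and normalizes to sum 1, so `tnf(s)` equals
#' `tnf(reverse_complement(s))`. Returns `NULL` (undefined; the contig is
#' left unbinned) when the sequence has no valid 4-mer window.
#'
#' @param sequence Nucleotide string (length >= 4 for a defined vector).
#' @return Named numeric vector over the 136 canonical classes, or `NULL`.
#' @export
tnf <- function(sequence) {
  if (nchar(sequence) < 4) return(NULL)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(sequence)), width = 4)
  if (sum(counts) == 0) return(NULL)
  cl <- .tnf_classes()
  v <- tapply(as.numeric(counts[cl$kmers]), cl$canon, sum)[cl$classes]
  v / sum(v)
}

#' TNF matrix for a contig set
#'
#' @param contigs A [contig_set()].
#' @param min_len Contigs shorter than this are excluded (left unbinned).
#' @return List with `matrix` (rows = binnable contigs) and `unbinned`
#'   (ids excluded for length or undefined composition).
#' @export
tnf_matrix <- function(contigs, min_len = 1000) {
  seqs <- as.character(contigs$seqs)
  ok <- nchar(seqs) >= min_len
  vecs <- lapply(seqs[ok], tnf)
  defined <- !vapply(vecs, is.null, logical(1))
  m <- do.call(rbind, vecs[defined])
  rownames(m) <- names(seqs)[ok][defined]
  list(matrix = m,
       unbinned = c(names(seqs)[!ok], names(seqs)[ok][!defined]))
}

#' Cluster contigs by tetranucleotide composition
#'
#' k-means on log-transformed TNF vectors. With `k = "auto"` the number of
#' clusters is chosen by maximizing the Calinski-Harabasz index over
#' `k_range` (on compositional data it recovers the true genome count
#' where mean silhouette tends to undersplit); the mean silhouette width
#' is still computed, and when even the best clustering is weak
#' (silhouette < 0.25) or all vectors are identical, a single bin is
#' returned. Deterministic for a fixed seed.
#'
#' @param vectors Numeric matrix of TNF vectors (rows = contigs, named).
#' @param k `"auto"` or a fixed number of bins.
#' @param seed Integer seed.
#' @param k_range Candidate k values for silhouette selection.
#' @return Object of class `bin_set`: `membership` data frame
#'   (`contig_id`, `bin_id`), `k`, `silhouette`.
#' @export
cluster_contigs <- function(vectors, k = "auto", seed = 1, k_range = 2:8) {
  n <- nrow(vectors)
  if (is.null(n) || n < 2) stop("need at least 2 contigs with defined vectors")
  if (nrow(unique(vectors)) == 1) {
    warning("all TNF vectors identical; returning a single bin")
    return(structure(list(membership = data.frame(
      contig_id = rownames(vectors), bin_id = "bin_1",
      stringsAsFactors = FALSE), k = 1L, silhouette = NA_real_),
      class = "bin_set"))
  }
  lv <- log(vectors + 1 / (2 * ncol(vectors)))
  pick <- with_seed(seed, {
    if (identical(k, "auto")) {
      ks <- k_range[k_range >= 2 & k_range <= n - 1]
      d <- stats::dist(lv)
      fits <- lapply(ks, function(kk) {
        km <- stats::kmeans(lv, centers = kk, nstart = 10, iter.max = 100)
        sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
        ch <- (km$betweenss / (kk - 1)) / (km$tot.withinss / (n - kk))
        list(km = km, sil = sil, ch = ch)
      })
      chs <- vapply(fits, `[[`, numeric(1), "ch")
      best <- which.max(chs)
      if (fits[[best]]$sil < 0.25) {
        list(cluster = rep(1L, n), k = 1L, sil = fits[[best]]$sil)
      } else {
        list(cluster = fits[[best]]$km$cluster, k = ks[best],
             sil = fits[[best]]$sil)
      }
    } else {
      k <- as.integer(k)
      if (k == 1) {
        list(cluster = rep(1L, n), k = 1L, sil = NA_real_)
      } else {
        km <- stats::kmeans(lv, centers = k, nstart = 10, iter.max = 100)
        sil <- mean(cluster::silhouette(km$cluster,
                                        stats::dist(lv))[, "sil_width"])
        list(cluster = km$cluster, k = k, sil = sil)
      }
    }
  })
  structure(list(membership = data.frame(
    contig_id = rownames(vectors),
    bin_id = sprintf("bin_%d", pick$cluster),
    stringsAsFactors = FALSE), k = pick$k, silhouette = pick$sil),
    class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("<bin_set> %d contigs in %d bins (mean silhouette %s)\n",
              nrow(x$membership), x$k,
              if (is.na(x$silhouette)) "NA" else sprintf("%.2f", x$silhouette)))
  invisible(x)
}

#' Bin a contig set end to end
#'
#' Computes TNF vectors (contigs shorter than `min_len` stay unbinned),
#' clusters them, and attaches per-bin assembly statistics. Bins partition
#' the binnable contigs; the unbinned pool is explicit.
#'
#' @param contigs A [contig_set()].
#' @inheritParams cluster_contigs
#' @param min_len Minimum contig length for binning (default 1000 bp).
#' @return A `bin_set` with additional elements `unbinned` and `bins`
#'   (per-bin data frame: bin_id, n_contigs, total_length, n50).
#' @export
bin_contigs <- function(contigs, k = "auto", seed = 1, min_len = 1000,
                        k_range = 2:8) {
  tm <- tnf_matrix(contigs, min_len = min_len)
  if (is.null(tm$matrix) || nrow(tm$matrix) < 2) {
    stop("fewer than 2 binnable contigs")
  }
  bs <- cluster_contigs(tm$matrix, k = k, seed = seed, k_range = k_range)
  bs$unbinned <- tm$unbinned
  lens <- stats::setNames(Biostrings::width(contigs$seqs),
                          names(contigs$seqs))
  bins <- lapply(split(bs$membership$contig_id, bs$membership$bin_id),
                 function(ids) {
    st <- compute_assembly_stats(lens[ids])
    data.frame(n_contigs = st$n_contigs, total_length = st$total_length,
               n50 = st$n50)
  })
  bdf <- do.call(rbind, bins)
  bs$bins <- cbind(bin_id = names(bins), bdf, stringsAsFactors = FALSE)
  rownames(bs$bins) <- NULL
  bs
}

#' Marker-based bin quality estimate
#'
#' Completeness is the percentage of single-copy marker families present
#' in the bin; contamination is the percentage of extra marker copies
#' (copies beyond the first, summed over families, relative to the marker
#' set size).
#'
#' @param bin_marker_hits Marker-model hits restricted to the bin's
#'   proteins (columns `family`, `protein_id`).
#' @param bin_id Bin label.
#' @param markers Marker family registry.
#' @return List with `bin_id`, `completeness`, `contamination`,
#'   `marker_counts`.
#' @export
assess_bin <- function(bin_marker_hits, bin_id = NA_character_,
                       markers = marker_families()) {
  hits <- bin_marker_hits[bin_marker_hits$family %in% markers, , drop = FALSE]
  counts <- if (nrow(hits) > 0) {
    tapply(hits$protein_id, hits$family, function(p) length(unique(p)))
  } else integer(0)
  counts <- counts[!is.na(counts)]
  list(bin_id = bin_id,
       completeness = 100 * length(counts) / length(markers),
       contamination = 100 * sum(pmax(0, counts - 1)) / length(markers),
       marker_counts = counts)
}

#' MAG quality gate
#'
#' Keeps bins with completeness strictly above `completeness_min` and
#' contamination strictly below `contamination_max` (both strict, per the
#' "more than" / "below" selection rule).
#'
#' @param estimates Data frame with columns `bin_id`, `completeness`,
#'   `contamination` (or a list of [assess_bin()] results).
#' @param completeness_min Completeness threshold in percent (default 25).
#' @param contamination_max Contamination threshold in percent (default 10).
#' @return The kept rows of `estimates`.
#' @export
gate_bins <- function(estimates, completeness_min = 25,
                      contamination_max = 10) {
  if (!is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(bin_id = e$bin_id, completeness = e$completeness,
                 contamination = e$contamination, stringsAsFactors = FALSE)
    }))
  }
  keep <- estimates$completeness > completeness_min &
    estimates$contamination < contamination_max
  estimates[keep, , drop = FALSE]
}
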