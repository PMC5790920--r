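#' Assembled contigs for one metagenome sample
#'
#' Light container pairing a sample id and environment code with a
#' `DNAStringSet` of contigs. Sequences are uppercased on construction and
#' restricted to the alphabet A, C, G, T, N; contig ids must be unique.
#'
#' @param sample_id Sample identifier.
#' @param environment_code Three-letter environment code plus sample
#'   number, e.g. `"WWT_7"`.
#' @param sequences Named character vector or `DNAStringSet` of contigs.
#' @return An object of class `contig_set`.
#' @export
contig_set <- function(sample_id, environment_code = sample_id,
                       sequences = character()) {
  if (is.character(sequences)) {
    ids <- names(sequences) %||% character(0)
  } else {
    ids <- names(sequences)
  }
  if (length(sequences) > 0 && (is.null(ids) || anyNA(ids) || any(ids == ""))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate contig id: ", ids[duplicated(ids)][1])
  }
  chars <- toupper(as.character(sequences))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("contig ", ids[bad][1], " contains characters outside {A,C,G,T,N}")
  }
  seqs <- Biostrings::DNAStringSet(chars)
  names(seqs) <- ids
  structure(list(sample_id = sample_id,
                 environment_code = environment_code,
                 seqs = seqs),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  st <- compute_assembly_stats(x)
  cat(sprintf("<contig_set %s [%s]> %d contigs, %d bp total, N50 %d\n",
              x$sample_id, x$environment_code, st$n_contigs,
              st$total_length, st$n50))
  invisible(x)
}

#' @export
length.contig_set <- function(x) length(x$seqs)

#' Read assembled contigs from FASTA
#'
#' Multi-line records are supported; sequences are uppercased. Duplicate
#' ids raise an error naming the offending id; an empty file yields an
#' empty set with a warning.
#'
#' @param path FASTA file.
#' @param sample_id,environment_code Labels; default to the file stem.
#' @return A [contig_set()].
#' @export
read_fasta <- function(path, sample_id = NULL, environment_code = NULL) {
  sample_id <- sample_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path))
  environment_code <- environment_code %||% sample_id
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    warning("empty FASTA file: ", path)
  }
  ## keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", names(seqs))
  v <- as.character(seqs)
  names(v) <- nm
  contig_set(sample_id, environment_code, v)
}

#' Write a contig set to FASTA
#'
#' Round-trips with [read_fasta()]: ids and sequences are preserved.
#'
#' @param contigs A [contig_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  stopifnot(inherits(contigs, "contig_set"))
  Biostrings::writeXStringSet(contigs$seqs, filepath = path)
  invisible(path)
}

#' Assembly statistics for a contig set
#'
#' N50 is the largest length L such that contigs of length >= L sum to at
#' least half of the total assembly length. Ambiguous bases (N) count
#' toward contig length: the statistics describe assembly extent, not
#' information content. An empty set yields all zeros.
#'
#' @param contigs A [contig_set()] or an integer vector of contig lengths.
#' @return List with `n50`, `max_contig`, `total_length`, `n_contigs`.
#' @export
compute_assembly_stats <- function(contigs) {
  lens <- if (inherits(contigs, "contig_set")) {
    Biostrings::width(contigs$seqs)
  } else {
    as.integer(contigs)
  }
  if (length(lens) == 0) {
    return(list(n50 = 0L, max_contig = 0L, total_length = 0L, n_contigs = 0L))
  }
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(as.numeric(lens))
  csum <- cumsum(as.numeric(lens))
  n50 <- lens[which(csum >= total / 2)[1]]
  list(n50 = as.integer(n50),
       max_contig = as.integer(lens[1]),
       total_length = as.integer(total),
       n_contigs = length(lens))
}

#' Metagenome selection gate
#'
#' A sample passes when its N50 is strictly higher than `n50_min` and it
#' contains at least one contig strictly longer than `contig_min`. Both
#' inequalities are strict, following the wording of the selection rule
#' ("higher than" / "longer than").
#'
#' @param stats Result of [compute_assembly_stats()].
#' @param n50_min N50 threshold in bp (default 300).
#' @param contig_min Longest-contig threshold in bp (default 600).
#' @return List with `pass` (logical) and `reason` (string; `NA` on pass).
#' @export
select_metagenome <- function(stats, n50_min = 300, contig_min = 600) {
  if (stats$n50 <= n50_min) {
    return(list(pass = FALSE,
                reason = sprintf("N50 %d not higher than %d", stats$n50, n50_min)))
  }
  if (stats$max_contig <= contig_min) {
    return(list(pass = FALSE,
                reason = sprintf("longest contig %d not longer than %d",
                                 stats$max_contig, contig_min)))
  }
  list(pass = TRUE, reason = NA_character_)
}
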