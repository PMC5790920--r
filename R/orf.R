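#' Six-frame ORF calling
#'
#' Scans all six reading frames of each contig. An ORF is a maximal
#' stop-to-stop stretch, reported from its first ATG; the translated
#' protein runs from that methionine to the last complete codon before the
#' stop (or contig end). Coordinates are 1-based inclusive nucleotide
#' positions on the forward strand of the contig; codons containing N
#' translate to the wildcard X. The caller is deliberately simple;
#' externally predicted proteins can be supplied directly to
#' [scan_sample()] to bypass it.
#'
#' @param contig A nucleotide string, a named character vector of contigs,
#'   or a [contig_set()].
#' @param min_protein_len Minimum protein length in residues (default 60).
#' @param contig_id,sample_id Labels used when `contig` is a bare string.
#' @return Data frame of protein records: `protein_id`, `sample_id`,
#'   `contig_id`, `start`, `end`, `strand`, `frame`, `sequence`.
#' @export
call_orfs <- function(contig, min_protein_len = 60,
                      contig_id = "contig", sample_id = NA_character_) {
  if (inherits(contig, "contig_set")) {
    seqs <- as.character(contig$seqs)
    out <- lapply(seq_along(seqs), function(i) {
      call_orfs(seqs[i], min_protein_len,
                contig_id = names(seqs)[i], sample_id = contig$sample_id)
    })
    res <- do.call(rbind, out)
    if (is.null(res)) res <- .empty_protein_df()
    return(res)
  }
  if (length(contig) > 1 || !is.null(names(contig))) {
    ids <- names(contig) %||% sprintf("contig%03d", seq_along(contig))
    out <- lapply(seq_along(contig), function(i) {
      call_orfs(unname(contig[i]), min_protein_len,
                contig_id = ids[i], sample_id = sample_id)
    })
    res <- do.call(rbind, out)
    if (is.null(res)) res <- .empty_protein_df()
    return(res)
  }

  contig <- toupper(contig)
  L <- nchar(contig)
  rows <- list()
  code <- Biostrings::GENETIC_CODE
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    for (frame in 1:3) {
      n_cod <- (L - frame + 1L) %/% 3L
      if (n_cod < 1) next
      starts <- frame + 3L * (seq_len(n_cod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      aa <- unname(code[codons])
      aa[is.na(aa)] <- "X"
      ## split at stops into maximal stretches
      stop_at <- c(0L, which(aa == "*"), n_cod + 1L)
      for (b in seq_len(length(stop_at) - 1L)) {
        lo <- stop_at[b] + 1L
        hi <- stop_at[b + 1L] - 1L
        if (hi < lo) next
        seg <- aa[lo:hi]
        m <- which(seg == "M")[1]
        if (is.na(m)) next
        k0 <- lo + m - 1L       # codon index of the ATG
        prot <- paste(aa[k0:hi], collapse = "")
        if (nchar(prot) < min_protein_len) next
        s_start <- frame + 3L * (k0 - 1L)
        s_end <- frame + 3L * hi - 1L
        if (strand == "+") {
          start <- s_start; end <- s_end
        } else {
          start <- L - s_end + 1L; end <- L - s_start + 1L
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sample_id, contig_id = contig_id,
          start = start, end = end, strand = strand, frame = frame,
          sequence = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(.empty_protein_df())
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$strand, df$frame), , drop = FALSE]
  df <- cbind(protein_id = sprintf("%s_p%04d", contig_id, seq_len(nrow(df))),
              df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

.empty_protein_df <- function() {
  data.frame(protein_id = character(), sample_id = character(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), sequence = character(),
             stringsAsFactors = FALSE)
}
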