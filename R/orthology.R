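#' Protein scoring scheme for pairwise alignment
#'
#' A symmetric substitution matrix with affine gap penalties (positive
#' numbers; they are subtracted). Defaults follow common protein-BLAST
#' practice: BLOSUM62 with gap open 11, gap extend 1.
#'
#' @param matrix A symmetric substitution matrix or the name of a matrix
#'   shipped with Biostrings (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (> 0).
#' @return Object of class `scoring_matrix`.
#' @export
scoring_matrix <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  if (!isSymmetric(unname(matrix))) stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend <= 0) stop("gap penalties must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_matrix")
}

## pairwiseAlignment gap arguments: gapOpening is charged on opening plus
## gapExtension per gap position, so an L-gap costs open + L * extend.
.pa <- function(a, b, sm, type, score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type,
    substitutionMatrix = sm$matrix,
    gapOpening = sm$gap_open, gapExtension = sm$gap_extend,
    scoreOnly = score_only)
}

#' Optimal local alignment (Smith-Waterman) of two proteins
#'
#' Exact dynamic programming under affine gap penalties. Identity is
#' matches over aligned columns (gap columns included); coverage is the
#' aligned query span over the query length. When no positive-scoring
#' local alignment exists the score floor of 0 is returned with an empty
#' alignment.
#'
#' @param a,b Nonempty protein sequences (`a` is the query).
#' @param sm A [scoring_matrix()].
#' @return List with `score`, `identity` (%), `coverage` (%),
#'   `aligned` (two-element character vector of aligned strings).
#' @export
smith_waterman <- function(a, b, sm = scoring_matrix()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  pa <- .pa(a, b, sm, "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, identity = 0, coverage = 0,
                aligned = c("", "")))
  }
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  ncol_aln <- nchar(ap)
  ident <- 100 * Biostrings::nmatch(pa) / ncol_aln
  span <- IRanges::width(Biostrings::pattern(pa)@range)
  list(score = sc, identity = ident,
       coverage = 100 * span / nchar(a),
       aligned = c(ap, as_))
}

## Local-alignment scores of one query against many references
## (vectorized over the references).
sw_scores <- function(query, refs, sm = scoring_matrix()) {
  sc <- vapply(as.character(refs), function(r) {
    .pa(query, r, sm, "local", score_only = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  sc[sc < 0] <- 0
  stats::setNames(sc, names(refs))
}

## Full score matrix queries x references.
sw_score_matrix <- function(queries, refs, sm = scoring_matrix()) {
  out <- matrix(0, nrow = length(queries), ncol = length(refs),
                dimnames = list(names(queries), names(refs)))
  for (j in seq_along(refs)) {
    sc <- .pa(as.character(queries), refs[[j]], sm, "local",
              score_only = TRUE)
    out[, j] <- pmax(sc, 0)
  }
  out
}

## Best hit per row of a score matrix with the tie rule: higher score,
## then higher identity, then lexicographically smaller id.
.best_hit <- function(scores, q, qseqs, rseqs, sm) {
  s <- stats::setNames(scores[q, ], colnames(scores))
  if (max(s) <= 0) return(NA_character_)
  cand <- names(s)[s == max(s)]
  if (length(cand) > 1) {
    ident <- vapply(cand, function(r) {
      smith_waterman(qseqs[[q]], rseqs[[r]], sm)$identity
    }, numeric(1))
    cand <- cand[order(-ident, cand)]
  }
  cand[1]
}

#' Reciprocal-best-hit ortholog calls between two proteomes
#'
#' A pair (q, r) is called when r is q's best local-alignment hit, q is
#' r's best hit, and the q-vs-r alignment passes the identity and query
#' coverage thresholds. Ties are broken by identity, then lexicographic
#' id. The result is a partial matching: each protein occurs in at most
#' one call.
#'
#' @param q_proteins,r_proteins Named character vectors of protein
#'   sequences (both nonempty).
#' @param sm A [scoring_matrix()].
#' @param min_identity Identity threshold in percent (default 30, `>=`).
#' @param min_coverage Query coverage threshold in percent (default 70).
#' @return Data frame: `query_id`, `ref_id`, `score`, `identity`,
#'   `coverage`.
#' @export
reciprocal_best_hits <- function(q_proteins, r_proteins,
                                 sm = scoring_matrix(),
                                 min_identity = 30, min_coverage = 70) {
  stopifnot(length(q_proteins) > 0, length(r_proteins) > 0)
  scores <- sw_score_matrix(q_proteins, r_proteins, sm)
  rows <- list()
  for (q in names(q_proteins)) {
    r <- .best_hit(scores, q, q_proteins, r_proteins, sm)
    if (is.na(r)) next
    ## reciprocal check: is q the best hit of r among all queries?
    qback <- .best_hit(t(scores), r, r_proteins, q_proteins, sm)
    if (!identical(qback, q)) next
    aln <- smith_waterman(q_proteins[[q]], r_proteins[[r]], sm)
    if (aln$identity < min_identity || aln$coverage < min_coverage) next
    rows[[length(rows) + 1]] <- data.frame(
      query_id = q, ref_id = r, score = aln$score,
      identity = aln$identity, coverage = aln$coverage,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(query_id = character(), ref_id = character(),
                      score = numeric(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Strain registry of the reference degrader panel.
.PANEL_STRAINS <- c(
  Mtu = "Mycobacterium tuberculosis H37Rv",
  Rjo = "Rhodococcus jostii RHA1",
  Cte = "Comamonas testosteroni CNB-2",
  Pch = "Pseudomonas stutzeri Chol1",
  Pha = "Pseudoalteromonas haloplanktis TAC125")

#' Synthetic reference degrader panel
#'
#' A deterministically generated stand-in for the proteomes of the five
#' characterized reference steroid degraders (the real proteomes are not
#' bundled). Each strain carries one annotated protein per configured
#' family, diverged from the family ancestor, plus unannotated background
#' proteins. Users may substitute a real panel of the same shape: per
#' strain, `proteins` (named sequences) and `annotation` (family per
#' protein id, `NA` for background proteins).
#'
#' @param families Family registry.
#' @param strain_divergence Divergence of each strain's family proteins
#'   from the family ancestor.
#' @param n_background Unannotated proteins per strain.
#' @return Named list (one element per strain) of lists with `strain`,
#'   `proteins`, `annotation`.
#' @export
synthetic_reference_panel <- function(families = steroid_families(),
                                      strain_divergence = 0.08,
                                      n_background = 5L) {
  anc <- family_ancestors(families)
  out <- lapply(seq_along(.PANEL_STRAINS), function(si) {
    code <- names(.PANEL_STRAINS)[si]
    with_seed(.REGISTRY_SEED + 5000L + si, {
      prot <- vapply(families, function(f) {
        mutate_protein(anc[[f]], strain_divergence,
                       sample.int(.Machine$integer.max, 1))
      }, character(1))
      names(prot) <- paste0(code, "_", families)
      bg <- vapply(seq_len(n_background), function(i) {
        random_protein(120L, start_met = TRUE)
      }, character(1))
      names(bg) <- sprintf("%s_bg%02d", code, seq_len(n_background))
      ann <- c(stats::setNames(families, names(prot)),
               stats::setNames(rep(NA_character_, n_background), names(bg)))
      list(strain = unname(.PANEL_STRAINS[si]),
           proteins = c(prot, bg), annotation = ann)
    })
  })
  names(out) <- names(.PANEL_STRAINS)
  out
}

#' Ortholog calls of a MAG against the full reference panel
#'
#' Runs [reciprocal_best_hits()] against each panel strain and keeps the
#' calls whose reference protein carries a family annotation.
#'
#' @param mag_proteins Named character vector of the MAG's proteins.
#' @param panel Result of [synthetic_reference_panel()] (or same shape).
#' @param sm,min_identity,min_coverage Passed to
#'   [reciprocal_best_hits()].
#' @return Data frame: `query_id`, `ref_id`, `strain`, `family`,
#'   `score`, `identity`, `coverage`.
#' @export
panel_ortholog_calls <- function(mag_proteins, panel,
                                 sm = scoring_matrix(),
                                 min_identity = 30, min_coverage = 70) {
  rows <- lapply(panel, function(st) {
    rbh <- reciprocal_best_hits(mag_proteins, st$proteins, sm,
                                min_identity, min_coverage)
    if (nrow(rbh) == 0) return(NULL)
    rbh$strain <- st$strain
    rbh$family <- unname(st$annotation[rbh$ref_id])
    rbh[!is.na(rbh$family), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_id = character(), ref_id = character(),
                      score = numeric(), identity = numeric(),
                      coverage = numeric(), strain = character(),
                      family = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Pathway completeness of a MAG
#'
#' The number of distinct configured families with at least one ortholog
#' call against any panel strain (0-10 under the default registry).
#'
#' @param calls Ortholog calls with a `family` column.
#' @param families Family registry.
#' @return Integer count.
#' @export
pathway_completeness <- function(calls, families = steroid_families()) {
  length(intersect(families, unique(calls$family)))
}

#' Assemble a MAG pathway profile
#'
#' @param mag_id MAG label.
#' @param hmm_families_present Families with HMM hits among the MAG's
#'   proteins.
#' @param ortholog_calls Optional [panel_ortholog_calls()] result.
#' @param families Family registry.
#' @return Object of class `mag_profile` with the HMM presence, key-enzyme
#'   flags, pathway completeness and both degrader flags.
#' @export
mag_profile <- function(mag_id, hmm_families_present, ortholog_calls = NULL,
                        families = steroid_families()) {
  present <- intersect(families, hmm_families_present)
  p <- structure(list(
    mag_id = mag_id,
    hmm_families_present = present,
    has_kshA_hit = "KshA" %in% present,
    has_hsaC_hit = "HsaC" %in% present,
    ortholog_calls = ortholog_calls,
    pathway_completeness = if (!is.null(ortholog_calls)) {
      pathway_completeness(ortholog_calls, families)
    } else NA_integer_),
    class = "mag_profile")
  p$predicted_degrader <- classify_predicted_degrader(p)
  p$confirmed_degrader <- if (!is.null(ortholog_calls)) {
    confirm_degrader(p)
  } else NA
  p
}

#' @export
print.mag_profile <- function(x, ...) {
  cat(sprintf(
    "<mag_profile %s> %d HMM families (KshA %s, HsaC %s), completeness %s; predicted %s, confirmed %s\n",
    x$mag_id, length(x$hmm_families_present),
    x$has_kshA_hit, x$has_hsaC_hit,
    ifelse(is.na(x$pathway_completeness), "-", x$pathway_completeness),
    x$predicted_degrader, x$confirmed_degrader))
  invisible(x)
}

#' Predicted-degrader classification rule
#'
#' A MAG is a predicted steroid degrader when its proteins have HMM hits
#' for at least `min_families` of the configured families, including at
#' least one KshA or HsaC hit.
#'
#' @param profile A [mag_profile()].
#' @param min_families Family-count threshold (default 5).
#' @return Logical flag.
#' @export
classify_predicted_degrader <- function(profile, min_families = 5) {
  length(profile$hmm_families_present) >= min_families &&
    (profile$has_kshA_hit || profile$has_hsaC_hit)
}

#' Confirmed-degrader rule (pluggable)
#'
#' Default rule: pathway completeness of at least `min_completeness`
#' ortholog-supported families, including an ortholog call for KshA or
#' HsaC. The criterion behind published per-MAG confirmation flags is not
#' fully determined by those flags, so the rule is a replaceable function.
#'
#' @param profile A [mag_profile()] with ortholog calls.
#' @param rule Optional replacement: a `function(profile)` returning a
#'   logical flag.
#' @param min_completeness Completeness threshold for the default rule.
#' @return Logical flag.
#' @export
confirm_degrader <- function(profile, rule = NULL, min_completeness = 6) {
  if (!is.null(rule)) return(rule(profile))
  if (is.null(profile$ortholog_calls)) stop("ortholog calls not computed")
  key_called <- any(key_families() %in% profile$ortholog_calls$family)
  profile$pathway_completeness >= min_completeness && key_called
}
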