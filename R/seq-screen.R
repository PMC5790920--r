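#' @useDynLib secoscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Encode a protein string as 0-based residue indices; residues outside
## the 20-letter alphabet (B, Z, X, ...) become -1 (background wildcard).
encode_protein <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  idx <- match(res, AA_ALPHABET) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

#' Build a profile HMM from a seed alignment
#'
#' Match states are the alignment columns with at most 50% gap characters.
#' Match emissions are Laplace-smoothed column residue counts; insert
#' states emit the uniform background. Transition probabilities are
#' Laplace-smoothed counts of the observed match/insert/delete state paths
#' of the seed sequences. The construction is fully deterministic.
#'
#' @param seed_alignment Named character vector of aligned protein
#'   sequences (gap characters `-` or `.`), or an `AAStringSet`. At least
#'   two sequences of equal aligned length.
#' @param family Family label carried by hits (e.g. `"KshA"`).
#' @param model_id Model identifier; several models may map to one family.
#' @param pseudocount Laplace pseudocount for emissions and transitions.
#' @return An object of class `profile_hmm` with elements `family`,
#'   `model_id`, `M`, `match_emissions` (M x 20 probability matrix),
#'   `transitions` (log2 scale), `consensus`, and (after
#'   [calibrate_hmm()]) `gumbel` and `bit_threshold`.
#' @export
build_profile_hmm <- function(seed_alignment, family = "unnamed",
                              model_id = family, pseudocount = 1) {
  aln <- as.character(seed_alignment)
  if (length(aln) < 2) stop("seed alignment needs at least 2 sequences")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: aligned lengths differ")
  }
  chars <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  chars[chars == "."] <- "-"
  n_seq <- nrow(chars)
  gap_frac <- colMeans(chars == "-")
  match_cols <- which(gap_frac <= 0.5)
  M <- length(match_cols)
  if (M < 1) stop("no match columns (all columns are majority-gap)")

  ## emissions: Laplace-smoothed residue counts per match column
  em <- matrix(pseudocount, nrow = M, ncol = 20,
               dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(M)) {
    col <- chars[, match_cols[k]]
    tab <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    em[k, ] <- em[k, ] + as.numeric(tab)
  }
  em <- em / rowSums(em)

  ## transitions: count state paths between consecutive match columns
  cnt <- list(MM = rep(pseudocount, max(M - 1, 0)),
              MI = rep(pseudocount, max(M - 1, 0)),
              MD = rep(pseudocount, max(M - 1, 0)),
              IM = rep(pseudocount, max(M - 1, 0)),
              II = rep(pseudocount, max(M - 1, 0)),
              DM = rep(pseudocount, max(M - 1, 0)),
              DD = rep(pseudocount, max(M - 1, 0)))
  if (M >= 2) {
    for (s in seq_len(n_seq)) {
      states <- ifelse(chars[s, match_cols] == "-", "D", "M")
      for (k in seq_len(M - 1)) {
        lo <- match_cols[k]; hi <- match_cols[k + 1]
        n_ins <- if (hi - lo > 1) {
          sum(chars[s, (lo + 1):(hi - 1)] != "-")
        } else 0L
        from <- states[k]; to <- states[k + 1]
        if (n_ins == 0) {
          key <- paste0(from, to)
          cnt[[key]][k] <- cnt[[key]][k] + 1
        } else {
          ## inserts between columns; transitions through I_k. Paths that
          ## would need the disallowed D->I / I->D moves are dropped.
          if (from == "M" && to == "M") {
            cnt$MI[k] <- cnt$MI[k] + 1
            cnt$II[k] <- cnt$II[k] + (n_ins - 1)
            cnt$IM[k] <- cnt$IM[k] + 1
          }
        }
      }
    }
  }
  norm2 <- function(a, b) {
    tot <- a + b
    list(log2(a / tot), log2(b / tot))
  }
  tot_m <- cnt$MM + cnt$MI + cnt$MD
  trans <- list(MM = log2(cnt$MM / tot_m),
                MI = log2(cnt$MI / tot_m),
                MD = log2(cnt$MD / tot_m))
  im <- norm2(cnt$IM, cnt$II); trans$IM <- im[[1]]; trans$II <- im[[2]]
  dm <- norm2(cnt$DM, cnt$DD); trans$DM <- dm[[1]]; trans$DD <- dm[[2]]

  structure(list(family = family, model_id = model_id, M = M,
                 match_emissions = em, transitions = trans,
                 pseudocount = pseudocount,
                 consensus = paste(AA_ALPHABET[max.col(em)], collapse = ""),
                 gumbel = NULL, bit_threshold = NULL),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm %s (model %s)> M = %d%s\n",
              x$family, x$model_id, x$M,
              if (!is.null(x$bit_threshold)) {
                sprintf(", bit threshold %.1f", x$bit_threshold)
              } else ", uncalibrated"))
  invisible(x)
}

.hmm_lod <- function(hmm) log2(20 * hmm$match_emissions)

.hmm_bits <- function(hmm, protein, forward) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nzchar(protein)) stop("protein must be nonempty")
  idx <- encode_protein(protein)
  if (any(idx < 0)) {
    message("nonstandard residues treated as background-emitting wildcards")
  }
  tr <- hmm$transitions
  hmm_dp_bits(idx, .hmm_lod(hmm), tr$MM, tr$MI, tr$MD,
              tr$IM, tr$II, tr$DM, tr$DD, forward)
}

#' Viterbi (best local path) bit score of a protein against a model
#'
#' Scores are log2-odds of the best local alignment path against a uniform
#' 20-letter background: the model may match any substring of the protein
#' (uniform entry over match states, free exit).
#'
#' @param hmm A [build_profile_hmm()] model.
#' @param protein Protein sequence (nonempty string).
#' @return Bit score (numeric scalar).
#' @export
viterbi_bits <- function(hmm, protein) .hmm_bits(hmm, protein, forward = FALSE)

#' Forward (summed over local paths) bit score
#'
#' Same model as [viterbi_bits()] but summing over all local alignment
#' paths; always at least the Viterbi score.
#'
#' @inheritParams viterbi_bits
#' @return Bit score (numeric scalar).
#' @export
forward_bits <- function(hmm, protein) .hmm_bits(hmm, protein, forward = TRUE)

## Sample a protein by emitting the match-state consensus path of the
## model (one residue per match state, drawn from the match emissions).
sample_hmm <- function(hmm, seed = 1) {
  with_seed(seed, {
    paste(vapply(seq_len(hmm$M), function(j) {
      sample(AA_ALPHABET, 1, prob = hmm$match_emissions[j, ])
    }, character(1)), collapse = "")
  })
}

#' Calibrate a model's score null with shuffled decoys
#'
#' Scores `n_decoys` random decoy proteins, fits a Gumbel
#' (location/scale, method of moments) to the resulting Viterbi score
#' distribution, and sets the model's default reporting threshold to the
#' Gumbel quantile at decoy false-positive rate `fpr`. E-values reported
#' by [scan_sample()] derive from this fit. Fully seeded and reproducible.
#'
#' The default `fpr` is deliberately strict: a screen multiplies the
#' per-comparison rate by (number of models) x (number of proteins), and
#' false marker assignments directly corrupt single-copy contamination
#' estimates, while genuine family members score orders of magnitude above
#' any plausible threshold.
#'
#' @param hmm A [build_profile_hmm()] model.
#' @param n_decoys Number of decoy proteins (default 1000).
#' @param decoy_length Decoy length; defaults to `max(100, M)`.
#' @param fpr Decoy false-positive rate defining the threshold.
#' @param seed Integer seed.
#' @return The model with `gumbel` and `bit_threshold` filled in.
#' @export
calibrate_hmm <- function(hmm, n_decoys = 1000,
                          decoy_length = max(100L, hmm$M),
                          fpr = 1e-6, seed = 1) {
  scores <- with_seed(seed, {
    idxs <- lapply(seq_len(n_decoys), function(i) {
      sample.int(20L, decoy_length, replace = TRUE) - 1L
    })
    tr <- hmm$transitions
    hmm_dp_bits_many(idxs, .hmm_lod(hmm), tr$MM, tr$MI, tr$MD,
                     tr$IM, tr$II, tr$DM, tr$DD, FALSE)
  })
  scale <- stats::sd(scores) * sqrt(6) / pi
  loc <- mean(scores) - 0.5772156649 * scale
  hmm$gumbel <- c(loc = loc, scale = scale)
  hmm$bit_threshold <- loc - scale * log(-log(1 - fpr))
  hmm$n_decoys <- n_decoys
  hmm
}

## Upper-tail Gumbel probability P(S >= s) for a calibrated model.
gumbel_upper <- function(gumbel, s) {
  p <- 1 - exp(-exp(-(s - gumbel["loc"]) / gumbel["scale"]))
  unname(pmax(p, .Machine$double.xmin))
}

#' Build and calibrate the default model set for a family registry
#'
#' One model per family, trained on the registry seed alignments and
#' calibrated with seeded decoys.
#'
#' @param families Family registry.
#' @param marker Build marker models instead of steroid-family models.
#' @param n_decoys Decoys per model for calibration.
#' @param seed Integer seed for calibration decoys.
#' @return Named list of calibrated `profile_hmm` objects.
#' @export
build_family_models <- function(families = steroid_families(),
                                marker = FALSE, n_decoys = 1000, seed = 1) {
  alns <- family_seed_alignments(families, marker = marker)
  models <- lapply(names(alns), function(fam) {
    m <- build_profile_hmm(alns[[fam]], family = fam, model_id = fam)
    calibrate_hmm(m, n_decoys = n_decoys,
                  seed = seed + sum(utf8ToInt(fam)) %% 10000L)
  })
  names(models) <- names(alns)
  models
}

#' Screen predicted proteins against a model set
#'
#' Scores every protein against every model (Viterbi bits). A protein may
#' hit several families, but within one family only its best-scoring model
#' is reported, so there is at most one hit per protein-family pair.
#' E-values are Gumbel tail probabilities from [calibrate_hmm()] times the
#' number of proteins scanned.
#'
#' @param proteins A data frame of protein records (as returned by
#'   [call_orfs()]) or a named character vector of protein sequences.
#' @param models List of `profile_hmm` objects (at least one family).
#' @param bit_threshold Reporting threshold; `NULL` uses each model's
#'   calibrated threshold.
#' @param sample_id Sample label attached to results.
#' @return List with `hits` (data frame: protein_id, contig_id, family,
#'   model_id, bit_score, e_value) and `profile` (family presence:
#'   `sample_id`, `families_present`, `n_families`).
#' @export
scan_sample <- function(proteins, models, bit_threshold = NULL,
                        sample_id = NULL) {
  if (length(models) == 0) stop("models must cover at least one family")
  if (is.data.frame(proteins)) {
    pr <- proteins
  } else {
    pr <- data.frame(protein_id = names(proteins) %||%
                       sprintf("p%04d", seq_along(proteins)),
                     contig_id = NA_character_,
                     sequence = as.character(proteins),
                     stringsAsFactors = FALSE)
  }
  sample_id <- sample_id %||% (if ("sample_id" %in% names(pr) && nrow(pr) > 0)
    pr$sample_id[1] else NA_character_)
  fam_all <- unique(vapply(models, function(m) m$family, character(1)))
  empty <- data.frame(protein_id = character(), contig_id = character(),
                      family = character(), model_id = character(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE)
  profile0 <- list(sample_id = sample_id, families_present = character(0),
                   n_families = 0L)
  if (nrow(pr) == 0) return(list(hits = empty, profile = profile0))

  enc <- lapply(pr$sequence, encode_protein)
  n <- nrow(pr)
  rows <- list()
  for (m in models) {
    thr <- bit_threshold %||% m$bit_threshold
    if (is.null(thr)) {
      stop("model ", m$model_id,
           " is uncalibrated and no bit_threshold was given")
    }
    tr <- m$transitions
    bits <- hmm_dp_bits_many(enc, .hmm_lod(m), tr$MM, tr$MI, tr$MD,
                             tr$IM, tr$II, tr$DM, tr$DD, FALSE)
    keep <- which(bits >= thr)
    if (length(keep) > 0) {
      ev <- if (!is.null(m$gumbel)) n * gumbel_upper(m$gumbel, bits[keep])
            else rep(NA_real_, length(keep))
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = pr$protein_id[keep],
        contig_id = if ("contig_id" %in% names(pr)) pr$contig_id[keep]
                    else NA_character_,
        family = m$family, model_id = m$model_id,
        bit_score = bits[keep], e_value = ev,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(list(hits = empty, profile = profile0))
  hits <- do.call(rbind, rows)
  ## one hit per protein-family pair: keep the best-scoring model
  ord <- order(hits$protein_id, hits$family, -hits$bit_score, hits$model_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("protein_id", "family")]), , drop = FALSE]
  rownames(hits) <- NULL
  fams <- sort(intersect(fam_all, unique(hits$family)))
  list(hits = hits,
       profile = list(sample_id = sample_id, families_present = fams,
                      n_families = length(fams)))
}
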