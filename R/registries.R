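#' Default steroid-degradation protein family registry
#'
#' The screen is keyed on a configurable set of protein families from the
#' aerobic 9,10-seco steroid degradation pathway. The two ring-opening
#' oxygenase families `KshA` (3-ketosteroid 9alpha-hydroxylase, oxygenase
#' component) and `HsaC` (catechol-ring meta-cleavage dioxygenase) are
#' mandatory members: they are the diagnostic key enzymes used by the
#' degrader classification rules. The remaining defaults are the canonical
#' A/B-ring and 2-hydroxyhexa-2,4-dienoate branch enzymes of the pathway;
#' the registry is a configuration surface, and alternative family sets can
#' be supplied everywhere a family list is accepted.
#'
#' @return Character vector of 10 family names, including `"KshA"` and
#'   `"HsaC"`.
#' @export
#' @examples
#' steroid_families()
steroid_families <- function() {
  c("KshA", "KshB", "KstD", "HsaA", "HsaB",
    "HsaC", "HsaD", "HsaE", "HsaF", "HsaG")
}

#' Key ring-opening enzyme families
#'
#' The two families whose presence is required (at least one of them) by the
#' predicted-degrader rule.
#'
#' @return Character vector `c("KshA", "HsaC")`.
#' @export
key_families <- function() c("KshA", "HsaC")

#' Universal single-copy marker gene registry
#'
#' Forty bacterial single-copy marker families (ribosomal proteins,
#' translation factors and other universally conserved housekeeping genes)
#' used for two estimators: genome equivalents of a sample (median marker
#' copy number) and completeness/contamination of a genome bin.
#'
#' @return Character vector of 40 marker family names.
#' @export
marker_families <- function() {
  c("rplA", "rplB", "rplC", "rplD", "rplE", "rplF", "rplK", "rplL",
    "rplM", "rplN", "rplP", "rplS", "rplT", "rpsB", "rpsC", "rpsE",
    "rpsG", "rpsH", "rpsI", "rpsJ", "rpsK", "rpsL", "rpsM", "rpsS",
    "rpoA", "rpoB", "gyrA", "gyrB", "recA", "infB", "infC", "pheS",
    "tsf", "pyrG", "secY", "nusA", "frr", "smpB", "ffh", "lepA")
}

#' Controlled vocabulary of global environment codes
#'
#' Metagenome samples are labelled with a three-letter environment code plus
#' a sample number (for example `WWT_7`, `DEO_2`). This vocabulary maps each
#' code to its global environment category.
#'
#' @return Named character vector: names are codes, values are descriptions.
#' @export
environment_codes <- function() {
  c(WWT = "aerobic wastewater treatment plant",
    SOI = "soil",
    DEO = "deep ocean",
    OPO = "marine oil seep / oil-polluted ocean",
    OMZ = "marine oxygen minimum zone",
    LEN = "lentic freshwater",
    THS = "thermal spring",
    DES = "deep subsurface",
    MSP = "marine sponge",
    RHI = "plant rhizosphere",
    TER = "termite gut")
}

## Amino-acid alphabet used throughout (20 canonical residues).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Fixed internal seed for the "known biology" layer: family and marker
## ancestor proteins and their seed alignments must be identical across
## sessions and independent of any user-supplied simulation seed.
.REGISTRY_SEED <- 104729L

## Cache for deterministically generated registry objects.
.registry_cache <- new.env(parent = emptyenv())

#' Ancestral protein sequences for the steroid family registry
#'
#' Deterministically generated reference proteins, one per family, used as
#' the common ancestor for seed alignments, planted genes and the synthetic
#' reference degrader panel. Always identical across sessions.
#'
#' @param families Character vector of family names.
#' @param length_aa Protein length in residues.
#' @return Named character vector of protein sequences (each starts with M).
#' @export
family_ancestors <- function(families = steroid_families(), length_aa = 150L) {
  key <- paste0("fam:", length_aa)
  if (is.null(.registry_cache[[key]])) {
    .registry_cache[[key]] <- with_seed(.REGISTRY_SEED, {
      all_fams <- steroid_families()
      anc <- vapply(seq_along(all_fams), function(i) {
        paste0("M", paste(sample(AA_ALPHABET, length_aa - 1L, replace = TRUE),
                          collapse = ""))
      }, character(1))
      names(anc) <- all_fams
      anc
    })
  }
  anc <- .registry_cache[[key]]
  extra <- setdiff(families, names(anc))
  if (length(extra) > 0) {
    ## non-default families get their own deterministic ancestors
    more <- vapply(extra, function(f) {
      with_seed(.REGISTRY_SEED + sum(utf8ToInt(f)), {
        paste0("M", paste(sample(AA_ALPHABET, length_aa - 1L, replace = TRUE),
                          collapse = ""))
      })
    }, character(1))
    anc <- c(anc, more)
  }
  anc[families]
}

#' Ancestral protein sequences for the single-copy marker registry
#'
#' @param length_aa Protein length in residues.
#' @return Named character vector of 40 marker protein sequences.
#' @export
marker_ancestors <- function(length_aa = 90L) {
  key <- paste0("mark:", length_aa)
  if (is.null(.registry_cache[[key]])) {
    .registry_cache[[key]] <- with_seed(.REGISTRY_SEED + 1L, {
      marks <- marker_families()
      anc <- vapply(seq_along(marks), function(i) {
        paste0("M", paste(sample(AA_ALPHABET, length_aa - 1L, replace = TRUE),
                          collapse = ""))
      }, character(1))
      names(anc) <- marks
      anc
    })
  }
  .registry_cache[[key]]
}

#' Seed alignments for a family set
#'
#' Builds, deterministically, one gapless seed alignment per family: the
#' ancestor plus `n_variants` diverged members. These play the role of the
#' curated seed alignments from which the profile HMMs are trained.
#'
#' @param families Character vector of family names.
#' @param n_variants Number of diverged members per alignment (besides the
#'   ancestor).
#' @param divergence Substitutions per site between ancestor and members.
#' @param marker Logical; use the marker registry ancestors instead of the
#'   steroid family ancestors.
#' @return Named list of character matrices is not used; returns a named
#'   list of character vectors (aligned sequences, equal lengths).
#' @export
family_seed_alignments <- function(families = steroid_families(),
                                   n_variants = 7L,
                                   divergence = 0.15,
                                   marker = FALSE) {
  anc <- if (marker) marker_ancestors()[families] else family_ancestors(families)
  out <- lapply(seq_along(families), function(i) {
    fam <- families[i]
    with_seed(.REGISTRY_SEED + 1000L + sum(utf8ToInt(fam)), {
      members <- vapply(seq_len(n_variants), function(j) {
        mutate_protein(anc[[i]], divergence,
                       seed = sample.int(.Machine$integer.max, 1))
      }, character(1))
      seqs <- c(anc[[i]], members)
      names(seqs) <- c(paste0(fam, "_ref"), paste0(fam, "_v", seq_len(n_variants)))
      seqs
    })
  })
  names(out) <- families
  out
}
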