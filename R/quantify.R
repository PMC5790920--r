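#' Estimate genome equivalents from single-copy marker hits
#'
#' The number of genome equivalents in a sample is estimated as the median
#' copy number over the detected universal single-copy marker families
#' (copies = distinct proteins hitting the marker's model). The median,
#' rather than the mean, keeps the estimate robust to marker genes split
#' across contig breaks. When no marker family is detected the estimate is
#' explicitly undefined (never zero) and the sample is excluded from
#' normalized comparisons downstream.
#'
#' @param marker_hits Hits data frame from [scan_sample()] run against the
#'   marker model set (columns `family`, `protein_id`).
#' @param sample_id Sample label.
#' @param markers Marker family registry.
#' @return Object of class `genome_equivalents`: `sample_id`,
#'   `genome_equivalents` (NA when undefined), `marker_counts`, `method`,
#'   `defined`.
#' @export
estimate_genome_equivalents <- function(marker_hits, sample_id = NA_character_,
                                        markers = marker_families()) {
  hits <- marker_hits[marker_hits$family %in% markers, , drop = FALSE]
  counts <- if (nrow(hits) > 0) {
    tapply(hits$protein_id, hits$family, function(p) length(unique(p)))
  } else {
    integer(0)
  }
  counts <- counts[!is.na(counts)]
  defined <- length(counts) > 0
  structure(list(sample_id = sample_id,
                 genome_equivalents = if (defined) {
                   as.numeric(stats::median(counts))
                 } else NA_real_,
                 marker_counts = counts,
                 method = "assembly-marker-median",
                 defined = defined),
            class = "genome_equivalents")
}

#' @export
print.genome_equivalents <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<genome_equivalents %s> %.3f (%d/%d marker families)\n",
                x$sample_id, x$genome_equivalents, length(x$marker_counts),
                length(marker_families())))
  } else {
    cat(sprintf("<genome_equivalents %s> undefined (no markers detected)\n",
                x$sample_id))
  }
  invisible(x)
}

#' Normalize HMM hit counts by genome equivalents
#'
#' Exact division, no rounding. Refuses samples whose genome-equivalent
#' estimate is undefined: such samples are not analyzed further.
#'
#' @param raw_hits Number of HMM hits in the sample.
#' @param ge A [estimate_genome_equivalents()] result or a positive number.
#' @return List with `sample_id`, `raw_hits`, `hits_per_genome_equivalent`.
#' @export
normalize_hits <- function(raw_hits, ge) {
  sample_id <- NA_character_
  if (inherits(ge, "genome_equivalents")) {
    sample_id <- ge$sample_id
    if (!ge$defined) {
      stop("sample ", sample_id,
           " excluded: genome equivalents undefined (no marker detected)")
    }
    ge <- ge$genome_equivalents
  }
  if (!is.finite(ge) || ge <= 0) stop("genome equivalents must be > 0")
  list(sample_id = sample_id, raw_hits = raw_hits,
       hits_per_genome_equivalent = raw_hits / ge)
}

#' All-families sample selection gate
#'
#' A sample passes when it has HMM hits for every family in the configured
#' registry (all 10 by default).
#'
#' @param profile Family presence profile from [scan_sample()].
#' @param families Family registry (nonempty).
#' @return `TRUE`/`FALSE`.
#' @export
gate_all_families <- function(profile, families = steroid_families()) {
  if (length(families) == 0) stop("family registry must be nonempty")
  all(families %in% profile$families_present)
}

#' Display filter for per-taxon hit summaries
#'
#' Keeps taxa assigned strictly more than `pct_min` percent of a sample's
#' HMM hits and to strictly more than `families_min` of the configured
#' protein families.
#'
#' @param rows Data frame with columns `pct_of_hits` and
#'   `n_families_for_taxon`.
#' @param pct_min Percentage threshold (default 10, strict).
#' @param families_min Family-count threshold (default 5, strict).
#' @return The filtered data frame.
#' @export
summary_display_filter <- function(rows, pct_min = 10, families_min = 5) {
  keep <- rows$pct_of_hits > pct_min & rows$n_families_for_taxon > families_min
  rows[keep, , drop = FALSE]
}
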