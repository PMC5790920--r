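#' Pipeline configuration
#'
#' Collects every gate threshold and tunable of the end-to-end analysis in
#' one serializable object. All defaults mirror the individual functions'
#' documented defaults.
#'
#' @param seed Integer seed used for model calibration and binning.
#' @param n50_min,contig_min Assembly selection gate ([select_metagenome()]).
#' @param bit_threshold Optional fixed reporting threshold; `NULL` uses
#'   per-model calibrated thresholds.
#' @param n_decoys Decoys per model for calibration.
#' @param min_protein_len Minimum ORF protein length.
#' @param families Family registry.
#' @param lca_window Top-hit score window for LCA assignment.
#' @param min_contig_len_binning Minimum contig length entering binning.
#' @param completeness_min,contamination_max MAG quality gate.
#' @param rbh_min_identity,rbh_min_coverage Reciprocal-best-hit thresholds.
#' @param min_families Predicted-degrader family-count threshold.
#' @param confirm_min_completeness Confirmed-degrader completeness
#'   threshold.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n50_min = 300, contig_min = 600,
                            bit_threshold = NULL, n_decoys = 1000,
                            min_protein_len = 60,
                            families = steroid_families(),
                            lca_window = 0.10,
                            min_contig_len_binning = 1000,
                            completeness_min = 25, contamination_max = 10,
                            rbh_min_identity = 30, rbh_min_coverage = 70,
                            min_families = 5L,
                            confirm_min_completeness = 6L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' Configurations round-trip through JSON so every run can embed its full
#' configuration in the output manifest.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$families <- as.character(x$families)
  cfg <- do.call(pipeline_config, x[setdiff(names(x), "bit_threshold")])
  cfg$bit_threshold <- x$bit_threshold
  cfg
}

#' Run the full screening pipeline on one or more samples
#'
#' Stages, in order: assembly QC gate; six-frame ORF calling; profile-HMM
#' screening against the steroid family and single-copy-marker model sets;
#' genome-equivalent estimation and hit normalization (samples without a
#' defined estimate are excluded); the all-families selection gate;
#' optional per-hit LCA taxonomy; TNF binning with marker-based quality
#' gating; per-bin family screening and predicted-degrader classification;
#' optional reciprocal-best-hit confirmation against a reference degrader
#' panel. Reruns with identical inputs and configuration give identical
#' results except for the manifest timestamp.
#'
#' @param samples A [contig_set()] or list of them.
#' @param config A [pipeline_config()].
#' @param family_models,marker_models Calibrated model lists; built from
#'   the registries when `NULL`.
#' @param ref_panel Optional reference degrader panel
#'   ([synthetic_reference_panel()] shape) for ortholog confirmation.
#' @param ref_db Optional labelled protein reference (list with `seqs`,
#'   `taxa`) for LCA taxonomy.
#' @param taxonomy A [taxonomy_tree()]; defaults to the bundled tree.
#' @return Manifest list: `config`, `samples` (per-sample stage results),
#'   `excluded` (data frame of sample, stage, reason), `mags` (per-bin
#'   profiles of the samples passing all gates), `timestamp`.
#' @export
run_pipeline <- function(samples, config = pipeline_config(),
                         family_models = NULL, marker_models = NULL,
                         ref_panel = NULL, ref_db = NULL,
                         taxonomy = load_taxonomy()) {
  if (inherits(samples, "contig_set")) samples <- list(samples)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(family_models)) {
    family_models <- build_family_models(config$families,
                                         n_decoys = config$n_decoys,
                                         seed = config$seed)
  }
  if (is.null(marker_models)) {
    marker_models <- build_family_models(marker_families(), marker = TRUE,
                                         n_decoys = config$n_decoys,
                                         seed = config$seed + 1L)
  }
  excluded <- data.frame(sample_id = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)
  drop <- function(sid, stage, reason) {
    excluded <<- rbind(excluded, data.frame(sample_id = sid, stage = stage,
                                            reason = reason,
                                            stringsAsFactors = FALSE))
  }
  results <- list()
  mags <- list()
  for (cs in samples) {
    sid <- cs$sample_id
    res <- list(sample_id = sid, environment_code = cs$environment_code)
    res$stats <- compute_assembly_stats(cs)
    gate <- select_metagenome(res$stats, config$n50_min, config$contig_min)
    if (!gate$pass) { drop(sid, "assembly_qc", gate$reason); next }

    proteins <- call_orfs(cs, min_protein_len = config$min_protein_len)
    res$n_proteins <- nrow(proteins)
    fam_scan <- scan_sample(proteins, family_models,
                            bit_threshold = config$bit_threshold,
                            sample_id = sid)
    mark_scan <- scan_sample(proteins, marker_models,
                             bit_threshold = config$bit_threshold,
                             sample_id = sid)
    res$family_hits <- fam_scan$hits
    res$family_profile <- fam_scan$profile

    ge <- estimate_genome_equivalents(mark_scan$hits, sample_id = sid)
    res$genome_equivalents <- ge
    if (!ge$defined) {
      drop(sid, "quantify", "genome equivalents undefined; not analyzed further")
      results[[sid]] <- res
      next
    }
    res$normalized <- normalize_hits(nrow(fam_scan$hits), ge)
    res$all_families <- gate_all_families(fam_scan$profile, config$families)
    if (!res$all_families) {
      drop(sid, "quantify",
           sprintf("HMM hits for %d/%d families only",
                   fam_scan$profile$n_families, length(config$families)))
      results[[sid]] <- res
      next
    }

    if (!is.null(ref_db)) {
      fh <- res$family_hits
      seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
      taxa <- vapply(fh$protein_id, function(p) {
        ts <- top_hit_window(seqs[[p]], ref_db, window = config$lca_window)
        lca <- assign_lca(ts, taxonomy)
        if (is.na(lca)) NA_character_
        else taxonomy$name_by_id[[as.character(lca)]]
      }, character(1))
      res$hit_taxonomy <- data.frame(protein_id = fh$protein_id,
                                     family = fh$family, taxon = unname(taxa),
                                     stringsAsFactors = FALSE)
      res$taxon_summary <- aggregate_sample_taxonomy(res$hit_taxonomy, sid)
    }

    bins <- bin_contigs(cs, seed = config$seed,
                        min_len = config$min_contig_len_binning)
    res$bins <- bins
    prot_bin <- bins$membership$bin_id[match(proteins$contig_id,
                                             bins$membership$contig_id)]
    quality <- lapply(split(proteins$protein_id, prot_bin), function(pids) {
      assess_bin(mark_scan$hits[mark_scan$hits$protein_id %in% pids, ,
                                drop = FALSE])
    })
    qdf <- do.call(rbind, lapply(names(quality), function(b) {
      data.frame(bin_id = b, completeness = quality[[b]]$completeness,
                 contamination = quality[[b]]$contamination,
                 stringsAsFactors = FALSE)
    }))
    res$bin_quality <- qdf
    kept <- gate_bins(qdf, config$completeness_min, config$contamination_max)
    res$kept_bins <- kept$bin_id

    for (b in kept$bin_id) {
      pids <- proteins$protein_id[!is.na(prot_bin) & prot_bin == b]
      fams <- unique(res$family_hits$family[
        res$family_hits$protein_id %in% pids])
      mag_id <- sprintf("%s.%s", sid, sub("^bin_", "", b))
      prof <- mag_profile(mag_id, fams, families = config$families)
      if (prof$predicted_degrader && !is.null(ref_panel)) {
        mp <- stats::setNames(proteins$sequence, proteins$protein_id)[pids]
        calls <- panel_ortholog_calls(
          mp, ref_panel,
          min_identity = config$rbh_min_identity,
          min_coverage = config$rbh_min_coverage)
        prof <- mag_profile(mag_id, fams, ortholog_calls = calls,
                            families = config$families)
      }
      prof$sample_id <- sid
      prof$bin_id <- b
      mags[[mag_id]] <- prof
    }
    results[[sid]] <- res
  }
  list(config = config, samples = results, excluded = excluded,
       mags = mags, timestamp = format(Sys.time(), tz = "UTC"))
}
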