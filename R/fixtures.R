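.parse_count <- function(x, column, rows) {
  v <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  bad <- which(is.na(v) & !(is.na(x) | x == ""))
  if (length(bad) > 0) {
    stop(sprintf("malformed %s in row %d: '%s'", column, rows[bad][1],
                 x[bad][1]))
  }
  v
}

#' Load the bundled MAG catalogue
#'
#' Reads the bundled catalogue of 49 predicted steroid-degrader MAGs
#' recovered from 33 public metagenomes across 11 global environments:
#' per MAG, the lowest-common-ancestor label, completeness, contamination,
#' assembly characteristics, pathway completeness (out of 10 families) and
#' the recorded steroid-degrader confirmation flag. Numeric columns are
#' parsed with locale-safe thousands-comma handling ("7,116,951" becomes
#' 7116951); empty optional fields become `NA`, never zero.
#'
#' @param path TSV path; defaults to the bundled fixture.
#' @return Data frame with an extra `metagenome_id` column (the MAG id up
#'   to its final dot).
#' @export
load_table1 <- function(path = system.file("extdata", "table1_mags.tsv",
                                           package = "secoscreen")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("global_environment", "mag_id", "lca_label", "completeness",
            "contamination", "total_length", "n_contigs", "n50",
            "n_proteins", "pathway_completeness", "steroid_degrader")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  rows <- seq_len(nrow(df))
  for (col in c("completeness", "contamination", "total_length",
                "n_contigs", "n50", "n_proteins", "pathway_completeness")) {
    df[[col]] <- .parse_count(df[[col]], col, rows)
  }
  bad_flag <- which(!df$steroid_degrader %in% c("Yes", "No"))
  if (length(bad_flag) > 0) {
    stop("malformed steroid_degrader flag in row ", bad_flag[1])
  }
  bad_id <- which(!grepl(".", df$mag_id, fixed = TRUE))
  if (length(bad_id) > 0) stop("malformed mag_id in row ", bad_id[1])
  if (any(df$pathway_completeness > 10, na.rm = TRUE)) {
    stop("pathway_completeness above 10")
  }
  df$metagenome_id <- sub("\\.[^.]*$", "", df$mag_id)
  df
}

#' Load the bundled sponge isolate panel
#'
#' Cholesterol-degrading bacterial isolates obtained from marine sponges,
#' with 16S rRNA best-hit identities and lineage strings.
#'
#' @param path TSV path; defaults to the bundled fixture.
#' @return Data frame of isolate records.
#' @export
load_table2 <- function(path = system.file("extdata",
                                           "table2_sponge_isolates.tsv",
                                           package = "secoscreen")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$silva_best_hit <- .parse_count(df$silva_best_hit, "silva_best_hit",
                                    seq_len(nrow(df)))
  if (any(df$silva_best_hit < 0 | df$silva_best_hit > 100, na.rm = TRUE)) {
    stop("silva_best_hit outside [0, 100]")
  }
  df
}

#' Summarize the MAG catalogue by report bucket
#'
#' Rolls every MAG's lowest-common-ancestor label up to its report bucket
#' (phylum for Actinobacteria, class for resolved Proteobacteria, the
#' unresolved-Proteobacteria and unclassified-Bacteria buckets otherwise),
#' and tallies distinct source metagenomes and confirmation flags.
#'
#' @param records Data frame from [load_table1()] (possibly filtered).
#' @param tree A [taxonomy_tree()]; defaults to the bundled tree.
#' @return List with `n_records`, `buckets` (named integer vector over all
#'   report buckets), `n_metagenomes`, `flags` (Yes/No counts).
#' @export
table1_summary <- function(records, tree = load_taxonomy()) {
  buckets_all <- c("Actinobacteria", "Alphaproteobacteria",
                   "Betaproteobacteria", "Gammaproteobacteria",
                   "Proteobacteria", "other phylum",
                   "unclassified-Bacteria", "unassigned")
  if (nrow(records) == 0) {
    return(list(n_records = 0L,
                buckets = stats::setNames(integer(length(buckets_all)),
                                          buckets_all),
                n_metagenomes = 0L,
                flags = c(Yes = 0L, No = 0L)))
  }
  b <- vapply(records$lca_label, rollup_report_rank, character(1),
              tree = tree)
  buckets <- vapply(buckets_all, function(x) sum(b == x), integer(1))
  flags <- c(Yes = sum(records$steroid_degrader == "Yes"),
             No = sum(records$steroid_degrader == "No"))
  list(n_records = nrow(records),
       buckets = buckets,
       n_metagenomes = length(unique(records$metagenome_id)),
       flags = flags)
}
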