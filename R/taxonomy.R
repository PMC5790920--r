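.RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Load a rank-aware taxonomy tree
#'
#' Reads a TSV of nodes (`taxon_id`, `parent_id`, `rank`, `name`) with
#' rank-prefixed names (`d__`, `p__`, `c__`, `o__`, `f__`, `g__`). The tree
#' must have a single root and every non-root node must name an existing
#' parent of equal or shallower rank. The bundled default is a curated
#' tree covering the taxa referenced by the MAG catalogue and the
#' synthetic-community lineages.
#'
#' @param path TSV path; defaults to the bundled tree.
#' @return Object of class `taxonomy_tree`.
#' @export
load_taxonomy <- function(path = system.file("extdata", "taxonomy.tsv",
                                             package = "secoscreen")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer",
                                         "character", "character"))
  taxonomy_tree(df)
}

#' Construct a taxonomy tree from a node table
#'
#' @param nodes Data frame with `taxon_id`, `parent_id` (NA for the root),
#'   `rank`, `name`.
#' @return Object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("taxon_id", "parent_id", "rank", "name") %in% names(nodes)))
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1) stop("taxonomy must have exactly one root")
  if (!all(nodes$rank %in% .RANKS)) {
    stop("unknown rank: ", setdiff(nodes$rank, .RANKS)[1])
  }
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate taxon_id")
  if (anyDuplicated(nodes$name)) stop("duplicate taxon name")
  miss <- setdiff(nodes$parent_id[!is.na(nodes$parent_id)], nodes$taxon_id)
  if (length(miss) > 0) stop("parent not in tree: ", miss[1])
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  rank_num <- match(nodes$rank, .RANKS)
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent_id[i]
    if (!is.na(p) && rank_num[match(p, nodes$taxon_id)] >= rank_num[i]) {
      stop("rank of ", nodes$name[i], " not deeper than its parent")
    }
  }
  structure(list(nodes = nodes,
                 parent = parent,
                 id_by_name = stats::setNames(nodes$taxon_id, nodes$name),
                 name_by_id = stats::setNames(nodes$name,
                                              as.character(nodes$taxon_id)),
                 rank_by_id = stats::setNames(nodes$rank,
                                              as.character(nodes$taxon_id)),
                 root = nodes$taxon_id[roots]),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, root %s\n",
              nrow(x$nodes), x$name_by_id[as.character(x$root)]))
  invisible(x)
}

#' Resolve a rank-prefixed label to a tree node
#'
#' @param tree A [taxonomy_tree()].
#' @param label Label such as `"g__Rhodococcus"`.
#' @return The node's taxon_id.
#' @export
resolve_label <- function(tree, label) {
  id <- tree$id_by_name[label]
  if (anyNA(id)) {
    stop("unresolvable taxonomy label(s): ",
         paste(label[is.na(id)], collapse = ", "))
  }
  unname(id)
}

## Path of taxon_ids from a node up to the root (self first).
taxon_ancestors <- function(tree, id) {
  path <- id
  while (!is.na(tree$parent[as.character(id)])) {
    id <- tree$parent[[as.character(id)]]
    path <- c(path, id)
  }
  path
}

#' Lowest common ancestor of a taxon set
#'
#' Returns the deepest node ancestral to (or equal to) every input taxon.
#' An empty set yields the unassigned sentinel `NA`.
#'
#' @param taxa Character vector of labels or integer vector of taxon_ids.
#' @param tree A [taxonomy_tree()].
#' @return A taxon_id, or `NA` for an empty input set.
#' @export
assign_lca <- function(taxa, tree) {
  if (length(taxa) == 0) return(NA_integer_)
  ids <- if (is.character(taxa)) resolve_label(tree, taxa) else as.integer(taxa)
  if (!all(ids %in% tree$nodes$taxon_id)) stop("taxon not in tree")
  ids <- unique(ids)
  path <- taxon_ancestors(tree, ids[1])
  for (id in ids[-1]) {
    path <- path[path %in% taxon_ancestors(tree, id)]
  }
  path[1]
}

#' Roll a lineage label up to its report bucket
#'
#' Report convention: Proteobacteria are reported at class level when the
#' lineage reaches class rank or below (Alpha-, Beta-, Gammaproteobacteria),
#' otherwise as the phylum; Actinobacteria are reported at the phylum;
#' labels resolved only to the bacterial domain become
#' `"unclassified-Bacteria"`; any other phylum becomes `"other phylum"`;
#' the unassigned sentinel (`NA`) maps to `"unassigned"`.
#'
#' @param label A rank-prefixed label, a taxon_id, or `NA`.
#' @param tree A [taxonomy_tree()].
#' @return One of `"Actinobacteria"`, `"Alphaproteobacteria"`,
#'   `"Betaproteobacteria"`, `"Gammaproteobacteria"`, `"Proteobacteria"`,
#'   `"other phylum"`, `"unclassified-Bacteria"`, `"unassigned"`.
#' @export
rollup_report_rank <- function(label, tree) {
  if (length(label) != 1) {
    return(vapply(label, rollup_report_rank, character(1), tree = tree))
  }
  if (is.na(label)) return("unassigned")
  id <- if (is.character(label)) resolve_label(tree, label) else as.integer(label)
  path <- taxon_ancestors(tree, id)
  ranks <- tree$rank_by_id[as.character(path)]
  names_ <- tree$name_by_id[as.character(path)]
  phylum <- names_[ranks == "phylum"]
  cls <- names_[ranks == "class"]
  phylum <- unname(phylum); cls <- unname(cls)
  if (length(phylum) == 0) return("unclassified-Bacteria")
  if (phylum == "p__Actinobacteria") return("Actinobacteria")
  if (phylum == "p__Proteobacteria") {
    if (length(cls) == 1 &&
        cls %in% c("c__Alphaproteobacteria", "c__Betaproteobacteria",
                   "c__Gammaproteobacteria")) {
      return(sub("^c__", "", cls))
    }
    return("Proteobacteria")
  }
  "other phylum"
}

#' Top-hit-window reference taxa for a query protein
#'
#' Aligns the query locally against all labelled reference proteins and
#' returns the taxa of references scoring within `window` of the best
#' score (score >= (1 - window) * best). With `window = 0` only exact
#' best-score ties are returned. When no reference scores above
#' `score_floor`, the query stays unassigned (empty set).
#'
#' @param query_protein Protein sequence.
#' @param ref_db List with `seqs` (named protein vector) and `taxa`
#'   (named character vector of labels, same names).
#' @param window Relative score window (default 0.10).
#' @param score_floor Minimum best score to assign at all.
#' @param sm A [scoring_matrix()].
#' @return Character vector of unique taxon labels (possibly empty).
#' @export
top_hit_window <- function(query_protein, ref_db, window = 0.10,
                           score_floor = 0, sm = scoring_matrix()) {
  stopifnot(length(ref_db$seqs) > 0, !is.null(ref_db$taxa))
  scores <- sw_scores(query_protein, ref_db$seqs, sm)
  best <- max(scores)
  if (best <= score_floor) return(character(0))
  keep <- scores >= (1 - window) * best
  unique(unname(ref_db$taxa[names(ref_db$seqs)[keep]]))
}

#' Per-sample taxon summary of assigned hits
#'
#' Aggregates per-hit LCA assignments into one row per taxon with the
#' percentage of the sample's hits (over assigned plus unassigned, so
#' percentages are conservative and sum to 100) and the number of distinct
#' protein families assigned to the taxon. Unassigned hits appear as the
#' `"unassigned"` row.
#'
#' @param hit_taxonomies Data frame with columns `protein_id`, `family`,
#'   `taxon` (label or `NA` for unassigned).
#' @param sample_id Sample label.
#' @return Data frame: `sample_id`, `taxon`, `pct_of_hits`,
#'   `n_families_for_taxon`.
#' @export
aggregate_sample_taxonomy <- function(hit_taxonomies,
                                      sample_id = NA_character_) {
  ht <- hit_taxonomies
  if (nrow(ht) == 0) {
    return(data.frame(sample_id = character(), taxon = character(),
                      pct_of_hits = numeric(),
                      n_families_for_taxon = integer(),
                      stringsAsFactors = FALSE))
  }
  taxon <- ifelse(is.na(ht$taxon), "unassigned", ht$taxon)
  total <- nrow(ht)
  agg <- lapply(split(seq_len(total), taxon), function(ix) {
    data.frame(pct_of_hits = 100 * length(ix) / total,
               n_families_for_taxon = length(unique(ht$family[ix])))
  })
  out <- do.call(rbind, agg)
  out <- cbind(sample_id = sample_id, taxon = names(agg), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$pct_of_hits, out$taxon), , drop = FALSE]
}

#' Export taxon paths and counts in a KRONA-compatible text layout
#'
#' One row per hit taxon: count followed by the tab-separated lineage path
#' from the root, suitable for external interactive chart rendering.
#'
#' @param hit_taxonomies As in [aggregate_sample_taxonomy()].
#' @param tree A [taxonomy_tree()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_krona_text <- function(hit_taxonomies, tree, path) {
  taxon <- ifelse(is.na(hit_taxonomies$taxon), "unassigned",
                  hit_taxonomies$taxon)
  counts <- table(taxon)
  lines <- vapply(names(counts), function(lbl) {
    lineage <- if (lbl == "unassigned") "unassigned" else {
      ids <- rev(taxon_ancestors(tree, resolve_label(tree, lbl)))
      paste(tree$name_by_id[as.character(ids)], collapse = "\t")
    }
    paste(counts[[lbl]], lineage, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
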