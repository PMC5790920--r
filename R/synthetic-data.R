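#' Simulation configuration for synthetic communities
#'
#' Bundles every knob of the synthetic-community generator: community
#' composition, genome size, contig fragmentation, and the sequence
#' divergence of planted pathway genes. The defaults describe a small,
#' compositionally contrasted community: a few degrader genomes carrying
#' one copy of every configured steroid family gene, a background of
#' genomes carrying none, per-genome GC drawn from \[0.35, 0.65\] so
#' tetranucleotide binning has signal, and log-normally fragmented contigs.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_degraders Number of genomes carrying all configured families.
#' @param n_background Number of genomes carrying none of them.
#' @param genome_length Genome length in bp.
#' @param families Family registry to plant; must include both key families.
#' @param fragment_length_mean,fragment_length_sd Contig length distribution
#'   (natural-scale mean and sd of a log-normal; sd 0 gives fixed lengths).
#' @param divergence Substitutions per site applied to planted family
#'   proteins, in \[0, 1).
#' @param abundances Per-genome relative weights (degraders first); `NULL`
#'   means equal. Nonnegative, not all zero.
#' @param depth Number of independent genome tilings emitted when
#'   fragmenting (default 1; values above 1 duplicate loci).
#' @param gc_range Range from which per-genome GC content is drawn.
#' @param gc_values Optional explicit per-genome GC contents (overrides
#'   `gc_range`); used to construct controlled compositional contrasts.
#' @param reverse_strand_genes If `TRUE`, each planted gene is placed on a
#'   randomly chosen strand; otherwise all genes are on the forward strand.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_degraders = 1L,
                       n_background = 2L,
                       genome_length = 40000L,
                       families = steroid_families(),
                       fragment_length_mean = 5000,
                       fragment_length_sd = 1500,
                       divergence = 0,
                       abundances = NULL,
                       depth = 1,
                       gc_range = c(0.35, 0.65),
                       gc_values = NULL,
                       reverse_strand_genes = FALSE) {
  if (n_degraders < 0 || n_background < 0) {
    stop("genome counts must be nonnegative")
  }
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1) {
    stop("divergence must be in [0, 1)")
  }
  n <- n_degraders + n_background
  if (!is.null(abundances)) {
    if (length(abundances) != n) stop("abundances must have one weight per genome")
    if (any(abundances < 0) || all(abundances == 0)) {
      stop("abundances must be nonnegative and not all zero")
    }
  }
  if (fragment_length_mean < 1) stop("fragment_length_mean must be >= 1")
  if (!is.null(gc_values) && length(gc_values) != n) {
    stop("gc_values must have one value per genome")
  }
  if (n_degraders + n_background > 0 &&
      !all(key_families() %in% families)) {
    stop("families must include ", paste(key_families(), collapse = " and "))
  }
  structure(list(seed = as.integer(seed),
                 n_degraders = as.integer(n_degraders),
                 n_background = as.integer(n_background),
                 genome_length = as.integer(genome_length),
                 families = families,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 divergence = divergence,
                 abundances = abundances,
                 depth = depth,
                 gc_range = gc_range,
                 gc_values = gc_values,
                 reverse_strand_genes = isTRUE(reverse_strand_genes)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic community configuration\n")
  cat(sprintf("  %d degrader + %d background genomes of %d bp (seed %d)\n",
              x$n_degraders, x$n_background, x$genome_length, x$seed))
  cat(sprintf("  %d families planted at divergence %.2f\n",
              length(x$families), x$divergence))
  cat(sprintf("  fragments ~ lognormal(mean %.0f, sd %.0f), depth %.1f\n",
              x$fragment_length_mean, x$fragment_length_sd, x$depth))
  invisible(x)
}

#' Mutate a protein sequence at a given divergence
#'
#' Substitutes each position independently with probability `divergence`,
#' replacing the residue with a uniformly chosen different residue, so the
#' expected fraction of changed positions equals `divergence`. Length is
#' preserved; no indels are introduced.
#'
#' @param protein Protein sequence (single string).
#' @param divergence Substitution probability per site, in \[0, 1).
#' @param seed Integer seed.
#' @return Mutated protein sequence of the same length.
#' @export
mutate_protein <- function(protein, divergence, seed) {
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (divergence == 0) return(protein)
  with_seed(seed, {
    res <- strsplit(protein, "", fixed = TRUE)[[1]]
    hit <- runif(length(res)) < divergence
    if (any(hit)) {
      res[hit] <- vapply(res[hit], function(a) {
        sample(setdiff(AA_ALPHABET, a), 1)
      }, character(1), USE.NAMES = FALSE)
    }
    paste(res, collapse = "")
  })
}

## Genus pools used to label synthetic genomes; all resolvable in the
## bundled taxonomy tree.
.DEGRADER_GENERA <- c("g__Rhodococcus", "g__Mycobacterium", "g__Comamonas",
                      "g__Pseudomonas", "g__Novosphingobium")
.BACKGROUND_GENERA <- c("g__Colwellia", "g__Thauera", "g__Gordonia",
                        "g__Sphingomonas", "g__Nocardioides")

## Divergence applied to the single-copy markers planted in every genome;
## small enough that marker detection is essentially certain, large enough
## that marker loci differ between genomes.
.MARKER_DIVERGENCE <- 0.05

#' Generate a synthetic reference genome panel with ground truth
#'
#' Builds `n_degraders` genomes carrying exactly one planted gene per
#' configured steroid family plus `n_background` genomes carrying none.
#' Every genome additionally carries each of the 40 universal single-copy
#' marker genes exactly once, so marker-based genome-equivalent and
#' completeness estimators are exact on the truth. Genes are embedded in
#' frame (ATG start, TAA stop) with synonymous codons biased toward the
#' genome's GC content; intervals never overlap.
#'
#' @param config A [sim_config()].
#' @return List with elements `genomes` (list of `reference_genome`
#'   objects: `genome_id`, `lineage`, `sequence`, `planted_genes`
#'   data frame) and `truth` (list of data frames `genomes` and `genes`).
#' @export
generate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_degraders + config$n_background
  empty_truth <- list(
    genomes = data.frame(genome_id = character(), degrader = logical(),
                         lineage = character(), gc = numeric(),
                         stringsAsFactors = FALSE),
    genes = data.frame(genome_id = character(), family = character(),
                       type = character(), start = integer(), end = integer(),
                       strand = character(), protein = character(),
                       stringsAsFactors = FALSE))
  if (n == 0) return(list(genomes = list(), truth = empty_truth))

  fam_anc <- family_ancestors(config$families)
  mark_anc <- marker_ancestors()

  with_seed(config$seed, {
    genomes <- vector("list", n)
    gtab <- empty_truth$genomes
    gene_rows <- list()
    for (i in seq_len(n)) {
      degrader <- i <= config$n_degraders
      gid <- sprintf("%s%02d", if (degrader) "deg" else "bg", i)
      gc <- if (!is.null(config$gc_values)) config$gc_values[i] else
        runif(1, config$gc_range[1], config$gc_range[2])
      lineage <- if (degrader) {
        .DEGRADER_GENERA[(i - 1) %% length(.DEGRADER_GENERA) + 1]
      } else {
        .BACKGROUND_GENERA[(i - 1) %% length(.BACKGROUND_GENERA) + 1]
      }

      ## proteins to plant: per-genome diverged markers, plus (for
      ## degraders) one diverged copy of every configured family protein
      ## mutated copies keep their initiator methionine so the embedded
      ## gene (ATG + body + TAA) translates exactly to the recorded protein
      mutate_cds <- function(p, d) {
        out <- mutate_protein(p, d, sample.int(.Machine$integer.max, 1))
        paste0("M", substring(out, 2))
      }
      plant <- data.frame(family = names(mark_anc), type = "marker",
                          protein = vapply(mark_anc, mutate_cds,
                                           character(1),
                                           d = .MARKER_DIVERGENCE),
                          stringsAsFactors = FALSE)
      if (degrader) {
        fam <- data.frame(family = names(fam_anc), type = "family",
                          protein = vapply(fam_anc, mutate_cds,
                                           character(1),
                                           d = config$divergence),
                          stringsAsFactors = FALSE)
        plant <- rbind(plant, fam)
      }
      plant <- plant[sample.int(nrow(plant)), , drop = FALSE]

      ## in-frame genes: ATG + codons for residues 2..n + TAA
      gene_dna <- vapply(plant$protein, function(p) {
        body <- reverse_translate(substring(p, 2), gc = gc)
        paste0("ATG", body, "TAA")
      }, character(1), USE.NAMES = FALSE)
      gene_len <- nchar(gene_dna)
      spacer_budget <- config$genome_length - sum(gene_len)
      n_sp <- nrow(plant) + 1L
      if (spacer_budget < n_sp) {
        stop("genome_length too small for the planted genes")
      }
      sp_len <- as.vector(stats::rmultinom(1, spacer_budget - n_sp,
                                           rep(1, n_sp))) + 1L

      pieces <- character(2L * nrow(plant) + 1L)
      pos <- 0L
      starts <- ends <- integer(nrow(plant))
      strands <- character(nrow(plant))
      for (j in seq_len(nrow(plant))) {
        sp <- random_dna(sp_len[j], gc)
        pieces[2L * j - 1L] <- sp
        pos <- pos + sp_len[j]
        strand <- "+"
        dna <- gene_dna[j]
        if (config$reverse_strand_genes && runif(1) < 0.5) {
          strand <- "-"
          dna <- revcomp(dna)
        }
        pieces[2L * j] <- dna
        starts[j] <- pos + 1L
        ends[j] <- pos + gene_len[j]
        strands[j] <- strand
        pos <- pos + gene_len[j]
      }
      pieces[2L * nrow(plant) + 1L] <- random_dna(sp_len[n_sp], gc)
      sequence <- paste(pieces, collapse = "")

      genomes[[i]] <- structure(
        list(genome_id = gid, lineage = lineage, gc = gc,
             sequence = sequence,
             planted_genes = data.frame(
               family = plant$family, type = plant$type,
               start = starts, end = ends, strand = strands,
               protein = plant$protein, stringsAsFactors = FALSE)),
        class = "reference_genome")
      gtab <- rbind(gtab, data.frame(genome_id = gid, degrader = degrader,
                                     lineage = lineage, gc = gc,
                                     stringsAsFactors = FALSE))
      gene_rows[[i]] <- cbind(genome_id = gid, genomes[[i]]$planted_genes)
    }
    list(genomes = genomes,
         truth = list(genomes = gtab, genes = do.call(rbind, gene_rows)))
  })
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome %s> %s, %d bp, GC %.2f, %d planted genes\n",
              x$genome_id, x$lineage, nchar(x$sequence), x$gc,
              nrow(x$planted_genes)))
  invisible(x)
}

#' Fragment a genome panel into a synthetic contig set
#'
#' Emulates assembled contigs: each genome with positive abundance is cut
#' into a contiguous tiling of forward-strand fragments whose lengths
#' follow a log-normal (degenerate when sd = 0; the final fragment is
#' truncated at the genome end), so every locus appears at most once per
#' tiling, as in an assembly. Abundance acts as a retention probability:
#' a fragment from genome i is kept with probability
#' `abundance_i / max(abundance)`, making the expected per-genome contig
#' mass proportional to abundance; zero-abundance genomes contribute
#' nothing. `depth` repeats the whole tiling that many times (independent
#' breakpoints); values above 1 duplicate loci and correspondingly inflate
#' single-copy-marker copy counts. Fragments are shuffled before ids are
#' assigned, so contig ids carry no information about the genome of
#' origin.
#'
#' @param panel Result of [generate_reference_panel()].
#' @param config The same [sim_config()].
#' @param sample_id,environment_code Labels for the resulting contig set.
#' @return List with `contigs` (a [contig_set()]) and `truth` (data frame
#'   mapping contig_id to genome_id, start, end).
#' @export
fragment_community <- function(panel, config,
                               sample_id = "SIM_1",
                               environment_code = "SIM_1") {
  stopifnot(inherits(config, "sim_config"))
  if (length(panel$genomes) == 0) stop("panel is empty")
  if (config$fragment_length_mean < 1) stop("fragment mean must be >= 1")
  w <- config$abundances %||% rep(1, length(panel$genomes))
  glen <- vapply(panel$genomes, function(g) nchar(g$sequence), integer(1))
  keep_p <- w / max(w)

  m <- config$fragment_length_mean
  s <- config$fragment_length_sd
  draw_len <- if (s <= 0) {
    function() m
  } else {
    sigma2 <- log(1 + (s / m)^2)
    mu <- log(m) - sigma2 / 2
    function() stats::rlnorm(1, mu, sqrt(sigma2))
  }

  with_seed(config$seed + 1L, {
    seqs <- character(0)
    map <- list()
    i <- 0L
    for (rep_k in seq_len(max(1L, round(config$depth)))) {
      for (gi in seq_along(panel$genomes)) {
        if (keep_p[gi] == 0) next
        g <- panel$genomes[[gi]]
        pos <- 1L
        while (pos <= glen[gi]) {
          len <- max(1L, round(draw_len()))
          end <- min(glen[gi], pos + len - 1L)
          if (stats::runif(1) < keep_p[gi]) {
            i <- i + 1L
            seqs[i] <- substring(g$sequence, pos, end)
            map[[i]] <- data.frame(genome_id = g$genome_id,
                                   start = pos, end = end,
                                   stringsAsFactors = FALSE)
          }
          pos <- end + 1L
        }
      }
    }
    if (i == 0L) {
      return(list(contigs = contig_set(sample_id, environment_code),
                  truth = data.frame(contig_id = character(),
                                     genome_id = character(),
                                     start = integer(), end = integer(),
                                     stringsAsFactors = FALSE)))
    }
    ord <- sample.int(i)
    seqs <- seqs[ord]
    map <- map[ord]
    ids <- sprintf("%s_c%05d", sample_id, seq_len(i))
    truth <- cbind(contig_id = ids, do.call(rbind, map))
    cs <- contig_set(sample_id = sample_id,
                     environment_code = environment_code,
                     sequences = stats::setNames(seqs, ids))
    list(contigs = cs, truth = truth)
  })
}

#' Write a genome panel to FASTA
#'
#' @param panel Result of [generate_reference_panel()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  seqs <- vapply(panel$genomes, function(g) g$sequence, character(1))
  names(seqs) <- vapply(panel$genomes, function(g) g$genome_id, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}
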