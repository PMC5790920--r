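#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Random protein of given length over the 20-letter alphabet (uniform).
## Caller is responsible for seeding.
random_protein <- function(length_aa, start_met = FALSE) {
  s <- sample(AA_ALPHABET, length_aa, replace = TRUE)
  if (start_met && length_aa >= 1) s[1] <- "M"
  paste(s, collapse = "")
}

## Random DNA of given length and GC content. Caller seeds.
random_dna <- function(length_bp, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length_bp, replace = TRUE, prob = p), collapse = "")
}

## Codon table partitioned by residue, for reverse translation.
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

## Reverse-translate a protein to DNA without a stop codon, choosing
## synonymous codons with probabilities biased toward the target GC
## content. Caller seeds.
reverse_translate <- function(protein, gc = 0.5) {
  tab <- .codons_by_aa()
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue: ", a)
    w <- vapply(opts, function(cd) {
      prod(base_p[strsplit(cd, "", fixed = TRUE)[[1]]])
    }, numeric(1))
    sample(opts, 1, prob = w)
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

## Translate a DNA string (length divisible by 3) with the standard code.
## Returns residues including "*" for stops.
translate_dna <- function(dna) {
  n <- nchar(dna)
  if (n < 3) return("")
  n <- n - n %% 3
  codons <- substring(dna, seq(1, n, by = 3), seq(3, n, by = 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

## Reverse complement of a DNA string.
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
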