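#' @importFrom stats rbinom runif rnorm var sd qgamma pchisq ppois
#'   t.test uniroot coef resid fitted quantile setNames
#' @importFrom utils read.delim write.table head
NULL

#' Reference gene
#'
#' Construct the reference (wild-type) coding sequence against which clone
#' sequences are compared. Coordinates throughout the package are 1-based and
#' relative to the first nucleotide of this sequence.
#'
#' @param sequence Character scalar over the strict alphabet `A`, `C`, `G`,
#'   `T` (lower case is accepted and uppercased). Ambiguity codes are
#'   rejected so that downstream mutation counts stay exact.
#' @param name Identifier for the gene.
#'
#' @return An object of class `reference_gene` with fields `name`,
#'   `sequence` and `length` (nt).
#' @export
#' @examples
#' ref <- reference_gene("ATGACGTGA", name = "toy")
#' ref$length
reference_gene <- function(sequence, name = "reference") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("reference sequence must have positive length", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !chars %in% DNA_BASES
  if (any(bad)) {
    stop(
      sprintf(
        "reference contains %d non-ACGT character(s), first at position %d ('%s')",
        sum(bad), which(bad)[1L], chars[which(bad)[1L]]
      ),
      call. = FALSE
    )
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "reference_gene"
  )
}

#' @export
print.reference_gene <- function(x, ...) {
  cat(sprintf(
    "<reference_gene> %s: %d nt (%s...)\n",
    x$name, x$length, substr(x$sequence, 1, min(24L, x$length))
  ))
  comp <- base_composition(x$sequence)
  cat("  composition:", paste(sprintf("%s=%.3f", names(comp), comp), collapse = " "), "\n")
  invisible(x)
}

#' Seeded random CDS-like reference sequence
#'
#' Generates a random coding-sequence-like reference: starts with ATG, ends
#' with a stop codon, and contains no internal in-frame stop codons. Used as
#' a synthetic stand-in where the experimental target gene is not available.
#'
#' @param length Sequence length in nt; must be a positive multiple of 3.
#'   Default 783, the length of the human deoxycytidine kinase coding
#'   sequence used as the default target size throughout the package.
#' @param seed Integer seed (mandatory; all stochastic entry points in this
#'   package require an explicit seed).
#' @param name Identifier.
#'
#' @return A [reference_gene()].
#' @export
random_reference <- function(length = 783L, seed, name = "synthetic_cds") {
  if (missing(seed)) stop("random_reference() requires an explicit seed", call. = FALSE)
  stopifnot(length > 0L, length %% 3L == 0L)
  stops <- c("TAA", "TAG", "TGA")
  withr::with_seed(as.integer(seed), {
    n_codons <- length %/% 3L
    codons <- character(n_codons)
    codons[1L] <- "ATG"
    if (n_codons > 2L) {
      all_codons <- apply(
        expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE),
        1L, paste0, collapse = ""
      )
      sense <- setdiff(all_codons, stops)
      codons[2:(n_codons - 1L)] <- sample(sense, n_codons - 2L, replace = TRUE)
    }
    codons[n_codons] <- sample(stops, 1L)
    reference_gene(paste(codons, collapse = ""), name = name)
  })
}

#' Base composition of a sequence
#'
#' @param sequence Character scalar over A/C/G/T.
#' @return Named numeric vector of length 4 summing to 1.
#' @export
base_composition <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = DNA_BASES))
  as.numeric(counts) / length(chars) -> p
  names(p) <- DNA_BASES
  p
}

# internal: sequence string <-> integer codes 1..4
seq_to_int <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1L]], DNA_BASES)
}

int_to_seq <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}
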