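#' Call substitutions in a clone against the reference
#'
#' Position-by-position comparison of a clone sequence with the reference
#' (substitution-only model: clones are fixed-length amplicons of the CDS, so
#' no alignment is performed and indels are unsupported). Coordinates are
#' 1-based and CDS-relative.
#'
#' @param clone Clone sequence string, same length as the reference.
#' @param reference A [reference_gene()].
#' @return Data frame of mutation events with columns `position`,
#'   `ref_base`, `alt_base`, sorted by ascending position; zero rows when the
#'   clone equals the reference.
#' @export
#' @examples
#' ref <- reference_gene("ACGTACGT")
#' call_mutations("ACGTACAT", ref)
call_mutations <- function(clone, reference) {
  stopifnot(inherits(reference, "reference_gene"), is.character(clone), length(clone) == 1L)
  clone <- toupper(clone)
  if (nchar(clone) != reference$length) {
    stop(sprintf(
      "clone length (%d) differs from reference length (%d): indels are unsupported in the substitution-only model",
      nchar(clone), reference$length
    ), call. = FALSE)
  }
  cchars <- strsplit(clone, "", fixed = TRUE)[[1L]]
  bad <- !cchars %in% DNA_BASES
  if (any(bad)) {
    stop(sprintf(
      "clone contains %d non-ACGT character(s), first at position %d ('%s'); ambiguity codes are rejected to keep counts exact",
      sum(bad), which(bad)[1L], cchars[which(bad)[1L]]
    ), call. = FALSE)
  }
  rchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  pos <- which(cchars != rchars)
  data.frame(
    position = pos,
    ref_base = rchars[pos],
    alt_base = cchars[pos],
    stringsAsFactors = FALSE
  )
}

#' Apply mutation events to the reference
#'
#' Inverse of [call_mutations()]: reconstructs a clone sequence from the
#' reference and a set of substitution events.
#'
#' @param reference A [reference_gene()].
#' @param events Data frame with columns `position`, `ref_base`, `alt_base`;
#'   positions must be unique and the recorded `ref_base` must match the
#'   reference.
#' @return The mutated sequence string.
#' @export
apply_mutations <- function(reference, events) {
  stopifnot(inherits(reference, "reference_gene"))
  if (nrow(events) == 0L) return(reference$sequence)
  if (anyDuplicated(events$position)) {
    stop("events share a position; a clone carries at most one substitution per site", call. = FALSE)
  }
  if (any(events$position < 1L) || any(events$position > reference$length)) {
    stop("event position outside the reference", call. = FALSE)
  }
  chars <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  if (!all(chars[events$position] == events$ref_base)) {
    stop("event ref_base does not match the reference sequence", call. = FALSE)
  }
  chars[events$position] <- events$alt_base
  paste(chars, collapse = "")
}

#' Call mutations for every clone of a library or FASTA set
#'
#' @param sequences Named character vector of clone sequences (e.g.
#'   `retro_library$sequences` or the result of [read_fasta()]).
#' @param reference A [reference_gene()].
#' @return Mutation table with columns `clone_id`, `position`, `ref_base`,
#'   `alt_base`.
#' @export
call_mutations_all <- function(sequences, reference) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  per_clone <- lapply(names(sequences), function(id) {
    ev <- call_mutations(sequences[[id]], reference)
    if (nrow(ev)) cbind(clone_id = id, ev, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, per_clone)
  if (is.null(out)) {
    out <- data.frame(clone_id = character(0), position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

SUBSTITUTION_TYPES <- {
  grid <- expand.grid(from = DNA_BASES, to = DNA_BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  grid <- grid[order(grid$from, grid$to), ]
  paste0(grid$from, ">", grid$to)
}

TRANSITION_TYPES <- c("A>G", "G>A", "C>T", "T>C")

#' Summarize the substitution spectrum of a set of mutation events
#'
#' Tabulates the 12 ordered substitution types, their fractions of the
#' total, and the overall transition fraction. The G>A fraction — the
#' signature class of reverse-transcriptase errors — is reported to 0.1%.
#'
#' @param events Data frame with columns `ref_base` and `alt_base` (order of
#'   rows is irrelevant); an empty table is allowed.
#' @return An object of class `spectrum_summary`: list with `counts` (named
#'   integer vector over the 12 types), `total`, `fraction`,
#'   `transition_fraction`, `g_to_a_fraction` and `g_to_a_percent` (rounded
#'   to 0.1). With zero events the fractions are `NA` and `undefined` is
#'   `TRUE`.
#' @export
summarize_spectrum <- function(events) {
  stopifnot(all(c("ref_base", "alt_base") %in% names(events)))
  type <- if (nrow(events) == 0L) character(0) else paste0(events$ref_base, ">", events$alt_base)
  bad <- !type %in% SUBSTITUTION_TYPES
  if (any(bad)) {
    stop("invalid substitution type(s): ", paste(unique(type[bad]), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(type, levels = SUBSTITUTION_TYPES))
  counts <- setNames(as.integer(counts), SUBSTITUTION_TYPES)
  total <- sum(counts)
  undefined <- total == 0L
  fraction <- if (undefined) setNames(rep(NA_real_, 12L), SUBSTITUTION_TYPES) else counts / total
  structure(
    list(
      counts = counts,
      total = total,
      fraction = fraction,
      transition_fraction = if (undefined) NA_real_ else sum(counts[TRANSITION_TYPES]) / total,
      g_to_a_fraction = if (undefined) NA_real_ else counts[["G>A"]] / total,
      g_to_a_percent = if (undefined) NA_real_ else round(100 * counts[["G>A"]] / total, 1),
      undefined = undefined
    ),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> %d events\n", x$total))
  if (x$undefined) {
    cat("  no events: fractions undefined\n")
    return(invisible(x))
  }
  nz <- x$counts[x$counts > 0]
  for (tp in names(sort(nz, decreasing = TRUE))) {
    cat(sprintf("  %s: %d (%.1f%%)\n", tp, x$counts[[tp]], 100 * x$fraction[[tp]]))
  }
  cat(sprintf("  transitions: %.1f%%; G>A: %.1f%%\n",
              100 * x$transition_fraction, x$g_to_a_percent))
  invisible(x)
}

#' Histogram of mutated positions along the CDS
#'
#' Bins mutation-event positions into `bins` half-open intervals
#' `[start, end)` spanning `[1, cds_length + 1)`, so the final position falls
#' in the last bin. Total counts are conserved.
#'
#' @param events Data frame with a `position` column.
#' @param bins Number of bins (>= 1).
#' @param cds_length Length of the coding sequence in nt.
#' @return Data frame with `bin_start`, `bin_end` (exclusive) and `count`.
#' @export
position_histogram <- function(events, bins, cds_length) {
  stopifnot(bins >= 1L, cds_length >= 1L)
  pos <- events$position
  if (length(pos) && (any(pos < 1L) || any(pos > cds_length))) {
    stop("event position outside the CDS [1, ", cds_length, "]", call. = FALSE)
  }
  edges <- seq(1, cds_length + 1, length.out = bins + 1L)
  idx <- findInterval(pos, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = bins)
  data.frame(
    bin_start = edges[-(bins + 1L)],
    bin_end = edges[-1L],
    count = counts
  )
}
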