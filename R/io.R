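#' Read sequences from a FASTA file
#'
#' Thin wrapper around Biostrings preserving record order and ids;
#' sequences are uppercased. Alphabet validation (strict A/C/G/T) happens
#' downstream in [call_mutations()] / [reference_gene()] so that files with
#' ambiguity codes can still be inspected.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (empty, with a warning, for
#'   an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  setNames(toupper(as.character(set)), names(set))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Parse generation labels from clone ids
#'
#' Clone ids encode the generation label as a prefix (`F16_clone0007`).
#'
#' @param clone_ids Character vector.
#' @return Character vector of labels (`NA` where no label is encoded).
#' @export
generation_from_id <- function(clone_ids) {
  m <- regmatches(clone_ids, regexec("^(F-?[0-9]+|plasmid)_", clone_ids))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1L))
}

PLATE_COLUMNS <- c("clone_id", "experiment_id", "concentration_nM", "readout")
MUTATION_COLUMNS <- c("clone_id", "position", "ref_base", "alt_base", "cycle_introduced")

# strict TSV reader: exact header, typed columns, row-numbered errors
read_tsv_strict <- function(path, columns, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  if (!identical(names(df), columns)) {
    stop(sprintf(
      "%s: header must be exactly '%s' (got '%s')",
      path, paste(columns, collapse = "\t"), paste(names(df), collapse = "\t")
    ), call. = FALSE)
  }
  for (col in numeric_cols) {
    suppressWarnings(vals <- as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !df[[col]] %in% c("NA", ""))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' in column '%s' at data row %d",
                   path, df[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
    }
    df[[col]] <- vals
  }
  df
}

#' Read a viability-plate TSV
#'
#' Schema: `clone_id`, `experiment_id`, `concentration_nM`, `readout`
#' (tab-separated, `#` comment lines allowed). Concentrations are nM;
#' readouts must be numeric and non-negative; every (clone, experiment)
#' must include a 0-concentration row.
#'
#' @param path TSV path.
#' @return A validated plate data frame.
#' @export
read_plate_tsv <- function(path) {
  df <- read_tsv_strict(path, PLATE_COLUMNS, c("concentration_nM", "readout"))
  validate_plate(df)
  df
}

#' Write a viability plate to TSV
#'
#' @param plate Plate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_tsv <- function(plate, path) {
  validate_plate(plate)
  write_tsv_plain(plate[, PLATE_COLUMNS], path)
}

#' Write a mutation table to TSV
#'
#' A header comment states the coordinate convention (1-based, relative to
#' the CDS start, inclusive).
#'
#' @param mutations Mutation table (`clone_id`, `position`, `ref_base`,
#'   `alt_base`, and optionally `cycle_introduced`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations_tsv <- function(mutations, path) {
  if (!"cycle_introduced" %in% names(mutations)) mutations$cycle_introduced <- NA_integer_
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# positions are 1-based, relative to the CDS start, inclusive", con)
  write.table(mutations[, MUTATION_COLUMNS], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a mutation table TSV
#'
#' @param path TSV path (as written by [write_mutations_tsv()]).
#' @return Mutation table data frame.
#' @export
read_mutations_tsv <- function(path) {
  df <- read_tsv_strict(path, MUTATION_COLUMNS, c("position", "cycle_introduced"))
  df$position <- as.integer(df$position)
  df
}

#' Write a screening-result table to TSV
#'
#' @param results Result data frame (e.g. from [screen_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  write_tsv_plain(results, path)
}

# deterministic plain TSV writer (UTF-8, unix newlines, no quoting)
write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(names(df), collapse = "\t")
  body <- do.call(paste, c(lapply(df, format_tsv_col), sep = "\t"))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) format(v, digits = 15, scientific = NA, trim = TRUE),
                  character(1L))
    out[is.na(x)] <- "NA"
    out
  } else if (is.logical(x)) {
    ifelse(x, "TRUE", "FALSE")
  } else {
    as.character(x)
  }
}
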