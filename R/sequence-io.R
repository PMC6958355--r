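#' Read a proteome set from a FASTA file
#'
#' Parses a (wrapped or unwrapped) FASTA file into a one-row-per-protein
#' tibble. The header token before the first whitespace becomes the record
#' id; the remainder of the header line is kept as the description.
#' Sequences are uppercased. The tolerated ambiguity letters
#' (B, J, O, U, X, Z) are retained and counted in `n_ambiguous`; downstream
#' propensity windows and cleavage contexts that touch them are skipped.
#'
#' @param path Path to a FASTA file.
#' @param name Proteome label attached to every record (column `proteome`).
#'   Defaults to the file name without extension.
#' @return A tibble with columns `proteome`, `id`, `description`,
#'   `sequence`, `length`, `n_ambiguous`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 first", "MKF", ">P2", "AAAA"), fa)
#' read_proteome_fasta(fa, name = "demo")
#' @export
read_proteome_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) {
    abort(sprintf("FASTA file is empty: %s", path))
  }
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    abort(sprintf(
      "Malformed FASTA: sequence line before the first header at line %d of %s",
      first, path
    ))
  }

  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    abort(sprintf("FASTA file contains no records: %s", path))
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) {
    abort(sprintf("FASTA header with empty id in %s", path))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate record id(s) in %s: %s", path, paste(dup, collapse = ", ")
    ))
  }
  desc <- trimws(sub("^\\S+", "", headers))
  sequence <- toupper(as.character(seqs))

  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  n_amb <- vapply(
    seq_along(sequence),
    function(i) check_sequence(sequence[i], ids[i]),
    integer(1)
  )
  out <- tibble(
    proteome = name,
    id = ids,
    description = desc,
    sequence = unname(sequence),
    length = nchar(unname(sequence)),
    n_ambiguous = n_amb
  )
  if (any(out$n_ambiguous > 0)) {
    flagged <- out$id[out$n_ambiguous > 0]
    warn(sprintf(
      "%d record(s) contain ambiguity letters (retained, excluded from windows): %s",
      length(flagged), paste(head(flagged, 5), collapse = ", ")
    ))
  }
  out
}

#' Read several FASTA files as named proteome sets
#'
#' @param paths Character vector of FASTA paths; names are used as proteome
#'   labels (unnamed entries fall back to file names).
#' @return A single tibble of all records with their `proteome` labels.
#' @export
read_proteome_sets <- function(paths) {
  labels <- names(paths) %||% rep("", length(paths))
  if (is.null(names(paths))) names(paths) <- rep("", length(paths))
  purrr::map2_dfr(paths, labels, function(p, lab) {
    read_proteome_fasta(p, name = if (nzchar(lab)) lab else NULL)
  })
}

#' Write a proteome set to FASTA
#'
#' Output is canonical unwrapped FASTA: one sequence line per record.
#'
#' @param proteins Tibble with at least `id` and `sequence` (optionally
#'   `description`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteins, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  desc <- proteins$description %||% rep("", nrow(proteins))
  headers <- ifelse(nzchar(desc),
                    paste(proteins$id, desc),
                    proteins$id)
  out <- character(2L * nrow(proteins))
  out[c(TRUE, FALSE)] <- paste0(">", headers)
  out[c(FALSE, TRUE)] <- proteins$sequence
  writeLines(out, path)
  invisible(path)
}

#' Map each distinct sequence to the proteome sets containing it
#'
#' @param proteins Tibble with `proteome` and a sequence column.
#' @param col Name of the sequence column (default `"sequence"`).
#' @return Tibble with one row per distinct sequence: `sequence`,
#'   `proteomes` (list-column of sorted set names), `n_proteomes`.
#' @export
unique_sequences <- function(proteins, col = "sequence") {
  stopifnot("proteome" %in% names(proteins), col %in% names(proteins))
  proteins |>
    dplyr::rename(sequence = dplyr::all_of(col)) |>
    dplyr::distinct(.data$sequence, .data$proteome) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      proteomes = list(sort(unique(.data$proteome))),
      n_proteomes = dplyr::n_distinct(.data$proteome),
      .groups = "drop"
    )
}

#' Write a pipeline table as TSV
#'
#' Tab-separated with a header row; floating-point columns are rounded to
#' `digits` significant digits (list-columns are collapsed with commas).
#'
#' @param x A data frame.
#' @param path Output path.
#' @param digits Significant digits for doubles (default 4).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, digits = 4) {
  out <- x |>
    dplyr::mutate(dplyr::across(
      dplyr::where(is.double), ~ signif(.x, digits)
    )) |>
    dplyr::mutate(dplyr::across(
      dplyr::where(is.list),
      ~ purrr::map_chr(.x, function(v) paste(unlist(v), collapse = ","))
    ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
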