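# Amino-acid alphabet handling. The 20 standard residues are the working
# alphabet; the IUPAC ambiguity/rare letters are tolerated in input records
# but excluded from every window or cleavage-context computation.

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

AA_AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

#' Split a sequence into residue characters
#' @noRd
aa_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Validate an amino-acid sequence, returning its ambiguity count
#'
#' Errors on characters outside the 20 standard residues plus the tolerated
#' ambiguity letters (B, J, O, U, X, Z); ambiguity letters are counted, never
#' dropped.
#' @noRd
check_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    abort("`sequence` must be a single string.")
  }
  if (nchar(sequence) < 1) {
    abort(sprintf("Record '%s' has an empty sequence.", id))
  }
  chars <- aa_chars(sequence)
  bad <- setdiff(unique(chars), c(AA_STANDARD, AA_AMBIGUOUS))
  if (length(bad) > 0) {
    abort(sprintf(
      "Record '%s' contains characters outside the amino-acid alphabet: %s",
      id, paste(bad, collapse = ", ")
    ))
  }
  sum(chars %in% AA_AMBIGUOUS)
}

read_resource <- function(file) {
  key <- paste0("res_", file)
  if (is.null(the[[key]])) {
    path <- system.file("extdata", file, package = "ampsieve", mustWork = TRUE)
    the[[key]] <- utils::read.delim(path, stringsAsFactors = FALSE,
                                    na.strings = NULL)
  }
  the[[key]]
}
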