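#' Cleavage stability score
#'
#' `CSS = 100 / (1 + sum of intestinal-protease cleavage sites)`. A
#' peptide with no recognisable site scores 100; the score decreases
#' strictly with every additional site and approaches 0.
#'
#' @param n_sites Total cleavage-site count(s); non-negative, vectorised.
#' @return CSS value(s) in (0, 100].
#' @examples
#' css(0)   # 100
#' css(14)  # 6.67 to two decimals
#' @export
css <- function(n_sites) {
  if (any(!is.finite(n_sites)) || any(n_sites < 0)) {
    abort("`n_sites` must be non-negative and finite.")
  }
  100 / (1 + n_sites)
}

#' Decay rate from half-life
#'
#' First-order decay: `d = ln(2) / tau`, with `tau` in seconds and `d`
#' in 1/s.
#'
#' @param half_life Half-life(s) in seconds; strictly positive.
#' @return Decay rate(s) in 1/s.
#' @export
decay_rate <- function(half_life) {
  if (any(!is.finite(half_life)) || any(half_life <= 0)) {
    abort("`half_life` must be strictly positive and finite (seconds).")
  }
  log(2) / half_life
}

#' Half-life provider
#'
#' Attaches a half-life (seconds) to every requested peptide, either from
#' a lookup table (e.g. exported batch predictions of an external
#' half-life model) or from the built-in deterministic stub. The stub
#' assigns the constant `stub_tau` to every peptide and is flagged
#' `"stub"` in `tau_source` wherever it is used, so downstream tables
#' always disclose estimated provenance.
#'
#' @param peptides Character vector of peptide sequences (or data frame
#'   with a `peptide` column).
#' @param table Optional lookup: a data frame with columns
#'   `peptide`/`sequence` and `tau`/`tau_seconds`/`half_life`, or a path
#'   to such a TSV. `NULL` (default) uses the stub for every peptide.
#' @param allow_stub_fallback When a table is given but misses peptides,
#'   fall back to the stub for the missing ones instead of aborting.
#' @param stub_tau Constant stub half-life in seconds (default 1).
#' @return Tibble `peptide`, `tau` (seconds), `tau_source`
#'   (`"table"`/`"stub"`).
#' @export
half_life_provider <- function(peptides, table = NULL,
                               allow_stub_fallback = FALSE, stub_tau = 1) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  out <- tibble(peptide = peptides, tau = NA_real_,
                tau_source = NA_character_)
  if (is.null(table)) {
    out$tau <- stub_tau
    out$tau_source <- "stub"
    return(out)
  }
  if (is.character(table) && length(table) == 1) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  table <- tibble::as_tibble(table)
  seq_col <- intersect(c("peptide", "sequence"), names(table))[1]
  tau_col <- intersect(c("tau", "tau_seconds", "half_life"), names(table))[1]
  if (is.na(seq_col) || is.na(tau_col)) {
    abort("Half-life table needs a sequence column and a tau column.")
  }
  bad <- which(!is.finite(table[[tau_col]]) | table[[tau_col]] <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Half-life table has non-positive tau at row(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  idx <- match(peptides, table[[seq_col]])
  out$tau <- table[[tau_col]][idx]
  out$tau_source <- ifelse(is.na(idx), NA_character_, "table")
  missing <- unique(peptides[is.na(idx)])
  if (length(missing) > 0) {
    if (!allow_stub_fallback) {
      abort(sprintf(
        "No half-life for %d peptide(s): %s%s",
        length(missing), paste(head(missing, 10), collapse = ", "),
        if (length(missing) > 10) ", ..." else ""
      ))
    }
    out$tau[is.na(out$tau_source)] <- stub_tau
    out$tau_source[is.na(out$tau_source)] <- "stub"
  }
  out
}

#' Score peptide stability against intestinal proteases
#'
#' Counts cleavage sites for the intestinal panel (pepsin pH > 2,
#' chymotrypsin, enterokinase, trypsin, thrombin) on each peptide in
#' isolation, computes the cleavage stability score and, via the
#' half-life provider, the first-order decay rate.
#'
#' @param peptides Tibble with a `peptide` column (e.g. from
#'   [dedupe_amps()]) or a character vector.
#' @param rules A [cleavage_rules()] table.
#' @param half_lives Passed to [half_life_provider()] as `table`.
#' @param allow_stub_fallback,stub_tau Passed to [half_life_provider()].
#' @param enzymes Intestinal enzyme panel (default Pb, CT, E, T, Th).
#' @return The input tibble with added columns `N_<enzyme>` per enzyme,
#'   `n_sites`, `css`, `tau`, `decay`, `tau_source`.
#' @export
score_stability <- function(peptides, rules = cleavage_rules(),
                            half_lives = NULL,
                            allow_stub_fallback = FALSE, stub_tau = 1,
                            enzymes = c("Pb", "CT", "E", "T", "Th")) {
  if (is.character(peptides)) peptides <- tibble(peptide = peptides)
  stopifnot("peptide" %in% names(peptides))
  counts <- count_cleavage_sites(peptides$peptide, rules, enzymes)
  taus <- half_life_provider(peptides$peptide, table = half_lives,
                             allow_stub_fallback = allow_stub_fallback,
                             stub_tau = stub_tau)
  peptides |>
    dplyr::bind_cols(counts[-1]) |>
    dplyr::mutate(
      css = css(.data$n_sites),
      tau = taus$tau,
      decay = decay_rate(taus$tau),
      tau_source = taus$tau_source
    )
}
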