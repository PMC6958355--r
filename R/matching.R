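#' Match digestion fragments to antimicrobial stretches
#'
#' A fragment matches a stretch when both come from the same parent
#' protein, the fragment fully contains the stretch, and the fragment
#' extends at most `max_overhang` residues beyond either stretch
#' terminus. Because matching is coordinate-based within one parent,
#' sequence identity over the overlap is 100% by construction. A fragment
#' may match several stretches and vice versa; each admissible pair
#' yields one row.
#'
#' @param fragments Tibble from [digest_proteome()] (columns `parent_id`,
#'   `start`, `end`, `peptide`, optionally `proteome`).
#' @param stretches Tibble from [scan_proteome()] (columns `parent_id`,
#'   `start`, `end`, `pv`, optionally `proteome`).
#' @param max_overhang Maximum residues of fragment overhang past each
#'   stretch terminus (default 2).
#' @return Tibble with one row per admissible (fragment, stretch) pair:
#'   `proteome` (if present in both inputs), `parent_id`, `peptide`,
#'   `start`, `end`, `stretch_start`, `stretch_end`, `pv`, `n_overhang`,
#'   `c_overhang`, `exact`.
#' @export
match_amps <- function(fragments, stretches, max_overhang = 2) {
  if (max_overhang < 0) abort("`max_overhang` must be >= 0.")
  keys <- intersect(c("proteome", "parent_id"),
                    intersect(names(fragments), names(stretches)))
  if (!"parent_id" %in% keys) {
    abort("Both inputs need a `parent_id` column.")
  }
  st <- stretches |>
    dplyr::select(dplyr::all_of(keys),
                  stretch_start = "start", stretch_end = "end", "pv")
  fragments |>
    dplyr::select(dplyr::all_of(keys), "peptide", "start", "end") |>
    dplyr::inner_join(st, by = keys, relationship = "many-to-many") |>
    dplyr::mutate(
      n_overhang = .data$stretch_start - .data$start,
      c_overhang = .data$end - .data$stretch_end
    ) |>
    dplyr::filter(
      .data$n_overhang >= 0, .data$n_overhang <= max_overhang,
      .data$c_overhang >= 0, .data$c_overhang <= max_overhang
    ) |>
    dplyr::mutate(exact = .data$n_overhang == 0L & .data$c_overhang == 0L) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)),
                   .data$start, .data$end, .data$stretch_start)
}

#' Deduplicate matches by peptide sequence and trace proteome membership
#'
#' Collapses the match table to one row per distinct peptide sequence.
#' The representative stretch for each peptide is the lowest-propensity
#' (most antimicrobial) witness; all witnesses are retained in a nested
#' list-column for back-tracing, and proteome membership is the set of
#' proteome labels in which the peptide occurs.
#'
#' @param matches Tibble from [match_amps()].
#' @return Tibble with one row per peptide: `peptide`, `length`, `pv`,
#'   `exact` (any witness exact), `n_witnesses`, `proteomes` (list-column
#'   of sorted labels), `n_proteomes`, `witnesses` (nested tibble).
#' @export
dedupe_amps <- function(matches) {
  has_set <- "proteome" %in% names(matches)
  if (!has_set) {
    matches$proteome <- "all"
  }
  matches |>
    dplyr::group_by(.data$peptide) |>
    dplyr::arrange(.data$pv, .data$parent_id, .data$stretch_start,
                   .by_group = TRUE) |>
    dplyr::summarise(
      length = nchar(.data$peptide[1]),
      pv = .data$pv[1],
      exact = any(.data$exact),
      n_witnesses = dplyr::n(),
      proteomes = list(sort(unique(.data$proteome))),
      n_proteomes = dplyr::n_distinct(.data$proteome),
      witnesses = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    )
}

#' Proteome overlap structure of a deduplicated peptide set
#'
#' @param deduped Tibble from [dedupe_amps()] (needs `peptide` and the
#'   `proteomes` list-column).
#' @return List with `pairwise` (tibble `proteome_a`, `proteome_b`,
#'   `n_common`, including the diagonal totals), `unique` (tibble
#'   `proteome`, `n_unique`) and `common_all` (count present in every
#'   proteome observed).
#' @export
amp_overlap <- function(deduped) {
  if (!"n_proteomes" %in% names(deduped)) {
    deduped$n_proteomes <- lengths(lapply(deduped$proteomes, unique))
  }
  long <- deduped |>
    dplyr::select("peptide", "proteomes") |>
    tidyr::unnest("proteomes") |>
    dplyr::rename(proteome = "proteomes")
  sets <- sort(unique(long$proteome))
  pairwise <- tidyr::expand_grid(proteome_a = sets, proteome_b = sets) |>
    dplyr::rowwise() |>
    dplyr::mutate(n_common = length(intersect(
      long$peptide[long$proteome == .data$proteome_a],
      long$peptide[long$proteome == .data$proteome_b]
    ))) |>
    dplyr::ungroup()
  uniq <- deduped |>
    dplyr::filter(.data$n_proteomes == 1) |>
    tidyr::unnest("proteomes") |>
    dplyr::count(proteome = .data$proteomes, name = "n_unique") |>
    tidyr::complete(proteome = sets, fill = list(n_unique = 0L))
  list(
    pairwise = pairwise,
    unique = uniq,
    common_all = sum(deduped$n_proteomes == length(sets))
  )
}

#' Count peptides common to a sub-collection of proteomes
#'
#' @param deduped Tibble from [dedupe_amps()].
#' @param proteomes Character vector of proteome labels.
#' @return Number of distinct peptides present in every listed proteome.
#' @export
common_amps <- function(deduped, proteomes) {
  sum(purrr::map_lgl(deduped$proteomes,
                     ~ all(proteomes %in% .x)))
}
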