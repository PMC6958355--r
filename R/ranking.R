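#' Normalise positive values by their maximum
#'
#' @param x Non-empty vector of strictly positive finite values.
#' @return `x / max(x)`; at least one element equals 1.
#' @export
normalize_max <- function(x) {
  if (length(x) == 0) abort("Cannot normalise an empty vector.")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("All values must be strictly positive and finite.")
  }
  x / max(x)
}

#' Rank peptides by the combined antimicrobial score
#'
#' The combined antimicrobial score of peptide x is
#' `CAS = css_bar / (pv_bar * d_bar)`, where each bar denotes the value
#' divided by its maximum over the whole scored set (pooled across
#' proteomes): a peptide scores high when it is stable (high CSS),
#' strongly antimicrobial (low propensity) and slow to decay. Rows are
#' sorted by decreasing CAS; ties break deterministically by higher CSS,
#' then lexicographic peptide sequence.
#'
#' @param scored Tibble with columns `peptide`, `css`, `pv`, `decay`
#'   (e.g. [score_stability()] output joined with stretch propensities).
#'   All three score columns must be strictly positive and complete.
#' @return An `amp_ranking` tibble: input columns plus `css_bar`,
#'   `pv_bar`, `d_bar`, `cas`, `rank`.
#' @export
rank_amps <- function(scored) {
  needed <- c("peptide", "css", "pv", "decay")
  missing <- setdiff(needed, names(scored))
  if (length(missing) > 0) {
    abort(sprintf("`scored` lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (col in c("css", "pv", "decay")) {
    bad <- which(!is.finite(scored[[col]]) | scored[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "Column `%s` must be strictly positive; offending peptide(s): %s",
        col, paste(head(scored$peptide[bad], 10), collapse = ", ")
      ))
    }
  }
  out <- scored |>
    dplyr::mutate(
      css_bar = normalize_max(.data$css),
      pv_bar = normalize_max(.data$pv),
      d_bar = normalize_max(.data$decay),
      cas = .data$css_bar / (.data$pv_bar * .data$d_bar)
    ) |>
    dplyr::arrange(dplyr::desc(.data$cas), dplyr::desc(.data$css),
                   .data$peptide) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("amp_ranking", class(out))
  attr(out, "maxima") <- c(css = max(scored$css), pv = max(scored$pv),
                           decay = max(scored$decay))
  out
}

#' Select the top-N peptides of a ranking
#'
#' @param ranking An `amp_ranking` from [rank_amps()].
#' @param n Number of peptides to keep (default 100; the whole set if
#'   fewer). The cutoff carries no scoring meaning — it sizes the subset.
#' @return The top rows, with attribute `cutoff_cas` (lowest CAS kept).
#' @export
top_amps <- function(ranking, n = 100) {
  if (n < 1) abort("`n` must be >= 1.")
  out <- dplyr::slice_head(ranking, n = n)
  attr(out, "cutoff_cas") <- min(out$cas)
  out
}

#' Per-proteome summary of a scored peptide set
#'
#' A peptide contributes to every proteome it is traced to, so shared
#' peptides are counted in each of their proteomes (the convention behind
#' per-proteome population metrics of a pooled ranking).
#'
#' @param ranking An `amp_ranking` with a `proteomes` list-column.
#' @param proteome_sizes Named vector of protein counts per proteome
#'   (for the `ratio` column), or `NULL`.
#' @return List with `proteomes` (per-proteome n, ratio, mean pv, mean
#'   decay, mean css, mean cas, n_unique), `pairwise` common-count
#'   tibble, and `common_all`.
#' @export
proteome_summary <- function(ranking, proteome_sizes = NULL) {
  if (!"proteomes" %in% names(ranking)) {
    abort("`ranking` needs a `proteomes` list-column (see dedupe_amps()).")
  }
  long <- ranking |>
    tidyr::unnest("proteomes") |>
    dplyr::rename(proteome_label = "proteomes")
  per <- long |>
    dplyr::group_by(proteome = .data$proteome_label) |>
    dplyr::summarise(
      n_amps = dplyr::n(),
      mean_pv = mean(.data$pv),
      mean_decay = mean(.data$decay),
      mean_css = mean(.data$css),
      mean_cas = mean(.data$cas),
      .groups = "drop"
    )
  ov <- amp_overlap(ranking)
  per <- dplyr::left_join(per, ov$unique, by = "proteome")
  if (!is.null(proteome_sizes)) {
    per <- per |>
      dplyr::mutate(
        n_proteins = as.integer(proteome_sizes[.data$proteome]),
        ratio = .data$n_amps / .data$n_proteins
      ) |>
      dplyr::relocate("n_proteins", .after = "proteome")
  }
  structure(
    list(proteomes = per, pairwise = ov$pairwise,
         common_all = ov$common_all),
    class = "amp_proteome_summary"
  )
}

#' @export
print.amp_proteome_summary <- function(x, ...) {
  cat("<amp_proteome_summary>\n")
  print(x$proteomes)
  cat(sprintf("Peptides common to all proteomes: %d\n", x$common_all))
  invisible(x)
}

#' @export
tidy.amp_ranking <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "amp_ranking")
  keep <- intersect(
    c("rank", "peptide", "length", "pv", "n_sites", "css", "tau", "decay",
      "tau_source", "css_bar", "pv_bar", "d_bar", "cas", "exact",
      "n_proteomes", "proteomes"),
    names(out)
  )
  dplyr::select(tibble::as_tibble(out), dplyr::all_of(keep))
}

#' @export
glance.amp_ranking <- function(x, ...) {
  tibble(
    n_peptides = nrow(x),
    n_proteomes = if ("proteomes" %in% names(x)) {
      length(unique(unlist(x$proteomes)))
    } else NA_integer_,
    top_cas = max(x$cas),
    median_cas = stats::median(x$cas),
    mean_css = mean(x$css),
    mean_decay = mean(x$decay),
    n_exact = if ("exact" %in% names(x)) sum(x$exact) else NA_integer_
  )
}
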