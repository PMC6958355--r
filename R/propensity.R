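#' Antimicrobial propensity scale
#'
#' A propensity scale assigns every standard residue a strictly positive,
#' dimensionless antimicrobial propensity; LOWER values mean stronger
#' antimicrobial character. The default scale ships as an editable
#' two-column table (`inst/extdata/ampa_propensity_scale.tsv`). The scan
#' slides a window of `window` residues along each protein, and maximal
#' runs of windows whose mean propensity falls strictly below `threshold`
#' are reported as antimicrobial stretches when they span at least
#' `min_stretch` residues.
#'
#' @param values Named numeric vector of per-residue propensities covering
#'   all 20 standard residues, or `NULL` for the shipped default scale.
#' @param name Label for the scale.
#' @param window Sliding-window width in residues (default 7).
#' @param threshold Propensity threshold; windows strictly below it are
#'   antimicrobial (default 0.225).
#' @param min_stretch Minimum reported stretch length in residues
#'   (default 12; inclusive).
#' @return An object of class `propensity_scale`.
#' @examples
#' sc <- propensity_scale()
#' sc$values[c("K", "R", "D")]
#' @export
propensity_scale <- function(values = NULL, name = NULL, window = 7,
                             threshold = 0.225, min_stretch = 12) {
  if (is.null(values)) {
    tab <- read_resource("ampa_propensity_scale.tsv")
    values <- setNames(tab$propensity, tab$residue)
    name <- name %||% "ampa-default"
  }
  name <- name %||% "custom"
  missing <- setdiff(AA_STANDARD, names(values))
  if (length(missing) > 0) {
    abort(sprintf(
      "Propensity scale lacks residues: %s", paste(missing, collapse = ", ")
    ))
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("Propensity values must all be strictly positive and finite.")
  }
  window <- as.integer(window)
  min_stretch <- as.integer(min_stretch)
  if (window < 1) abort("`window` must be >= 1.")
  if (min_stretch < window) abort("`min_stretch` must be >= `window`.")
  if (!is.numeric(threshold) || length(threshold) != 1) {
    abort("`threshold` must be a single number.")
  }
  structure(
    list(values = values[AA_STANDARD], name = name, window = window,
         threshold = threshold, min_stretch = min_stretch),
    class = "propensity_scale"
  )
}

#' Read a propensity scale from a two-column file
#'
#' @param path Path to a tab-separated file with columns `residue` and
#'   `propensity` (header required).
#' @inheritParams propensity_scale
#' @export
read_propensity_scale <- function(path, window = 7, threshold = 0.225,
                                  min_stretch = 12) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  propensity_scale(setNames(tab[[2]], tab[[1]]),
                   name = basename(path), window = window,
                   threshold = threshold, min_stretch = min_stretch)
}

#' @export
print.propensity_scale <- function(x, ...) {
  cat(sprintf(
    "<propensity_scale '%s'> window=%d threshold=%g min_stretch=%d\n",
    x$name, x$window, x$threshold, x$min_stretch
  ))
  print(round(x$values, 3))
  invisible(x)
}

# Per-residue propensities with NA at ambiguity letters
residue_propensities <- function(sequence, scale) {
  chars <- aa_chars(sequence)
  unname(scale$values[chars])
}

#' Sliding-window propensity profile
#'
#' One row per window start 1 ... L - W + 1 whose window contains only
#' standard residues; windows touching an ambiguity letter are omitted.
#' Sequences shorter than the window give an empty profile.
#'
#' @param sequence Protein sequence (uppercase).
#' @param scale A [propensity_scale()].
#' @return Tibble with columns `start` (1-based window start) and `mean_pv`.
#' @export
window_profile <- function(sequence, scale = propensity_scale()) {
  w <- scale$window
  v <- residue_propensities(sequence, scale)
  n <- length(v)
  if (n < w) {
    return(tibble(start = integer(0), mean_pv = numeric(0)))
  }
  bad <- is.na(v)
  v0 <- ifelse(bad, 0, v)
  cs <- c(0, cumsum(v0))
  cb <- c(0, cumsum(bad))
  starts <- seq_len(n - w + 1)
  n_bad <- cb[starts + w] - cb[starts]
  means <- (cs[starts + w] - cs[starts]) / w
  keep <- n_bad == 0
  tibble(start = starts[keep], mean_pv = means[keep])
}

#' Call antimicrobial stretches in one sequence
#'
#' A stretch is the residue span covered by a maximal run of consecutive
#' window starts whose window mean is strictly below the scale threshold:
#' starts w1 ... wk map to residues `[w1, wk + window - 1]`. Spans shorter
#' than `min_stretch` are discarded. The reported `pv` is the mean residue
#' propensity over the span.
#'
#' @inheritParams window_profile
#' @return Tibble with columns `start`, `end`, `length`, `sequence`, `pv`,
#'   in position order.
#' @export
call_stretches <- function(sequence, scale = propensity_scale()) {
  w <- scale$window
  prof <- window_profile(sequence, scale)
  below <- prof$start[prof$mean_pv < scale$threshold]
  empty <- tibble(
    start = integer(0), end = integer(0), length = integer(0),
    sequence = character(0), pv = numeric(0)
  )
  if (length(below) == 0) return(empty)
  run <- cumsum(c(1L, as.integer(diff(below) != 1L)))
  v <- residue_propensities(sequence, scale)
  spans <- tibble(start = below, run = run) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      end = max(.data$start) + w - 1L,
      start = min(.data$start),
      .groups = "drop"
    ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L) |>
    dplyr::filter(.data$length >= scale$min_stretch)
  if (nrow(spans) == 0) return(empty)
  spans |>
    dplyr::mutate(
      sequence = substring(sequence, .data$start, .data$end),
      pv = purrr::map2_dbl(.data$start, .data$end,
                           ~ mean(v[.x:.y]))
    ) |>
    dplyr::arrange(.data$start) |>
    dplyr::select("start", "end", "length", "sequence", "pv")
}

#' Scan a proteome set for antimicrobial stretches
#'
#' Applies [call_stretches()] to every record and tags results with the
#' parent id (and proteome label when present).
#'
#' @param proteins Tibble with columns `id` and `sequence` (and optionally
#'   `proteome`).
#' @param scale A [propensity_scale()].
#' @return Tibble of stretches with `proteome` (if supplied), `parent_id`,
#'   `start`, `end`, `length`, `sequence`, `pv`.
#' @export
scan_proteome <- function(proteins, scale = propensity_scale()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  has_set <- "proteome" %in% names(proteins)
  res <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    st <- call_stretches(proteins$sequence[i], scale)
    if (nrow(st) == 0) return(NULL)
    st$parent_id <- proteins$id[i]
    if (has_set) st$proteome <- proteins$proteome[i]
    st
  })
  cols <- c(if (has_set) "proteome", "parent_id",
            "start", "end", "length", "sequence", "pv")
  if (nrow(res) == 0) {
    return(tibble::as_tibble(setNames(
      lapply(cols, function(cl) {
        if (cl %in% c("start", "end", "length")) integer(0)
        else if (cl == "pv") numeric(0) else character(0)
      }), cols
    )))
  }
  dplyr::select(res, dplyr::all_of(cols))
}
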