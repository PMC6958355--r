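#' Pepsin digestion boundaries
#'
#' Boundaries are 0-based gap indices: boundary `b` sits between residues
#' `b` and `b + 1`, so the protein termini contribute boundaries `0` and
#' `L`. Cleavage sites (bond positions) are used as-is.
#'
#' @param length Protein length L.
#' @param sites Integer vector of cleaved bond positions (1 ... L-1).
#' @return Sorted distinct boundary vector including `0` and `L`.
#' @export
pepsin_boundaries <- function(length, sites = integer(0)) {
  length <- as.integer(length)
  sites <- as.integer(sites)
  if (any(sites < 1L | sites >= length)) {
    abort("Cleavage sites must lie strictly inside the sequence (1 ... L-1).")
  }
  sort(unique(c(0L, sites, length)))
}

#' Closed-form fragment count for partial digestion
#'
#' With `n_sites` internal pepsin sites a protein has `n_sites + 2`
#' boundaries; every unordered boundary pair except the full-length pair
#' yields a distinct fragment, i.e. `choose(n_sites + 2, 2) - 1`.
#'
#' @param n_sites Number of internal cleavage sites (vectorised).
#' @return Number of enumerable fragments.
#' @export
fragment_count <- function(n_sites) {
  choose(n_sites + 2, 2) - 1
}

#' Enumerate all partial-digestion fragments
#'
#' Models complete and partial pepsin digestion at once: every fragment
#' obtainable under any subset of hydrolysed sites is the interval between
#' some boundary pair, so one fragment is emitted per unordered boundary
#' pair `(b1 < b2)`, covering residues `[b1 + 1, b2]`. The full-length
#' pair `(0, L)` is always excluded: the intact protein is not a
#' digestion product.
#'
#' @param sequence Protein sequence.
#' @param boundaries Sorted boundary vector including `0` and `L`
#'   (see [pepsin_boundaries()]).
#' @return Tibble with `start`, `end`, `length`, `peptide`.
#' @examples
#' b <- pepsin_boundaries(4, sites = 2)
#' enumerate_fragments("ABCD", b)  # "AB" and "CD"
#' @export
enumerate_fragments <- function(sequence, boundaries) {
  L <- nchar(sequence)
  b <- as.integer(boundaries)
  if (is.unsorted(b, strictly = TRUE) || b[1] != 0L || b[length(b)] != L) {
    abort("`boundaries` must be strictly increasing and include 0 and L.")
  }
  n <- length(b)
  if (n < 2) abort("Need at least the two terminal boundaries.")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  keep <- !(i == 1L & j == n)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) {
    return(tibble(start = integer(0), end = integer(0),
                  length = integer(0), peptide = character(0)))
  }
  start <- b[i] + 1L
  end <- b[j]
  tibble(
    start = start,
    end = end,
    length = end - start + 1L,
    peptide = substring(sequence, start, end)
  )
}

#' Filter fragments to the reportable length window
#'
#' @param fragments Tibble with a `length` column.
#' @param min_len,max_len Inclusive length bounds (defaults 12 and 47:
#'   the minimum antimicrobial stretch length and the longest observed
#'   stretch plus the two-residue overhang margin at each end).
#' @return The surviving rows, order preserved.
#' @export
filter_length <- function(fragments, min_len = 12, max_len = 47) {
  if (min_len > max_len) {
    abort("`min_len` must not exceed `max_len`.")
  }
  dplyr::filter(fragments,
                .data$length >= min_len, .data$length <= max_len)
}

#' Digest a proteome set with pepsin (pH < 1.8)
#'
#' Runs cleavage-site recognition for pepsin `Pa` on every record and
#' enumerates the partial-digestion fragments inside the length window.
#' Only boundary pairs whose span lies in `[min_len, max_len]` are
#' materialised, which keeps whole-proteome digestion tractable; the
#' result is identical to [enumerate_fragments()] followed by
#' [filter_length()].
#'
#' @param proteins Tibble with `id`, `sequence` (optionally `proteome`).
#' @param rules A [cleavage_rules()] table containing enzyme `Pa`.
#' @param min_len,max_len Inclusive fragment length window.
#' @return Tibble with `proteome` (if supplied), `parent_id`, `start`,
#'   `end`, `length`, `peptide`, plus one attribute `n_sites` (named
#'   integer vector of per-protein Pa site counts).
#' @export
digest_proteome <- function(proteins, rules = cleavage_rules(),
                            min_len = 12, max_len = 47) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (min_len > max_len) abort("`min_len` must not exceed `max_len`.")
  has_set <- "proteome" %in% names(proteins)
  site_counts <- integer(nrow(proteins))
  res <- purrr::map_dfr(seq_len(nrow(proteins)), function(k) {
    s <- proteins$sequence[k]
    L <- nchar(s)
    sites <- find_cleavage_sites(s, "Pa", rules)
    site_counts[k] <<- length(sites)
    b <- pepsin_boundaries(L, sites)
    n <- length(b)
    # all pairs (i < j) with span in the window, excluding (0, L)
    span <- outer(b, b, function(x, y) y - x)
    ok <- upper.tri(span) & span >= min_len & span <= max_len
    ok[1, n] <- FALSE
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    start <- b[idx[, 1]] + 1L
    end <- b[idx[, 2]]
    ord <- order(start, end)
    start <- start[ord]
    end <- end[ord]
    out <- tibble(
      parent_id = proteins$id[k],
      start = start,
      end = end,
      length = end - start + 1L,
      peptide = substring(s, start, end)
    )
    if (has_set) out$proteome <- proteins$proteome[k]
    out
  })
  cols <- c(if (has_set) "proteome", "parent_id",
            "start", "end", "length", "peptide")
  if (nrow(res) == 0) {
    res <- tibble::as_tibble(setNames(lapply(cols, function(cl) {
      if (cl %in% c("start", "end", "length")) integer(0) else character(0)
    }), cols))
  } else {
    res <- dplyr::select(res, dplyr::all_of(cols))
  }
  attr(res, "n_sites") <- setNames(site_counts, proteins$id)
  res
}
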