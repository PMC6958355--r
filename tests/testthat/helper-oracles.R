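# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (loops, full enumeration) so they cannot
# share a defect with the vectorised implementation they check.

# Two-valued synthetic scale: residue A is "antimicrobial" (low), B..Z high.
toy_scale <- function(lo = 0.1, hi = 0.5, window = 7, threshold = 0.225,
                      min_stretch = 12) {
  vals <- setNames(rep(hi, 20), ampsieve:::AA_STANDARD)
  vals["A"] <- lo
  propensity_scale(vals, name = "toy", window = window,
                   threshold = threshold, min_stretch = min_stretch)
}

random_seq <- function(n, alphabet = c("A", "G")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Naive window scan: test every window with an explicit loop.
naive_profile <- function(sequence, scale) {
  chars <- strsplit(sequence, "")[[1]]
  w <- scale$window
  out <- list()
  if (length(chars) >= w) {
    for (s in seq_len(length(chars) - w + 1)) {
      vals <- scale$values[chars[s:(s + w - 1)]]
      if (any(is.na(vals))) next
      out[[length(out) + 1]] <- data.frame(start = s, mean_pv = mean(vals))
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), mean_pv = numeric(0)))
  }
  do.call(rbind, out)
}

# Naive stretch assembly: walk the qualifying starts and close runs at gaps.
naive_stretches <- function(sequence, scale) {
  prof <- naive_profile(sequence, scale)
  below <- prof$start[prof$mean_pv < scale$threshold]
  spans <- list()
  if (length(below) > 0) {
    run_start <- below[1]
    prev <- below[1]
    for (s in c(below[-1], NA)) {
      if (is.na(s) || s != prev + 1) {
        spans[[length(spans) + 1]] <- c(run_start, prev + scale$window - 1)
        run_start <- s
      }
      prev <- s
    }
  }
  spans <- Filter(function(sp) sp[2] - sp[1] + 1 >= scale$min_stretch, spans)
  chars <- strsplit(sequence, "")[[1]]
  do.call(rbind, c(list(data.frame(start = integer(0), end = integer(0),
                                   pv = numeric(0))),
                   lapply(spans, function(sp) {
                     data.frame(start = sp[1], end = sp[2],
                                pv = mean(scale$values[chars[sp[1]:sp[2]]]))
                   })))
}

# Brute-force partial-digestion oracle: enumerate every subset of cut
# sites, collect the contiguous fragments each subset produces, and drop
# the intact protein.
subset_fragments <- function(L, sites) {
  seen <- new.env()
  n <- length(sites)
  for (mask in 0:(2^n - 1)) {
    cut <- sites[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    b <- c(0, cut, L)
    for (k in seq_len(length(b) - 1)) {
      key <- paste(b[k] + 1, b[k + 1])
      assign(key, TRUE, envir = seen)
    }
  }
  keys <- ls(seen)
  out <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  out <- out[!(out[, 1] == 1 & out[, 2] == L), , drop = FALSE]
  sort(sprintf("%d:%d", out[, 1], out[, 2]))
}

# All-boundary-pair oracle with explicit double loop.
pair_fragments <- function(boundaries) {
  L <- max(boundaries)
  out <- list()
  for (i in seq_along(boundaries)) {
    for (j in seq_along(boundaries)) {
      if (boundaries[i] < boundaries[j] &&
          !(boundaries[i] == 0 && boundaries[j] == L)) {
        out[[length(out) + 1]] <- c(boundaries[i] + 1, boundaries[j])
      }
    }
  }
  if (length(out) == 0) return(character(0))
  m <- do.call(rbind, out)
  sort(sprintf("%d:%d", m[, 1], m[, 2]))
}

# Hand-derived protease rule fixtures (expected cleaved bond positions).
rule_fixtures <- function() {
  list(
    list("T",  "AKA",          c(2L)),          # K not before P
    list("T",  "AKPA",         integer(0)),     # proline veto
    list("T",  "ARPA",         integer(0)),     # proline veto on R
    list("T",  "AWKP",         c(3L)),          # WKP override
    list("T",  "AMRP",         c(3L)),          # MRP override
    list("T",  "ACKDA",        integer(0)),     # Keil CKD
    list("T",  "ADKDA",        integer(0)),     # Keil DKD
    list("T",  "ACKHA",        integer(0)),     # Keil CKH
    list("T",  "ACKYA",        integer(0)),     # Keil CKY
    list("T",  "ACRK",         integer(0)),     # Keil CRK
    list("T",  "ARRHA",        c(2L)),          # RRH vetoes bond 3 only
    list("T",  "ARRRA",        c(2L, 4L)),      # RRR vetoes the middle bond
    list("T",  "AKXA",         integer(0)),     # ambiguous P1' never called
    list("E",  "AAADDDDKGGG",  c(8L)),          # acidic run then K
    list("E",  "DDDKA",        c(4L)),
    list("E",  "ADDKA",        integer(0)),     # run too short
    list("E",  "EEEKA",        c(4L)),          # E accepted in the run
    list("Th", "AGRGA",        c(3L)),          # G-R/G
    list("Th", "AARGA",        integer(0)),
    list("Th", "MAPRAA",       c(4L)),          # extended context
    list("Th", "MAPRDA",       integer(0)),     # acidic P1' veto
    list("Th", "MAPRAD",       integer(0)),     # acidic P2' veto
    list("Th", "DAPRAA",       integer(0)),     # P4 outside allowed set
    list("Pa", "AAFAA",        c(2L, 3L)),      # bonds both sides of F
    list("Pa", "AALAA",        c(2L, 3L)),
    list("Pa", "AAWAA",        integer(0)),     # W only above pH 2
    list("Pa", "FAAAA",        c(1L)),
    list("Pb", "AAWAA",        c(2L, 3L)),
    list("Pb", "AAYAA",        c(2L, 3L)),
    list("CT", "AMA",          c(2L)),          # low specificity: M
    list("CT", "AMYA",         c(3L)),          # M before Y vetoed; Y cleaves
    list("CT", "AHA",          c(2L)),          # low specificity: H
    list("CT", "AHDA",         integer(0)),     # H before D vetoed
    list("CT", "ALA",          c(2L))           # low specificity: L
  )
}

# Small scored fixture for ranking tests.
random_scored <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      peptide = replicate(n, paste(sample(LETTERS[1:20], 8, replace = TRUE),
                                   collapse = "")),
      css = 100 / (1 + rpois(n, 5)),
      pv = runif(n, 0.05, 0.3),
      decay = rlnorm(n, 0, 1)
    )
  })
}
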