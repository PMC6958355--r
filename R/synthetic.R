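#' Configuration for the synthetic proteome generator
#'
#' The generator emulates the structure the pipeline is built to mine:
#' proteome sets of a few hundred proteins whose sequences are inert
#' background except for planted antimicrobial-like stretches (cationic,
#' low-propensity runs of 12-43 residues) with controlled pepsin-cleavable
#' flanks, so that every pipeline stage can be checked against exact
#' ground truth.
#'
#' @param n_proteomes Number of proteome sets (default 6, labelled like
#'   the milk-whey/cheese study sets CP, S, Ch, K, M, F).
#' @param proteome_names Optional labels (length `n_proteomes`).
#' @param proteins_per_proteome Proteins per set (default 500; study
#'   proteomes ranged roughly 490-690).
#' @param length_meanlog,length_sdlog Log-normal protein length
#'   parameters (defaults `log(250)` and 0.45).
#' @param plant_rate Expected planted stretches per protein (Poisson;
#'   default 1).
#' @param plant_length Inclusive stretch length range, within [12, 43].
#' @param overhang_mode `"exact"` (pepsin sites exactly at stretch
#'   boundaries), `"jitter"` (0-2 residue overhangs sampled per side) or
#'   `"reject"` (sites forced 3 residues out, so no admissible match).
#' @param share_prob Probability that a protein is copied into each other
#'   proteome (whole-protein sharing drives cross-set overlaps).
#' @param background_freqs Optional named sampling weights for background
#'   residues (restricted to the high-propensity background pool).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(n_proteomes = 6, proteome_names = NULL,
                             proteins_per_proteome = 500,
                             length_meanlog = log(250), length_sdlog = 0.45,
                             plant_rate = 1, plant_length = c(12, 43),
                             overhang_mode = c("exact", "jitter", "reject"),
                             share_prob = 0.15, background_freqs = NULL,
                             seed = 1) {
  overhang_mode <- match.arg(overhang_mode)
  if (is.null(proteome_names)) {
    proteome_names <- if (n_proteomes == 6) {
      c("CP", "S", "Ch", "K", "M", "F")
    } else {
      paste0("Set", seq_len(n_proteomes))
    }
  }
  if (length(proteome_names) != n_proteomes) {
    abort("`proteome_names` must have length `n_proteomes`.")
  }
  if (plant_length[1] < 12 || plant_length[2] > 43 ||
      plant_length[1] > plant_length[2]) {
    abort("`plant_length` must be an increasing range within [12, 43].")
  }
  if (share_prob < 0 || share_prob > 1) {
    abort("`share_prob` must be a probability.")
  }
  if (plant_rate < 0) abort("`plant_rate` must be >= 0.")
  if (length_sdlog <= 0) abort("`length_sdlog` must be > 0.")
  structure(
    list(
      n_proteomes = as.integer(n_proteomes),
      proteome_names = proteome_names,
      proteins_per_proteome = as.integer(proteins_per_proteome),
      length_meanlog = length_meanlog, length_sdlog = length_sdlog,
      plant_rate = plant_rate,
      plant_length = as.integer(plant_length),
      overhang_mode = overhang_mode,
      share_prob = share_prob,
      background_freqs = background_freqs,
      seed = as.integer(seed)
    ),
    class = "synthesis_config"
  )
}

# Residue pools for the generator, derived from the scan scale so the
# planted design provably interacts with the propensity threshold:
#  - edge residues (M, plus F when a terminal pepsin site is wanted) sit
#    just below the threshold, so windows straddling a plant boundary
#    fail once one flank residue (D/E, far above threshold) enters;
#  - interior residues are any low-propensity letters other than the
#    pepsin targets F/L, keeping plant interiors free of stray sites;
#  - background residues all sit comfortably above the threshold, so the
#    background can never host a qualifying window run.
generator_pools <- function(scale) {
  v <- scale$values
  th <- scale$threshold
  pools <- list(
    edge = "M", edge_site = "F", flank_fill = c("D", "E"),
    flank_site = "L",
    interior = setdiff(names(v)[v < th], c("F", "L")),
    background = names(v)[v >= th + 0.02]
  )
  worst_edge6 <- v["F"] + 5 * v["M"]
  need_fill <- scale$window * th - worst_edge6
  feasible <- v["M"] < th && v["F"] < th && v["L"] >= th &&
    all(v[pools$flank_fill] >= need_fill) &&
    length(pools$interior) >= 3 && length(pools$background) >= 5
  if (!feasible) {
    abort(paste(
      "The supplied scale cannot support the planted-stretch design",
      "(edge/flank residue propensities do not bracket the threshold)."
    ))
  }
  pools
}

sample_overhang <- function(mode) {
  switch(mode,
         exact = 0L,
         jitter = sample(0:2, 1),
         reject = 3L)
}

build_plant <- function(m, j_n, j_c, pools, interior_w) {
  left <- c(if (j_n == 0L) pools$edge_site else pools$edge,
            rep(pools$edge, 5))
  right <- c(rep(pools$edge, 5),
             if (j_c == 0L) pools$edge_site else pools$edge)
  mid <- if (m > 12) {
    sample(pools$interior, m - 12, replace = TRUE, prob = interior_w)
  } else character(0)
  c(left, mid, right)
}

# Flank zones are 7 residues of D/E; the pepsin trigger L is placed so the
# nearest admissible fragment boundary realises the intended overhang
# (cleavage occurs on both sides of an L, hence the offset bookkeeping).
build_left_zone <- function(j_n, pools) {
  zone <- sample(pools$flank_fill, 7, replace = TRUE)
  if (j_n >= 1L) zone[7L - j_n] <- pools$flank_site
  zone
}

build_right_zone <- function(j_c, pools) {
  zone <- sample(pools$flank_fill, 7, replace = TRUE)
  if (j_c >= 1L) zone[j_c + 1L] <- pools$flank_site
  zone
}

generate_protein <- function(config, pools, interior_w, bg_w, scale) {
  n_plants <- rpois(1, config$plant_rate)
  plants <- purrr::map(seq_len(n_plants), function(i) {
    lens <- config$plant_length[1]:config$plant_length[2]
    m <- if (length(lens) == 1L) lens else sample(lens, 1)
    j_n <- sample_overhang(config$overhang_mode)
    j_c <- sample_overhang(config$overhang_mode)
    list(m = m, j_n = j_n, j_c = j_c)
  })
  module_len <- vapply(plants, function(p) p$m + 14L, integer(1))
  for (attempt in seq_len(20)) {
    target <- round(rlnorm(1, config$length_meanlog, config$length_sdlog))
    bg_total <- max(target - sum(module_len), (n_plants + 1L) * 7L)
    extra <- bg_total - (n_plants + 1L) * 7L
    gaps <- rep(7L, n_plants + 1L)
    if (extra > 0 && n_plants >= 0) {
      add <- tabulate(sample.int(n_plants + 1L, extra, replace = TRUE),
                      nbins = n_plants + 1L)
      gaps <- gaps + add
    }
    pieces <- character(0)
    starts <- integer(n_plants)
    ends <- integer(n_plants)
    pos <- 0L
    for (i in seq_len(n_plants + 1L)) {
      bg <- sample(pools$background, gaps[i], replace = TRUE, prob = bg_w)
      pieces <- c(pieces, bg)
      pos <- pos + gaps[i]
      if (i <= n_plants) {
        p <- plants[[i]]
        zone_l <- build_left_zone(p$j_n, pools)
        plant <- build_plant(p$m, p$j_n, p$j_c, pools, interior_w)
        zone_r <- build_right_zone(p$j_c, pools)
        pieces <- c(pieces, zone_l, plant, zone_r)
        starts[i] <- pos + 8L
        ends[i] <- pos + 7L + p$m
        pos <- pos + 14L + p$m
      }
    }
    sequence <- paste(pieces, collapse = "")
    called <- call_stretches(sequence, scale)
    if (nrow(called) == n_plants &&
        identical(called$start, starts) && identical(called$end, ends)) {
      truth <- if (n_plants == 0) NULL else tibble(
        start = starts, end = ends,
        sequence = substring(sequence, starts, ends),
        pv = called$pv,
        planned_n_overhang = vapply(plants, `[[`, integer(1), "j_n"),
        planned_c_overhang = vapply(plants, `[[`, integer(1), "j_c")
      )
      return(list(sequence = sequence, truth = truth))
    }
  }
  abort("Failed to generate a background free of spurious stretches.")
}

#' Generate synthetic proteome sets with planted antimicrobial stretches
#'
#' Every plant is a low-propensity stretch whose boundaries the scan is
#' guaranteed to call exactly (verified by running the scan during
#' generation; a clash triggers resampling of the background), flanked by
#' acidic spacer zones carrying pepsin (pH < 1.8) sites at the positions
#' dictated by `overhang_mode`. Whole proteins are optionally copied
#' between proteomes to create realistic cross-set sharing.
#'
#' @param config A [synthesis_config()].
#' @param scale The [propensity_scale()] the downstream scan will use.
#' @return A list of class `amp_simulation` with elements `proteins`
#'   (tibble: `proteome`, `id`, `description`, `sequence`), `truth`
#'   (tibble: `proteome`, `parent_id`, `start`, `end`, `sequence`, `pv`,
#'   `planned_n_overhang`, `planned_c_overhang`, `shared_from`) and
#'   `config`.
#' @examples
#' sim <- simulate_proteomes(synthesis_config(
#'   n_proteomes = 2, proteins_per_proteome = 5, seed = 7
#' ))
#' sim$truth
#' @export
simulate_proteomes <- function(config, scale = propensity_scale()) {
  stopifnot(inherits(config, "synthesis_config"))
  pools <- generator_pools(scale)
  interior_w <- ifelse(pools$interior %in% c("K", "R"), 3, 1)
  bg_w <- if (is.null(config$background_freqs)) {
    rep(1, length(pools$background))
  } else {
    w <- config$background_freqs[pools$background]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) abort("`background_freqs` excludes the whole pool.")
    w
  }
  withr::with_seed(config$seed, {
    own <- purrr::map(seq_len(config$n_proteomes), function(s) {
      pname <- config$proteome_names[s]
      recs <- purrr::map(seq_len(config$proteins_per_proteome), function(k) {
        g <- generate_protein(config, pools, interior_w, bg_w, scale)
        id <- sprintf("%s_%04d", pname, k)
        truth <- g$truth
        if (!is.null(truth)) {
          truth$parent_id <- id
        }
        list(
          protein = tibble(
            proteome = pname, id = id,
            description = sprintf("synthetic protein %d of set %s", k, pname),
            sequence = g$sequence
          ),
          truth = truth
        )
      })
      list(
        proteins = purrr::map_dfr(recs, "protein"),
        truth = purrr::map_dfr(recs, function(r) {
          if (is.null(r$truth)) return(NULL)
          dplyr::mutate(r$truth, proteome = pname, shared_from = NA_character_)
        })
      )
    })
    proteins <- purrr::map_dfr(own, "proteins")
    truth <- purrr::map_dfr(own, "truth")

    if (config$share_prob > 0 && config$n_proteomes > 1) {
      shared_p <- list()
      shared_t <- list()
      for (s in config$proteome_names) {
        donors <- proteins[proteins$proteome == s, ]
        for (t in setdiff(config$proteome_names, s)) {
          take <- runif(nrow(donors)) < config$share_prob
          if (!any(take)) next
          cp <- donors[take, ]
          cp$proteome <- t
          shared_p[[length(shared_p) + 1L]] <- cp
          tr <- truth[truth$proteome == s & truth$parent_id %in% cp$id, ]
          if (nrow(tr) > 0) {
            tr$proteome <- t
            tr$shared_from <- s
            shared_t[[length(shared_t) + 1L]] <- tr
          }
        }
      }
      proteins <- dplyr::bind_rows(proteins, shared_p)
      truth <- dplyr::bind_rows(truth, shared_t)
    }
    truth <- if (nrow(truth) > 0) {
      dplyr::select(truth, "proteome", "parent_id", "start", "end",
                    "sequence", "pv", "planned_n_overhang",
                    "planned_c_overhang", "shared_from") |>
        dplyr::arrange(.data$proteome, .data$parent_id, .data$start)
    } else {
      tibble(
        proteome = character(0), parent_id = character(0),
        start = integer(0), end = integer(0), sequence = character(0),
        pv = numeric(0), planned_n_overhang = integer(0),
        planned_c_overhang = integer(0), shared_from = character(0)
      )
    }
    structure(
      list(proteins = dplyr::arrange(proteins, .data$proteome, .data$id),
           truth = truth, config = config),
      class = "amp_simulation"
    )
  })
}

#' @export
print.amp_simulation <- function(x, ...) {
  cat(sprintf(
    "<amp_simulation> %d proteome(s), %d protein record(s), %d planted stretch(es), mode '%s', seed %d\n",
    length(unique(x$proteins$proteome)), nrow(x$proteins), nrow(x$truth),
    x$config$overhang_mode, x$config$seed
  ))
  invisible(x)
}

#' Draw synthetic half-lives for a peptide set
#'
#' Half-lives are drawn from a log-normal distribution (the skewed shape
#' typical of empirical peptide half-life data), one value per distinct
#' peptide, deterministically for a given seed. The table plugs directly
#' into [half_life_provider()].
#'
#' @param peptides Character vector or data frame with a `peptide` column.
#' @param meanlog,sdlog Log-normal parameters of the half-life in
#'   seconds (defaults -0.5 and 1, centring the decay rate near the
#'   ~1/s scale typical of unprotected peptides in intestinal extracts).
#'   `sdlog = 0` degenerates to the constant `exp(meanlog)`.
#' @param seed Integer seed.
#' @return Tibble `peptide`, `tau` (seconds).
#' @export
assign_half_lives <- function(peptides, meanlog = -0.5, sdlog = 1,
                              seed = 1) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  if (sdlog < 0) abort("`sdlog` must be >= 0.")
  peptides <- unique(peptides)
  withr::with_seed(as.integer(seed), {
    tibble(peptide = peptides,
           tau = rlnorm(length(peptides), meanlog, sdlog))
  })
}
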