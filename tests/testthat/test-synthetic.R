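small_config <- function(mode, seed = 42, n = 15, sets = 1,
                         share = 0) {
  synthesis_config(
    n_proteomes = sets, proteins_per_proteome = n,
    overhang_mode = mode, share_prob = share, seed = seed,
    length_meanlog = log(150), length_sdlog = 0.3
  )
}

test_that("generation is deterministic given the config seed", {
  a <- simulate_proteomes(small_config("jitter", seed = 9))
  b <- simulate_proteomes(small_config("jitter", seed = 9))
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth, b$truth)
  c <- simulate_proteomes(small_config("jitter", seed = 10))
  expect_false(identical(a$proteins$sequence, c$proteins$sequence))
})

test_that("a zero plant rate yields proteomes with no stretches at all", {
  cfg <- synthesis_config(n_proteomes = 1, proteins_per_proteome = 10,
                          plant_rate = 0, seed = 4)
  sim <- simulate_proteomes(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(scan_proteome(sim$proteins)), 0L)
})

test_that("the scan recovers planted stretches exactly, with no extras", {
  sim <- simulate_proteomes(small_config("exact", seed = 12))
  st <- scan_proteome(sim$proteins)
  expect_equal(nrow(st), nrow(sim$truth))
  key <- function(d) sort(paste(d$parent_id, d$start, d$end))
  expect_equal(key(st), key(sim$truth))
  expect_true(all(st$length >= 12 & st$length <= 43))
})

test_that("exact mode releases every plant as an exact fragment match", {
  sim <- simulate_proteomes(small_config("exact", seed = 23))
  st <- scan_proteome(sim$proteins)
  fr <- digest_proteome(sim$proteins)
  m <- match_amps(fr, st)
  expect_equal(nrow(m), nrow(sim$truth))
  expect_true(all(m$exact))
  # matched fragment sequences are the planted sequences themselves
  expect_setequal(unique(m$peptide), unique(sim$truth$sequence))
})

test_that("jitter mode recovers every plant within the overhang margin", {
  sim <- simulate_proteomes(small_config("jitter", seed = 31))
  st <- scan_proteome(sim$proteins)
  fr <- digest_proteome(sim$proteins)
  m <- match_amps(fr, st)
  matched <- unique(paste(m$parent_id, m$stretch_start, m$stretch_end))
  planted <- unique(paste(sim$truth$parent_id, sim$truth$start,
                          sim$truth$end))
  expect_setequal(matched, planted)
  # the planned overhang is realised by some released fragment
  by_plant <- dplyr::group_by(m, .data$parent_id, .data$stretch_start)
  mins <- dplyr::summarise(by_plant,
                           n_min = min(.data$n_overhang),
                           c_min = min(.data$c_overhang),
                           .groups = "drop")
  truth <- dplyr::arrange(sim$truth, .data$parent_id, .data$start)
  mins <- dplyr::arrange(mins, .data$parent_id, .data$stretch_start)
  expect_equal(mins$n_min, truth$planned_n_overhang)
  expect_equal(mins$c_min, truth$planned_c_overhang)
})

test_that("reject mode leaves no admissible matches", {
  sim <- simulate_proteomes(small_config("reject", seed = 8))
  st <- scan_proteome(sim$proteins)
  expect_gt(nrow(st), 0)
  fr <- digest_proteome(sim$proteins)
  m <- match_amps(fr, st)
  expect_equal(nrow(m), 0L)
})

test_that("protein sharing copies whole records across proteomes", {
  sim <- simulate_proteomes(small_config("exact", seed = 6, n = 20,
                                         sets = 3, share = 0.3))
  dup <- sim$proteins |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1)
  expect_gt(nrow(dup), 0)
  # per-proteome ids stay unique
  per <- sim$proteins |>
    dplyr::count(.data$proteome, .data$id) |>
    dplyr::filter(.data$n > 1)
  expect_equal(nrow(per), 0L)
  # shared plants are recorded with their origin
  expect_true(any(!is.na(sim$truth$shared_from)))
})

test_that("synthetic half-lives are deterministic and log-normal", {
  peps <- replicate(1000, random_seq(10, c("K", "R", "M", "G")))
  peps <- unique(peps)
  a <- assign_half_lives(peps, seed = 3)
  b <- assign_half_lives(peps, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$tau > 0))

  # degenerate sdlog collapses to the constant exp(meanlog)
  d <- assign_half_lives(peps[1:5], meanlog = 1.5, sdlog = 0, seed = 1)
  expect_equal(d$tau, rep(exp(1.5), 5))

  # mean of log tau within 3 standard errors of meanlog
  mu <- -0.5; sdl <- 1
  hl <- assign_half_lives(peps, meanlog = mu, sdlog = sdl, seed = 11)
  se <- sdl / sqrt(nrow(hl))
  expect_lt(abs(mean(log(hl$tau)) - mu), 3 * se)
})

test_that("invalid configurations are rejected up front", {
  expect_error(synthesis_config(plant_length = c(10, 43)), "plant_length")
  expect_error(synthesis_config(plant_length = c(12, 50)), "plant_length")
  expect_error(synthesis_config(share_prob = 1.5), "probability")
  expect_error(synthesis_config(plant_rate = -1), "plant_rate")
  expect_error(synthesis_config(n_proteomes = 2,
                                proteome_names = "only-one"),
               "proteome_names")
})
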