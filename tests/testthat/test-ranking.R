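test_that("max-normalisation maps positives onto (0, 1]", {
  expect_equal(normalize_max(c(2, 4)), c(0.5, 1))
  expect_equal(normalize_max(7), 1)
  withr::with_seed(2, {
    x <- rlnorm(50)
    perm <- sample(50)
    expect_equal(normalize_max(x)[perm], normalize_max(x[perm]))
  })
  expect_error(normalize_max(numeric(0)), "empty")
  expect_error(normalize_max(c(1, 0)), "positive")
  expect_error(normalize_max(c(1, -2)), "positive")
})

test_that("CAS ranking follows the normalised score and its tie rules", {
  single <- rank_amps(tibble::tibble(peptide = "KKKK", css = 50,
                                     pv = 0.2, decay = 1))
  expect_equal(single$css_bar, 1)
  expect_equal(single$pv_bar, 1)
  expect_equal(single$d_bar, 1)
  expect_equal(single$cas, 1)
  expect_equal(single$rank, 1L)

  # halving the decay of one of two otherwise equal peptides ranks it first
  two <- rank_amps(tibble::tibble(
    peptide = c("AAAA", "CCCC"), css = c(50, 50),
    pv = c(0.2, 0.2), decay = c(2, 1)
  ))
  expect_equal(two$peptide[two$rank == 1], "CCCC")
  expect_gt(two$cas[two$rank == 1], two$cas[two$rank == 2])
})

test_that("ranking equals an independent unnormalised-ratio oracle", {
  scored <- random_scored(200, seed = 77)
  r <- rank_amps(scored)
  # CAS is scale-invariant, so ranking by css/(pv*decay) with the same
  # tie-break must give the identical permutation.
  oracle <- scored[order(-(scored$css / (scored$pv * scored$decay)),
                         -scored$css, scored$peptide), ]
  expect_equal(r$peptide, oracle$peptide)
  expect_equal(r$rank, seq_len(nrow(scored)))
  # every normalised column attains its maximum of exactly 1
  expect_equal(max(r$css_bar), 1)
  expect_equal(max(r$pv_bar), 1)
  expect_equal(max(r$d_bar), 1)
})

test_that("CAS values and ranks are invariant to rescaling any input", {
  scored <- random_scored(150, seed = 13)
  base <- rank_amps(scored)
  for (col in c("css", "pv", "decay")) {
    tweaked <- scored
    tweaked[[col]] <- tweaked[[col]] * 7
    r2 <- rank_amps(tweaked)
    expect_equal(r2$peptide, base$peptide)
    expect_equal(r2$cas, base$cas)
  }
})

test_that("a low-propensity peptide can still rank poorly via fast decay", {
  scored <- random_scored(100, seed = 19)
  best_pv <- which.min(scored$pv)
  scored$decay[best_pv] <- max(scored$decay) * 50
  r <- rank_amps(scored)
  expect_gt(r$rank[r$peptide == scored$peptide[best_pv]], 50)
})

test_that("ranking validates its inputs", {
  expect_error(rank_amps(tibble::tibble(peptide = "K", css = 1, pv = 0.1)),
               "decay")
  bad <- tibble::tibble(peptide = c("K", "R"), css = c(10, 10),
                        pv = c(0.1, -0.1), decay = c(1, 1))
  expect_error(rank_amps(bad), "R")
})

test_that("top-N selection reports the cutoff and respects n", {
  scored <- random_scored(50, seed = 5)
  r <- rank_amps(scored)
  t10 <- top_amps(r, 10)
  expect_equal(nrow(t10), 10)
  expect_equal(attr(t10, "cutoff_cas"), min(t10$cas))
  expect_equal(t10$peptide, r$peptide[1:10])
  expect_equal(nrow(top_amps(r, 500)), 50)
  expect_equal(top_amps(r, 1)$peptide, r$peptide[1])
  expect_error(top_amps(r, 0), "n")
})

test_that("per-proteome summaries match hand-computed means", {
  scored <- tibble::tibble(
    peptide = c("K1", "K2", "K3", "K4", "K5"),
    css = c(100, 50, 25, 20, 10),
    pv = c(0.1, 0.2, 0.1, 0.25, 0.05),
    decay = c(1, 2, 0.5, 1, 4),
    proteomes = list("A", c("A", "B"), "B", "B", c("A", "B"))
  )
  r <- rank_amps(scored)
  s <- proteome_summary(r, proteome_sizes = c(A = 10, B = 20))
  a <- s$proteomes[s$proteomes$proteome == "A", ]
  in_a <- r[purrr::map_lgl(r$proteomes, ~ "A" %in% .x), ]
  expect_equal(a$n_amps, 3L)
  expect_equal(a$ratio, 3 / 10)
  expect_equal(a$mean_css, mean(in_a$css))
  expect_equal(a$mean_pv, mean(in_a$pv))
  expect_equal(a$mean_cas, mean(in_a$cas))
  expect_equal(a$n_unique, 1L)
  pair_ab <- s$pairwise$n_common[s$pairwise$proteome_a == "A" &
                                   s$pairwise$proteome_b == "B"]
  expect_equal(pair_ab, 2L)
  expect_equal(s$common_all, 2L)
})

test_that("tidy and glance expose the ranking as plain tables", {
  r <- rank_amps(random_scored(30, seed = 3))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "amp_ranking"))
  expect_true(all(c("rank", "peptide", "cas") %in% names(td)))
  g <- glance(r)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_peptides, 30)
  expect_equal(g$top_cas, max(r$cas))
})
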