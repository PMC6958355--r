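test_that("FASTA parsing preserves records, ids and order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKF", ">P2", "AAA"), fa)
  ps <- read_proteome_fasta(fa, name = "demo")
  expect_equal(ps$id, c("P1", "P2"))
  expect_equal(ps$sequence, c("MKF", "AAA"))
  expect_equal(ps$description, c("some description", ""))
  expect_equal(ps$proteome, c("demo", "demo"))

  # wrapped sequence lines are accepted
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">W1", "MKFA", "GGG", ">W2", "CCC"), fa2)
  ps2 <- read_proteome_fasta(fa2)
  expect_equal(ps2$sequence, c("MKFAGGG", "CCC"))

  # a large entry count is preserved exactly
  n <- 489
  fa3 <- withr::local_tempfile(fileext = ".fasta")
  withr::with_seed(11, {
    writeLines(unlist(lapply(seq_len(n), function(i) {
      c(sprintf(">sp|Q%05d|SYN", i), random_seq(30, LETTERS[c(1, 3, 4)]))
    })), fa3)
  })
  expect_equal(nrow(read_proteome_fasta(fa3)), n)
})

test_that("malformed FASTA is rejected with a useful message", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKF", ">P1", "AAA"), fa)
  expect_error(read_proteome_fasta(fa), "line 1")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKF", ">P1", "AAA"), dup)
  expect_error(read_proteome_fasta(dup), "Duplicate.*P1")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_proteome_fasta(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MK1F"), bad)
  expect_error(read_proteome_fasta(bad), "alphabet")
})

test_that("ambiguity letters are flagged and counted, never dropped", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKXFZAA", ">P2", "AAAA"), fa)
  expect_warning(ps <- read_proteome_fasta(fa), "ambiguity")
  expect_equal(ps$n_ambiguous, c(2L, 0L))
  expect_equal(nchar(ps$sequence[1]), 7L)
})

test_that("FASTA round-trip preserves ids and sequences exactly", {
  withr::with_seed(5, {
    prot <- tibble::tibble(
      id = sprintf("sp|ACC%d|NAME", 1:20),
      description = ifelse(1:20 %% 2 == 0, "desc text", ""),
      sequence = replicate(20, random_seq(sample(10:80, 1),
                                          ampsieve:::AA_STANDARD))
    )
  })
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(prot, fa)
  back <- read_proteome_fasta(fa)
  expect_equal(back$id, prot$id)
  expect_equal(back$sequence, prot$sequence)
})

test_that("unique_sequences maps each sequence to its proteome sets", {
  prot <- tibble::tibble(
    proteome = c("A", "A", "B", "B"),
    id = c("a1", "a2", "b1", "b2"),
    sequence = c("MKF", "CCC", "MKF", "DDD")
  )
  u <- unique_sequences(prot)
  expect_equal(nrow(u), 3)
  expect_equal(u$proteomes[u$sequence == "MKF"][[1]], c("A", "B"))
  expect_equal(u$n_proteomes[u$sequence == "MKF"], 2L)

  # disjoint sets of sizes 3 and 4 give 7 keys
  prot2 <- tibble::tibble(
    proteome = rep(c("A", "B"), c(3, 4)),
    id = paste0("p", 1:7),
    sequence = c("AAA", "CCC", "DDD", "EEE", "FFF", "GGG", "HHH")
  )
  expect_equal(nrow(unique_sequences(prot2)), 7)
})

test_that("unique_sequences agrees with brute-force pairwise comparison", {
  withr::with_seed(21, {
    prot <- tibble::tibble(
      proteome = sample(c("A", "B", "C"), 60, replace = TRUE),
      id = paste0("p", 1:60),
      sequence = replicate(60, random_seq(4, c("M", "K")))
    )
  })
  u <- unique_sequences(prot)
  # brute force: loop over distinct sequences and sets
  for (s in unique(prot$sequence)) {
    expected <- sort(unique(prot$proteome[prot$sequence == s]))
    expect_equal(u$proteomes[u$sequence == s][[1]], expected)
  }
  expect_lte(nrow(u), nrow(prot))
  all_distinct <- !anyDuplicated(prot$sequence)
  expect_equal(nrow(u) == nrow(prot), as.logical(all_distinct))
})

test_that("write_table emits headers and 4 significant digits", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_table(tibble::tibble(a = character(0), b = numeric(0)), tmp)
  expect_equal(length(readLines(tmp)), 1L)

  write_table(tibble::tibble(a = c("x", "y", "z"),
                             b = c(1.23456789, 2, 3.1)), tmp)
  lines <- readLines(tmp)
  expect_equal(length(lines), 4L)
  expect_match(lines[2], "1\\.235")

  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(back$b, signif(c(1.23456789, 2, 3.1), 4))
})
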