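#' Run the whole peptide-mining pipeline
#'
#' Executes the stages scan -> digest -> match -> dedupe -> stability ->
#' rank -> summarise, writing every intermediate table to `out_dir` as
#' TSV (so each stage is independently auditable) together with a JSON
#' manifest recording parameter values, resource-file checksums and
#' per-stage record counts. Outputs are deterministic: running the same
#' configuration twice yields byte-identical files.
#'
#' @param proteins Tibble of protein records (`proteome`, `id`,
#'   `sequence`), e.g. from [read_proteome_sets()] or
#'   [simulate_proteomes()]; alternatively pass `fasta`.
#' @param fasta Named character vector of FASTA paths (names = proteome
#'   labels), used when `proteins` is `NULL`.
#' @param out_dir Output directory (created if missing).
#' @param scale A [propensity_scale()].
#' @param rules A [cleavage_rules()] table.
#' @param min_len,max_len Fragment length window (defaults 12 and 47).
#' @param max_overhang Matching overhang margin (default 2).
#' @param half_lives Half-life source for [half_life_provider()]; `NULL`
#'   uses the stub (flagged in the outputs).
#' @param allow_stub_fallback Fall back to the stub for peptides missing
#'   from the half-life table.
#' @param top_n Size of the reported top set (default 100).
#' @param properties Append physicochemical descriptors to the ranked
#'   table (default TRUE).
#' @return Invisibly, a list of class `amp_pipeline` with `counts`,
#'   `files`, `ranking`, `top`, `summary`, `manifest`.
#' @export
run_pipeline <- function(proteins = NULL, fasta = NULL, out_dir,
                         scale = propensity_scale(),
                         rules = cleavage_rules(),
                         min_len = 12, max_len = 47, max_overhang = 2,
                         half_lives = NULL, allow_stub_fallback = FALSE,
                         top_n = 100, properties = TRUE) {
  if (is.null(proteins)) {
    if (is.null(fasta)) abort("Supply `proteins` or `fasta`.")
    proteins <- read_proteome_sets(fasta)
  }
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (!"proteome" %in% names(proteins)) proteins$proteome <- "all"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s",
                    name, conditionMessage(e)))
    })
    message(sprintf("stage %-10s %7d records", name, nrow(res)))
    res
  }

  write_table(dplyr::select(proteins, -dplyr::any_of("sequence")) |>
                dplyr::mutate(length = nchar(proteins$sequence)),
              path("01_proteins.tsv"))

  stretches <- stage("scan", function() scan_proteome(proteins, scale))
  write_table(stretches, path("02_stretches.tsv"))

  fragments <- stage("digest", function() {
    digest_proteome(proteins, rules, min_len = min_len, max_len = max_len)
  })
  write_table(fragments, path("03_fragments.tsv"))

  matches <- stage("match", function() {
    match_amps(fragments, stretches, max_overhang = max_overhang)
  })
  write_table(matches, path("04_matches.tsv"))

  selected <- stage("dedupe", function() dedupe_amps(matches))

  scored <- stage("stability", function() {
    score_stability(dplyr::select(selected, -"witnesses"), rules,
                    half_lives = half_lives,
                    allow_stub_fallback = allow_stub_fallback)
  })
  write_table(scored, path("05_peptides.tsv"))

  ranking <- stage("rank", function() rank_amps(scored))
  ranked_out <- tidy(ranking)
  if (properties && nrow(ranked_out) > 0) {
    ranked_out <- dplyr::left_join(
      ranked_out, peptide_properties(ranking$peptide), by = "peptide"
    )
  }
  write_table(ranked_out, path("06_ranked.tsv"))

  top <- top_amps(ranking, n = top_n)
  write_table(tidy(top), path("07_top.tsv"))

  sizes <- table(proteins$proteome)
  summ <- proteome_summary(ranking,
                           proteome_sizes = setNames(as.integer(sizes),
                                                     names(sizes)))
  write_table(summ$proteomes, path("08_summary_proteomes.tsv"))
  write_table(summ$pairwise, path("09_pairwise_overlap.tsv"))

  counts <- c(
    proteins = nrow(proteins), stretches = nrow(stretches),
    fragments = nrow(fragments), matches = nrow(matches),
    selected = nrow(selected), ranked = nrow(ranking)
  )
  manifest <- list(
    package = "ampsieve",
    version = as.character(utils::packageVersion("ampsieve")),
    parameters = list(
      scale = scale$name, window = scale$window,
      threshold = scale$threshold, min_stretch = scale$min_stretch,
      chymotrypsin = attr(rules, "chymotrypsin"),
      min_len = min_len, max_len = max_len, max_overhang = max_overhang,
      half_life_source = if (is.null(half_lives)) "stub" else "table",
      top_n = top_n
    ),
    resources = as.list(tools::md5sum(c(
      scale = system.file("extdata", "ampa_propensity_scale.tsv",
                          package = "ampsieve"),
      rules = attr(rules, "source")
    ))),
    counts = as.list(counts)
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  out <- structure(
    list(counts = counts,
         files = list.files(out_dir, full.names = TRUE),
         ranking = ranking, top = top, summary = summ,
         manifest = manifest),
    class = "amp_pipeline"
  )
  invisible(out)
}

#' @export
print.amp_pipeline <- function(x, ...) {
  cat("<amp_pipeline>\n")
  print(x$counts)
  invisible(x)
}

#' @export
glance.amp_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(as.list(x$counts)),
    tibble(top_cas = max(x$ranking$cas),
           cutoff_cas = attr(x$top, "cutoff_cas"))
  )
}
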