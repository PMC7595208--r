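#' Read a STAR splice-junction table (SJ.out.tab dialect)
#'
#' Nine tab-separated columns, no header: chrom, intron start (1-based),
#' intron end (1-based inclusive), strand code (0 undefined, 1 `+`, 2 `-`),
#' motif code (0 non-canonical, 1 GT/AG, 2 CT/AC, 3 GC/AG, 4 CT/GC,
#' 5 AT/AC, 6 GT/AT), annotated flag (0/1), uniquely-mapping read count,
#' multimapping read count, maximum spliced overhang. Plain or gzipped.
#'
#' Coordinates are converted to the package's 0-based half-open convention;
#' strand-code-0 junctions are kept as `strand = "*"` — lossless reading,
#' filtering decides their fate later.
#'
#' @param path Path to an SJ.out.tab-style file.
#' @return A tibble with columns `chrom`, `donor_start`, `acceptor_end`,
#'   `strand`, `motif`, `annotated`, `unique_reads`, `multimapping_reads`,
#'   `max_overhang`.
#' @export
read_star_sj <- function(path) {
  cols <- c("chrom", "start1", "end1", "strand_code", "motif_code",
            "annotated", "unique_reads", "multimapping_reads", "max_overhang")
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = cols, col_types = readr::cols(
      chrom = readr::col_character(),
      .default = readr::col_integer()
    ))
  )
  probs <- readr::problems(raw)
  if (nrow(raw) > 0 && ncol(raw) != 9) {
    stop("expected 9 tab-separated columns in ", path, " (malformed file)",
         call. = FALSE)
  }
  if (nrow(probs) > 0 || (nrow(raw) > 0 && any(!complete.cases(raw)))) {
    line <- if (nrow(probs) > 0) probs$row[1] else which(!complete.cases(raw))[1]
    stop("malformed junction line ", line, " in ", path, call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      chrom = character(), donor_start = integer(), acceptor_end = integer(),
      strand = character(), motif = character(), annotated = logical(),
      unique_reads = integer(), multimapping_reads = integer(),
      max_overhang = integer()
    ))
  }
  if (any(raw$unique_reads < 0 | raw$multimapping_reads < 0)) {
    stop("negative read count in ", path, call. = FALSE)
  }
  if (any(raw$motif_code < 0 | raw$motif_code > 6)) {
    stop("motif code outside 0..6 in ", path, call. = FALSE)
  }
  tibble::tibble(
    chrom = raw$chrom,
    donor_start = raw$start1 - 1L,
    acceptor_end = raw$end1,
    strand = c("*", "+", "-")[raw$strand_code + 1L],
    motif = .motif_levels[raw$motif_code + 1L],
    annotated = raw$annotated == 1L,
    unique_reads = raw$unique_reads,
    multimapping_reads = raw$multimapping_reads,
    max_overhang = raw$max_overhang
  )
}

#' Write junction records in the STAR SJ.out.tab dialect
#'
#' Inverse of [read_star_sj()]; provided mainly for the simulator.
#' Missing optional columns default to 0 (`multimapping_reads`,
#' `annotated`) or a nominal overhang of 25.
#'
#' @param records Tibble as returned by [read_star_sj()].
#' @param path Output path (ends in `.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_star_sj <- function(records, path) {
  n <- nrow(records)
  get <- function(col, default) {
    if (col %in% names(records)) records[[col]] else rep(default, n)
  }
  out <- tibble::tibble(
    chrom = records$chrom,
    start1 = records$donor_start + 1L,
    end1 = records$acceptor_end,
    strand_code = match(records$strand, c("*", "+", "-")) - 1L,
    motif_code = match(records$motif, .motif_levels) - 1L,
    annotated = as.integer(get("annotated", FALSE)),
    unique_reads = records$unique_reads,
    multimapping_reads = as.integer(get("multimapping_reads", 0L)),
    max_overhang = as.integer(get("max_overhang", 25L))
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a generic per-sample junction-count TSV
#'
#' Header `chrom start_1based end_1based strand motif count`; 1-based
#' inclusive coordinates on disk, converted on read.
#'
#' @param path Path to the TSV.
#' @return Tibble with `chrom`, `donor_start`, `acceptor_end`, `strand`,
#'   `motif`, `unique_reads`.
#' @export
read_junction_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    start_1based = readr::col_integer(),
    end_1based = readr::col_integer(),
    strand = readr::col_character(),
    motif = readr::col_character(),
    count = readr::col_integer()
  ))
  if (any(raw$count < 0)) stop("negative count in ", path, call. = FALSE)
  if (any(!raw$motif %in% .motif_levels)) {
    stop("unknown motif class in ", path, call. = FALSE)
  }
  tibble::tibble(
    chrom = raw$chrom,
    donor_start = raw$start_1based - 1L,
    acceptor_end = raw$end_1based,
    strand = raw$strand,
    motif = raw$motif,
    unique_reads = raw$count
  )
}

#' Read a sample metadata table
#'
#' TSV with header `sample_id experiment disease`; `disease` must take
#' exactly the two levels `CTRL` and `FECD` (case-sensitive), `experiment`
#' is free text (e.g. `"2019"`, `"2020"`).
#'
#' @param path Path to the TSV.
#' @return Tibble `sample_id`, `experiment`, `disease`.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    experiment = readr::col_character(),
    disease = readr::col_character()
  ))
  validate_sample_meta(meta)
}

#' Validate sample metadata
#'
#' @param meta Tibble `sample_id`, `experiment`, `disease`.
#' @return The validated tibble.
#' @export
validate_sample_meta <- function(meta) {
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(meta$disease), c("CTRL", "FECD"))
  if (length(bad) > 0) {
    stop("disease must be CTRL or FECD; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  meta
}

#' Merge per-sample junction records into a long count table
#'
#' Takes one record tibble per sample and produces the union of all
#' junctions in long (tidy) form, one row per junction x sample, with
#' `count = unique_reads` for samples where the junction was observed and
#' an explicit 0 otherwise. Multimapping reads are excluded: the uniquely
#' mapped junction count is the support measure throughout.
#'
#' Per-junction `motif` is retained (taken from the first sample that
#' reports the junction; the motif is a property of the genomic sequence,
#' so samples cannot disagree on it for a genuinely identical junction).
#'
#' @param records_list Named list of per-sample record tibbles
#'   ([read_star_sj()] / [read_junction_tsv()] output), or an unnamed list
#'   plus `sample_ids`.
#' @param sample_ids Optional character vector of sample ids (defaults to
#'   `names(records_list)`).
#' @return A tibble `chrom`, `donor_start`, `acceptor_end`, `strand`,
#'   `motif`, `sample`, `count`, with every junction present for every
#'   sample.
#' @export
merge_samples <- function(records_list, sample_ids = names(records_list)) {
  if (is.null(sample_ids) || any(sample_ids == "")) {
    stop("sample ids required (name the list or pass sample_ids)",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1], call. = FALSE)
  }
  if (length(records_list) != length(sample_ids)) {
    stop("one record set per sample id required", call. = FALSE)
  }
  long <- purrr::map2_dfr(records_list, sample_ids, function(rec, id) {
    .check_junction_cols(rec, paste0("sample ", id))
    tibble::tibble(
      chrom = rec$chrom, donor_start = rec$donor_start,
      acceptor_end = rec$acceptor_end, strand = rec$strand,
      motif = rec$motif, sample = id,
      count = as.integer(rec$unique_reads)
    )
  })
  junctions <- long |>
    dplyr::distinct(.data$chrom, .data$donor_start, .data$acceptor_end,
                    .data$strand, .keep_all = TRUE) |>
    dplyr::select(dplyr::all_of(.junction_key), "motif")
  grid <- tidyr::expand_grid(
    junctions,
    sample = sample_ids
  )
  out <- grid |>
    dplyr::left_join(
      dplyr::select(long, -"motif"),
      by = c(.junction_key, "sample")
    ) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L))
  out
}
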