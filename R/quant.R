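#' Filtering thresholds for a junction dataset
#'
#' Defaults follow the locus-usage analysis convention: mitochondrial
#' junctions and non-canonical intron motifs are removed, a junction must
#' be supported by at least 6 uniquely-mapped reads summed over the whole
#' dataset to be kept genome-wide, and within the gene of interest a
#' further floor of 4 dataset-wide reads applies. Thresholds use ">= keeps"
#' semantics: a row sum exactly at the threshold is retained.
#'
#' @param min_dataset_reads_genomewide Genome-wide dataset-sum floor
#'   (default 6).
#' @param min_dataset_reads_gene In-gene dataset-sum floor (default 4).
#' @param exclude_chroms Chromosome names removed outright
#'   (default `c("chrM", "MT")`).
#' @param canonical_only Drop junctions whose intron motif is
#'   non-canonical (default `TRUE`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_dataset_reads_genomewide = 6L,
                          min_dataset_reads_gene = 4L,
                          exclude_chroms = c("chrM", "MT"),
                          canonical_only = TRUE) {
  stopifnot(min_dataset_reads_genomewide >= 0, min_dataset_reads_gene >= 0)
  structure(
    list(min_dataset_reads_genomewide = min_dataset_reads_genomewide,
         min_dataset_reads_gene = min_dataset_reads_gene,
         exclude_chroms = exclude_chroms,
         canonical_only = isTRUE(canonical_only)),
    class = "filter_config"
  )
}

.row_totals <- function(jx) {
  jx |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.junction_key))) |>
    dplyr::mutate(.row_total = sum(.data$count)) |>
    dplyr::ungroup()
}

#' Dataset-level junction filtering
#'
#' Removes junctions on excluded chromosomes, junctions with a
#' non-canonical intron motif (when `canonical_only`), and junctions whose
#' uniquely-mapped read count summed over every sample of the dataset falls
#' below the genome-wide floor. The sample set is never changed; filtering
#' drops whole junction rows.
#'
#' @param jx Long junction count table from [merge_samples()].
#' @param cfg A [filter_config()].
#' @return The filtered long table.
#' @export
filter_dataset <- function(jx, cfg = filter_config()) {
  jx |>
    .row_totals() |>
    dplyr::filter(
      !.data$chrom %in% cfg$exclude_chroms,
      !(cfg$canonical_only & .data$motif == "non-canonical"),
      .data$.row_total >= cfg$min_dataset_reads_genomewide
    ) |>
    dplyr::select(-".row_total")
}

#' Gene-level junction filtering
#'
#' Among junctions overlapping `gene_region`, removes those whose
#' dataset-wide sum is below `min_reads`; junctions outside the region are
#' untouched. Applied after [filter_dataset()] and after the normalization
#' denominator has been fixed.
#'
#' @param jx Long junction count table.
#' @param gene_region One-row tibble `chrom,start,end` (0-based half-open).
#' @param min_reads Dataset-sum floor inside the gene (default 4).
#' @return The filtered long table.
#' @export
filter_gene <- function(jx, gene_region, min_reads = 4L) {
  jx |>
    .row_totals() |>
    dplyr::filter(
      !(.data$chrom == gene_region$chrom &
          .data$donor_start < gene_region$end &
          .data$acceptor_end > gene_region$start &
          .data$.row_total < min_reads)
    ) |>
    dplyr::select(-".row_total")
}

#' Per-sample spliced-read totals
#'
#' The junctions-per-million denominator: the sum of uniquely-mapped
#' junction reads over all junctions of the table, per sample. Convention:
#' computed genome-wide after dataset-level filtering but before gene-level
#' filtering, so every spliced read that survived quality filtering counts
#' toward the library's spliced depth.
#'
#' @param jx Long junction count table.
#' @return Tibble `sample`, `total_spliced_reads`.
#' @export
spliced_totals <- function(jx) {
  jx |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total_spliced_reads = sum(.data$count), .groups = "drop")
}

#' Normalize junction counts to junctions per million spliced reads
#'
#' `jpm(j, s) = count(j, s) / total_spliced_reads(s) * 1e6`. When
#' `totals` is omitted the denominator is computed from `jx` itself, in
#' which case each sample's values sum to exactly one million.
#'
#' @param jx Long junction count table.
#' @param totals Optional denominator table from [spliced_totals()]
#'   (used when `jx` has already been gene-filtered but the denominator
#'   must reflect the pre-gene-filter population).
#' @return `jx` with the `count` column replaced by `jpm`.
#' @export
normalize_jpm <- function(jx, totals = NULL) {
  if (is.null(totals)) totals <- spliced_totals(jx)
  zero <- totals$sample[totals$total_spliced_reads <= 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero spliced-read total: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  jx |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::mutate(jpm = .data$count / .data$total_spliced_reads * 1e6) |>
    dplyr::select(-"count", -"total_spliced_reads")
}

#' Window specification for an extended exon
#'
#' An extended 5' exon arises when transcription reads directly into an
#' internal exon instead of splicing to it; it has no junction, so it is
#' quantified by reads crossing a 2-bp window immediately transcript-
#' upstream of the internal exon. "Upstream" is resolved in transcript
#' orientation: on the minus strand the window is the two bases at
#' genomically larger coordinates adjacent to the exon's genomic end,
#' `[exon_end, exon_end + 2)`; on the plus strand
#' `[exon_start - 2, exon_start)`.
#'
#' @param gene A [gene_model()].
#' @param exon_names Internal exon names to place windows on
#'   (default `c("4", "7")`).
#' @param event_names Event labels the window counts are reported under
#'   (default `c("4c", "7bII")`, the extended exons of those acceptors).
#' @return Tibble `event`, `exon`, `chrom`, `start`, `end`, `strand`.
#' @export
window_spec <- function(gene, exon_names = c("4", "7"),
                        event_names = c("4c", "7bII")) {
  stopifnot(length(exon_names) == length(event_names))
  ex <- gene$internal_exons[match(exon_names, gene$internal_exons$name), ]
  if (any(is.na(ex$name))) {
    stop("unknown internal exon in window_spec", call. = FALSE)
  }
  minus <- ex$strand == "-"
  tibble::tibble(
    event = event_names,
    exon = exon_names,
    chrom = ex$chrom,
    start = ifelse(minus, ex$end, ex$start - 2L),
    end = ifelse(minus, ex$end + 2L, ex$start),
    strand = ex$strand
  )
}

#' Count reads crossing a 2-bp window
#'
#' A read counts iff at least one of its aligned blocks covers *every*
#' position of the window. A spliced read whose intron gap spans the window
#' (one block ending at the window start, the next resuming at its end) is
#' evidence of splicing, not of exon extension, and is not counted; neither
#' is a block covering only one of the two bases.
#'
#' @param blocks Tibble of aligned blocks, one row per block:
#'   `read_id`, `chrom`, `block_start`, `block_end` (0-based half-open).
#' @param window One row of a [window_spec()] table (or any list with
#'   `chrom`, `start`, `end`).
#' @return Integer number of crossing reads.
#' @export
count_window <- function(blocks, window) {
  if (window$end - window$start != 2) {
    stop("window must be exactly 2 bp wide", call. = FALSE)
  }
  if (nrow(blocks) == 0) return(0L)
  hit <- blocks$chrom == window$chrom &
    blocks$block_start <= window$start &
    blocks$block_end >= window$end
  length(unique(blocks$read_id[hit]))
}

#' Read aligned-read blocks from a simple TSV
#'
#' Header `read_id chrom block_start block_end`, one line per aligned
#' block, 0-based half-open coordinates.
#'
#' @param path Path to the TSV.
#' @return Tibble of blocks as consumed by [count_window()].
#' @export
read_blocks_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    chrom = readr::col_character(),
    block_start = readr::col_integer(),
    block_end = readr::col_integer()
  ))
}

#' Read aligned-read blocks from a BED12 file
#'
#' Each BED12 record is one read; its blocks (blockStarts/blockSizes) are
#' expanded to the long block table consumed by [count_window()]. Requires
#' the rtracklayer package.
#'
#' @param path Path to a BED12 file.
#' @return Tibble of blocks.
#' @export
read_blocks_bed12 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_blocks_bed12 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  nb <- lengths(bl)
  flat <- as.data.frame(unlist(bl, use.names = FALSE))
  ids <- gr$name
  if (is.null(ids) || anyNA(ids)) ids <- paste0("read", seq_along(nb))
  tibble::tibble(
    read_id = rep(ids, nb),
    chrom = as.character(flat$seqnames),
    block_start = flat$start - 1L,
    block_end = flat$end
  )
}

#' Aggregate junction-level usage to events or isoform groups
#'
#' Joins the annotation onto junction-level normalized values and sums
#' member junctions per label and sample. Unannotated junctions are
#' excluded; for `by = "isoform"` rows labelled `"none"` are excluded too.
#' Pre-labelled rows (e.g. extended-exon window counts, which have no
#' junction) are appended via `extra` before grouping.
#'
#' @param jpm Long junction-level table with a `jpm` column
#'   (from [normalize_jpm()]).
#' @param ann Annotation tibble ([read_annotation()]).
#' @param by `"event"` or `"isoform"`.
#' @param extra Optional tibble of pre-labelled rows with columns
#'   `event`, `isoform`, `sample`, `jpm`.
#' @return Tibble `row_id`, `sample`, `jpm`, with every label present for
#'   every sample (absent members contribute 0 through the join).
#' @export
aggregate_usage <- function(jpm, ann, by = c("event", "isoform"),
                            extra = NULL) {
  by <- match.arg(by)
  labelled <- jpm |>
    dplyr::inner_join(dplyr::select(ann, dplyr::all_of(.junction_key),
                                    "event", "isoform"),
                      by = .junction_key) |>
    dplyr::select("event", "isoform", "sample", "jpm")
  if (!is.null(extra) && nrow(extra) > 0) {
    labelled <- dplyr::bind_rows(labelled, extra)
  }
  if (by == "isoform") {
    labelled <- dplyr::filter(labelled, .data$isoform != "none")
  }
  labelled |>
    dplyr::group_by(row_id = .data[[by]], .data$sample) |>
    dplyr::summarise(jpm = sum(.data$jpm), .groups = "drop")
}

#' Quantify alternative 5'-exon usage for one dataset (experiment)
#'
#' The full quantification pipeline for one experiment's samples:
#'
#' 1. merge per-sample junction records ([merge_samples()]);
#' 2. dataset-level filtering ([filter_dataset()]);
#' 3. fix the per-sample spliced-read denominators ([spliced_totals()]);
#' 4. gene-level filtering ([filter_gene()]);
#' 5. junctions-per-million normalization ([normalize_jpm()]) with the
#'    step-3 denominators;
#' 6. extended-exon window counting ([count_window()]), normalized with the
#'    same denominators and added as event rows;
#' 7. aggregation to 5'-exon events and to isoform groups
#'    ([aggregate_usage()]).
#'
#' @param records_list Named list of per-sample junction record tibbles.
#' @param ann Junction annotation ([read_annotation()]).
#' @param gene_region One-row tibble `chrom,start,end` delimiting the locus.
#' @param cfg A [filter_config()].
#' @param windows Optional [window_spec()] table for extended exons.
#' @param blocks_list Optional named list (same sample names) of
#'   aligned-block tibbles used for window counting.
#' @param window_isoforms Optional tibble `event`, `isoform` assigning
#'   window events to isoform groups; defaults to isoform `"none"`.
#' @return A `usage_quant` list with elements `junctions` (long jpm table),
#'   `events`, `isoforms` (aggregated `row_id`/`sample`/`jpm` tibbles),
#'   `totals` (denominators), and `annotation`.
#' @export
quantify_usage <- function(records_list, ann, gene_region,
                           cfg = filter_config(),
                           windows = NULL, blocks_list = NULL,
                           window_isoforms = NULL) {
  jx <- merge_samples(records_list) |>
    filter_dataset(cfg)
  totals <- spliced_totals(jx)
  jx <- filter_gene(jx, gene_region, cfg$min_dataset_reads_gene)
  jpm <- normalize_jpm(jx, totals)

  extra <- NULL
  if (!is.null(windows) && nrow(windows) > 0) {
    if (is.null(blocks_list)) {
      stop("windows given but no blocks_list to count them from",
           call. = FALSE)
    }
    wcounts <- purrr::imap_dfr(blocks_list, function(blocks, id) {
      tibble::tibble(
        event = windows$event,
        sample = id,
        count = purrr::map_int(seq_len(nrow(windows)), function(i) {
          count_window(blocks, windows[i, ])
        })
      )
    })
    iso_map <- window_isoforms %||%
      tibble::tibble(event = windows$event, isoform = "none")
    extra <- wcounts |>
      dplyr::left_join(totals, by = "sample") |>
      dplyr::mutate(jpm = .data$count / .data$total_spliced_reads * 1e6) |>
      dplyr::left_join(iso_map, by = "event") |>
      dplyr::mutate(isoform = tidyr::replace_na(.data$isoform, "none")) |>
      dplyr::select("event", "isoform", "sample", "jpm")
  }

  structure(
    list(
      junctions = jpm,
      events = aggregate_usage(jpm, ann, by = "event", extra = extra),
      isoforms = aggregate_usage(jpm, ann, by = "isoform", extra = extra),
      totals = totals,
      annotation = ann
    ),
    class = "usage_quant"
  )
}

#' @export
print.usage_quant <- function(x, ...) {
  cat("<usage_quant> ", dplyr::n_distinct(x$junctions$sample), " samples, ",
      dplyr::n_distinct(x$events$row_id), " events, ",
      dplyr::n_distinct(x$isoforms$row_id), " isoform groups\n", sep = "")
  invisible(x)
}
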