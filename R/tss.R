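#' Construct a transcription start site set
#'
#' A TSS set holds the start positions observed for one promoter region:
#' 0-based genomic coordinates on one chromosome and strand, optionally
#' with per-position support counts (CAGE reads, RACE clones). Positions
#' are stored sorted ascending.
#'
#' @param positions Integer vector of 0-based positions, nonempty.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param support Optional numeric support per position.
#' @return A `tss_set` tibble (`chrom`, `position`, `strand`, `support`).
#' @export
tss_set <- function(positions, chrom, strand, support = NULL) {
  if (length(positions) < 1) stop("positions must be nonempty", call. = FALSE)
  stopifnot(strand %in% c("+", "-"))
  ord <- order(positions)
  out <- tibble::tibble(
    chrom = chrom,
    position = as.integer(positions[ord]),
    strand = strand,
    support = if (is.null(support)) NA_real_ else as.numeric(support[ord])
  )
  class(out) <- c("tss_set", class(out))
  out
}

#' Read TSS positions from a BED6 file
#'
#' The TSS of each record is the interval start for `+` records and
#' `end - 1` for `-` records (0-based). All records must share one
#' chromosome and one strand. The score column is kept as support.
#'
#' @param path Path to a BED6 file.
#' @return A [tss_set()].
#' @export
read_tss_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicnc"
  )
  if (dplyr::n_distinct(bed$chrom) != 1 ||
      dplyr::n_distinct(bed$strand) != 1) {
    stop("TSS BED must be on a single chromosome and strand", call. = FALSE)
  }
  pos <- ifelse(bed$strand == "+", bed$start, bed$end - 1L)
  tss_set(pos, bed$chrom[1], bed$strand[1], support = bed$score)
}

#' Span of a TSS set
#'
#' `max(position) - min(position)` in base pairs; 0 for a single start.
#' Duplicated positions do not change the spread.
#'
#' @param tss A [tss_set()].
#' @return Integer spread in bp.
#' @export
tss_spread <- function(tss) {
  as.integer(max(tss$position) - min(tss$position))
}

#' Classify a promoter as focused or dispersed
#'
#' A dispersed promoter initiates transcription across a broad region
#' (on the order of 100 nucleotides) rather than at a single focused
#' start. The rule used here: *dispersed* iff the TSS spread is at least
#' `dispersed_threshold_bp` **and** there are at least three distinct TSS
#' positions; anything else is *focused*. The >= 3 clause is this
#' package's convention — two isolated starts, however far apart, do not
#' constitute a spread initiation region.
#'
#' Monotone: adding a TSS can only move a promoter toward "dispersed".
#'
#' @param tss A [tss_set()].
#' @param dispersed_threshold_bp Spread threshold in bp (default 100).
#' @return `"focused"` or `"dispersed"`.
#' @export
classify_promoter <- function(tss, dispersed_threshold_bp = 100L) {
  if (tss_spread(tss) >= dispersed_threshold_bp &&
      dplyr::n_distinct(tss$position) >= 3) {
    "dispersed"
  } else {
    "focused"
  }
}

#' Would any transcript carry the repeat tract in its 5' UTR?
#'
#' TRUE iff any TSS lies transcript-upstream of the repeat tract's far
#' edge, so that transcription initiated there runs through the repeat
#' before reaching the gene body. For a minus-strand gene that means a
#' TSS at a genomic position strictly greater than `repeat_tract$end - 1`;
#' for a plus-strand gene, strictly less than `repeat_tract$start`. A TSS
#' exactly at the repeat boundary does not place the repeat in the UTR
#' (strict-inequality convention).
#'
#' @param tss A [tss_set()].
#' @param repeat_tract One-row tibble/list `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Logical scalar.
#' @export
repeat_in_any_utr <- function(tss, repeat_tract) {
  if (tss$chrom[1] != repeat_tract$chrom) {
    stop("TSS set and repeat tract are on different chromosomes",
         call. = FALSE)
  }
  if (tss$strand[1] == "-") {
    any(tss$position > repeat_tract$end - 1L)
  } else {
    any(tss$position < repeat_tract$start)
  }
}
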