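#' @name coordinates
#' @title Coordinate conventions
#' @description
#' All coordinates inside the package are 0-based, half-open
#' (`start` inclusive, `end` exclusive), the BED convention. Files on disk
#' use whatever their format dictates — STAR junction tables and the
#' annotation TSV are 1-based inclusive — and every reader/writer converts
#' at the boundary. A splice junction is identified by the exact 4-tuple
#' (`chrom`, `donor_start`, `acceptor_end`, `strand`), where `donor_start`
#' is the first intronic base and `acceptor_end` the position just past the
#' last intronic base. There is no fuzzy matching anywhere.
#' @keywords internal
NULL

# STAR motif codes 0..6, in order
.motif_levels <- c("non-canonical", "GT/AG", "CT/AC", "GC/AG",
                   "CT/GC", "AT/AC", "GT/AT")

.junction_key <- c("chrom", "donor_start", "acceptor_end", "strand")

.check_junction_cols <- function(x, what = "junction table") {
  missing <- setdiff(.junction_key, names(x))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x$donor_start >= x$acceptor_end)
  if (length(bad) > 0) {
    stop(what, ": donor_start must be < acceptor_end (row ", bad[1], ")",
         call. = FALSE)
  }
  invisible(x)
}

#' Read a junction-to-event annotation table
#'
#' The annotation maps each curated splice junction of the locus to a
#' 5'-exon *event label* (the "5'exon-acceptor" nomenclature, e.g. `"4aI-4"`
#' or the internal-exon form `"6-7"`) and to the protein *isoform group* its
#' transcripts encode (`"TCF4-A"` ... `"TCF4-I"`, `"other"`, or `"none"` for
#' rows that only feed the internal-exon analysis).
#'
#' On disk the table is a TSV with header
#' `chrom  intron_start_1based  intron_end_1based  strand  exon_event  isoform`,
#' 1-based inclusive (mirroring STAR). Coordinates are converted to the
#' package's 0-based half-open convention on read.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `chrom`, `donor_start`, `acceptor_end`,
#'   `strand`, `event`, `isoform`.
#' @export
read_annotation <- function(path) {
  ann <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    intron_start_1based = readr::col_integer(),
    intron_end_1based = readr::col_integer(),
    strand = readr::col_character(),
    exon_event = readr::col_character(),
    isoform = readr::col_character()
  )))
  probs <- readr::problems(ann)
  if (nrow(probs) > 0) {
    stop("malformed annotation row at line ", probs$row[1], " of ",
         path, call. = FALSE)
  }
  ann <- tibble::tibble(
    chrom = ann$chrom,
    donor_start = ann$intron_start_1based - 1L,
    acceptor_end = ann$intron_end_1based,
    strand = ann$strand,
    event = ann$exon_event,
    isoform = ann$isoform
  )
  validate_annotation(ann)
}

#' Validate an in-memory annotation table
#'
#' Checks the invariants of the annotation contract: junction 4-tuples are
#' unique, event labels are nonempty, coordinates are ordered.
#'
#' @param ann A tibble with columns `chrom`, `donor_start`, `acceptor_end`,
#'   `strand`, `event`, `isoform`.
#' @return The validated tibble, invisibly usable in pipes.
#' @export
validate_annotation <- function(ann) {
  .check_junction_cols(ann, "annotation")
  if (any(is.na(ann$event) | ann$event == "")) {
    stop("annotation: event label must be nonempty", call. = FALSE)
  }
  dup <- duplicated(ann[.junction_key])
  if (any(dup)) {
    d <- ann[which(dup)[1], ]
    stop("annotation: duplicate junction ", d$chrom, ":", d$donor_start,
         "-", d$acceptor_end, "(", d$strand, ")", call. = FALSE)
  }
  ann
}

#' Write an annotation table to TSV
#'
#' Inverse of [read_annotation()]: coordinates go back to 1-based inclusive.
#'
#' @param ann Annotation tibble (internal 0-based convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  out <- tibble::tibble(
    chrom = ann$chrom,
    intron_start_1based = ann$donor_start + 1L,
    intron_end_1based = ann$acceptor_end,
    strand = ann$strand,
    exon_event = ann$event,
    isoform = ann$isoform
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Look up the event label of a junction
#'
#' Exact-coordinate lookup: a junction matches an annotation row iff
#' `chrom`, `donor_start`, `acceptor_end` and `strand` all agree. Returns
#' `NA_character_` when there is no match — curation is by exact identity,
#' so a coordinate shifted by a single base is a different junction.
#'
#' @param junction A one-row data frame (or list) with the four key fields.
#' @param ann Annotation tibble from [read_annotation()].
#' @return The event label, or `NA_character_`.
#' @export
match_junction <- function(junction, ann) {
  hit <- ann$chrom == junction$chrom &
    ann$donor_start == junction$donor_start &
    ann$acceptor_end == junction$acceptor_end &
    ann$strand == junction$strand
  if (any(hit)) ann$event[which(hit)[1]] else NA_character_
}

#' Construct a multi-promoter gene model
#'
#' A gene model bundles the locus extent, the named internal exons, the
#' named alternative 5' exons (each driven by its own promoter), and the
#' trinucleotide-repeat tract. It is a plain list of tibbles with class
#' `"gene_model"`.
#'
#' @param gene_region One-row tibble `chrom,start,end,strand`.
#' @param internal_exons Tibble `name,chrom,start,end,strand`, ordered in
#'   transcript orientation.
#' @param five_prime_exons Tibble `name,chrom,start,end,strand`.
#' @param repeat_tract One-row tibble `chrom,start,end`.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_region, internal_exons, five_prime_exons,
                       repeat_tract) {
  exons <- dplyr::bind_rows(internal_exons, five_prime_exons)
  if (any(exons$start < gene_region$start | exons$end > gene_region$end)) {
    stop("gene_model: all exons must lie within gene_region", call. = FALSE)
  }
  if (length(unique(exons$strand)) != 1) {
    stop("gene_model: exon strands must be consistent", call. = FALSE)
  }
  structure(
    list(gene_region = gene_region,
         internal_exons = internal_exons,
         five_prime_exons = five_prime_exons,
         repeat_tract = repeat_tract),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_region$chrom, ":", x$gene_region$start, "-",
      x$gene_region$end, " (", x$gene_region$strand, ")\n", sep = "")
  cat("  internal exons: ", nrow(x$internal_exons),
      " | 5' exons: ", nrow(x$five_prime_exons),
      " | repeat tract: ", x$repeat_tract$start, "-", x$repeat_tract$end,
      "\n", sep = "")
  invisible(x)
}

#' Demonstration TCF4-like gene model
#'
#' A minus-strand locus on chr18 (hg19-like coordinates) with internal exons
#' 3 through 21, a set of alternative 5' exons named after the locus's
#' figure-style nomenclature (3b, 3c, 3d, 4aI, 4aIII, 4b, 4c, 7bII, 8a,
#' 8bII, 8cII, 10a), and a CTG-repeat tract in the intron between internal
#' exons 3 and 4 — upstream, in transcript orientation, of the 4a/4b/4c
#' promoters. Coordinates are schematic (exon sizes and spacings are not the
#' real locus) but respect the real topology: the gene is transcribed from
#' the reverse strand, so transcript order runs from high to low genomic
#' coordinates, and the repeat tract sits inside the
#' chr18:53,252,500-53,254,500 promoter-region window.
#'
#' Used by the test-suite and by [simulate_dataset()] as the default locus.
#'
#' @return A [gene_model()] object.
#' @export
build_demo_gene <- function() {
  chrom <- "chr18"
  # minus strand: transcript 5' end = high genomic coordinates.
  # internal exons 3..21 laid out from high to low coordinates.
  n_int <- 19L
  names_int <- as.character(3:21)
  width <- 150L
  gap <- 20000L
  # exon 3 ends near the top of the locus; exon 21 near the bottom
  starts <- 53260000L - (seq_len(n_int) - 1L) * gap
  internal <- tibble::tibble(
    name = names_int, chrom = chrom,
    start = starts, end = starts + width, strand = "-"
  )
  exon <- function(nm) internal[internal$name == nm, ]
  # repeat tract: between exon 3 and exon 4 in transcript orientation,
  # i.e. genomically below exon 3's start and above exon 4's end;
  # inside the chr18:53,252,500-53,254,500 window.
  repeat_tract <- tibble::tibble(chrom = chrom,
                                 start = 53253385L, end = 53253460L)
  # 5' exons: 3b/3c/3d upstream of exon 3; 4aI/4aIII/4b/4c between the
  # repeat and internal exon 4; the rest near their acceptor exons.
  fpe <- function(nm, start) {
    tibble::tibble(name = nm, chrom = chrom, start = as.integer(start),
                   end = as.integer(start + 120L), strand = "-")
  }
  five_prime <- dplyr::bind_rows(
    fpe("3b", 53297000L),
    fpe("3c", 53290000L),
    fpe("3d", 53284000L),
    fpe("4aI", 53252900L),
    fpe("4aIII", 53252100L),
    fpe("4b", 53251300L),
    fpe("4c", exon("4")$end + 30L),   # extended exon reading into exon 4
    fpe("7bII", exon("7")$end + 30L), # extended exon reading into exon 7
    fpe("8a", exon("8")$end + 4000L),
    fpe("8bII", exon("8")$end + 2600L),
    fpe("8cII", exon("8")$end + 1200L),
    fpe("10a", exon("10")$end + 3000L)
  )
  gene_region <- tibble::tibble(
    chrom = chrom, start = 52889562L, end = 53332018L, strand = "-"
  )
  gene_model(gene_region, internal, five_prime, repeat_tract)
}
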