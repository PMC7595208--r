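mk_jx <- function(chrom, motif, counts, donor = 100L) {
  # one junction across length(counts) samples
  tibble::tibble(
    chrom = chrom, donor_start = donor, acceptor_end = donor + 500L,
    strand = "-", motif = motif,
    sample = paste0("s", seq_along(counts)), count = as.integer(counts)
  )
}

test_that("dataset filter applies threshold, chromosome and motif rules", {
  jx <- dplyr::bind_rows(
    mk_jx("chr18", "GT/AG", c(3, 3), donor = 100L),   # sum 6: kept
    mk_jx("chr18", "GT/AG", c(3, 2), donor = 700L),   # sum 5: removed
    mk_jx("chrM", "GT/AG", c(50, 50), donor = 1300L), # chrM: removed
    mk_jx("chr18", "non-canonical", c(50, 50), donor = 1900L) # removed
  )
  out <- filter_dataset(jx, filter_config())
  expect_equal(unique(out$donor_start), 100L)
  expect_equal(sort(unique(out$sample)), c("s1", "s2"))
  # identity configuration changes nothing
  cfg0 <- filter_config(0L, 0L, character(0), canonical_only = FALSE)
  expect_equal(filter_dataset(jx, cfg0), jx)
})

test_that("gene filter is scoped to the gene region", {
  region <- tibble::tibble(chrom = "chr18", start = 0L, end = 10000L)
  jx <- dplyr::bind_rows(
    mk_jx("chr18", "GT/AG", c(2, 1), donor = 100L),    # in gene, sum 3: out
    mk_jx("chr18", "GT/AG", c(2, 2), donor = 700L),    # in gene, sum 4: kept
    mk_jx("chr18", "GT/AG", c(1, 0), donor = 50000L),  # outside: kept
    mk_jx("chr7", "GT/AG", c(1, 0), donor = 100L)      # other chrom: kept
  )
  out <- filter_gene(jx, region, min_reads = 4L)
  expect_setequal(
    unique(paste(out$chrom, out$donor_start)),
    c("chr18 700", "chr18 50000", "chr7 100")
  )
  empty <- jx[0, ]
  expect_equal(nrow(filter_gene(empty, region)), 0)
})

test_that("dataset + gene filtering is idempotent", {
  jx <- random_jx(30, 4, seed = 5)
  region <- tibble::tibble(chrom = "chr18", start = 0L, end = 60000L)
  once <- filter_gene(filter_dataset(jx), region)
  twice <- filter_gene(filter_dataset(once), region)
  expect_equal(twice, once)
})

test_that("jpm normalization matches its definition and conserves mass", {
  jx <- dplyr::bind_rows(
    mk_jx("chr18", "GT/AG", c(5, 10), donor = 100L),
    mk_jx("chr18", "GT/AG", c(0, 990), donor = 700L)
  )
  out <- normalize_jpm(jx)
  expect_equal(out$jpm[out$donor_start == 100L & out$sample == "s1"], 1e6)
  expect_equal(out$jpm[out$donor_start == 700L & out$sample == "s1"], 0)
  expect_equal(out$jpm[out$donor_start == 100L & out$sample == "s2"],
               10 / 1000 * 1e6)
  sums <- out |>
    dplyr::group_by(sample) |>
    dplyr::summarise(s = sum(jpm))
  expect_equal(sums$s, rep(1e6, 2), tolerance = 1e-6)
  # zero-total sample is an error naming the sample
  jx0 <- mk_jx("chr18", "GT/AG", c(0, 4))
  expect_error(normalize_jpm(jx0), "s1")
})

test_that("count_window requires one block to cover both window bases", {
  w <- tibble::tibble(chrom = "chr18", start = 1000L, end = 1002L)
  blk <- function(id, s, e) tibble::tibble(read_id = id, chrom = "chr18",
                                           block_start = s, block_end = e)
  # fully covering block
  expect_equal(count_window(blk("r1", 990L, 1012L), w), 1L)
  # spliced read whose intron gap spans the window: not crossing
  spliced <- dplyr::bind_rows(blk("r2", 900L, 1000L), blk("r2", 1002L, 1100L))
  expect_equal(count_window(spliced, w), 0L)
  # block covering only one of the two bases
  expect_equal(count_window(blk("r3", 990L, 1001L), w), 0L)
  # per-position coverage oracle on a batch of random reads
  set.seed(42)
  reads <- purrr::map_dfr(1:200, function(i) {
    s <- sample(980:1020, 1)
    blk(paste0("x", i), s, s + sample(1:30, 1))
  })
  oracle <- reads |>
    dplyr::group_by(read_id) |>
    dplyr::summarise(cross = any(block_start <= 1000 & block_end >= 1002))
  expect_equal(count_window(reads, w), sum(oracle$cross))
  expect_error(count_window(reads, tibble::tibble(chrom = "chr18",
                                                  start = 1000L,
                                                  end = 1003L)),
               "2 bp")
})

test_that("block readers agree on BED12 input", {
  skip_if_not_installed("rtracklayer")
  bed <- withr::local_tempfile(fileext = ".bed")
  # two reads: one 2-block spliced read, one single-block read
  writeLines(c(
    paste0("chr18\t900\t1100\tr1\t0\t-\t900\t1100\t0\t2\t100,98\t0,102"),
    paste0("chr18\t990\t1012\tr2\t0\t-\t990\t1012\t0\t1\t22\t0")
  ), bed)
  blocks <- read_blocks_bed12(bed)
  expect_equal(nrow(blocks), 3)
  w <- tibble::tibble(chrom = "chr18", start = 1000L, end = 1002L)
  expect_equal(count_window(blocks, w), 1L)  # only r2 crosses
  expect_equal(blocks$block_start[blocks$read_id == "r1"], c(900L, 1002L))
})

test_that("aggregation sums member junctions per label", {
  ann <- tibble::tibble(
    chrom = "chr18", donor_start = c(100L, 700L, 1300L),
    acceptor_end = c(600L, 1200L, 1800L), strand = "-",
    event = c("3b-4", "3b-4", "3b-3"),
    isoform = c("TCF4-C", "TCF4-C", "TCF4-B")
  )
  jpm <- dplyr::bind_rows(
    mk_jx("chr18", "GT/AG", c(1, 1), donor = 100L),
    mk_jx("chr18", "GT/AG", c(1, 1), donor = 700L),
    mk_jx("chr18", "GT/AG", c(1, 1), donor = 1300L),
    mk_jx("chr18", "GT/AG", c(1, 1), donor = 5000L)  # unannotated
  ) |>
    dplyr::mutate(jpm = c(2, 4, 3, 6, 10, 1, 99, 99)) |>
    dplyr::select(-count)
  ev <- aggregate_usage(jpm, ann, by = "event")
  expect_equal(ev$jpm[ev$row_id == "3b-4" & ev$sample == "s1"], 2 + 3)
  expect_equal(ev$jpm[ev$row_id == "3b-4" & ev$sample == "s2"], 4 + 6)
  expect_false("5000" %in% ev$row_id)  # unannotated junctions excluded
  # empty annotation -> empty output
  expect_equal(nrow(aggregate_usage(jpm, ann[0, ], by = "event")), 0)
  # isoform level: labels collapse further
  iso <- aggregate_usage(jpm, ann, by = "isoform")
  expect_equal(iso$jpm[iso$row_id == "TCF4-C" & iso$sample == "s1"], 5)
  expect_equal(iso$jpm[iso$row_id == "TCF4-B" & iso$sample == "s1"], 10)
})

test_that("aggregation is linear", {
  ann <- build_demo_annotation()
  sim <- simulate_dataset(sim_config(seed = 31))
  ids <- sim$meta$sample_id[1:4]
  jx <- merge_samples(sim$sj[ids]) |> filter_dataset()
  a <- normalize_jpm(jx)
  b <- a |> dplyr::mutate(jpm = jpm * 2)
  sum_then_agg <- aggregate_usage(
    dplyr::mutate(a, jpm = a$jpm + b$jpm), ann, by = "event")
  agg_then_sum <- aggregate_usage(a, ann, by = "event") |>
    dplyr::mutate(jpm = jpm * 3)
  expect_equal(sum_then_agg, agg_then_sum, tolerance = 1e-12)
})

test_that("window events flow through quantify_usage into both levels", {
  sim <- simulate_dataset(sim_config(seed = 41))
  q <- quantify_simulated(sim)[["2019"]]
  expect_true(all(c("4c", "7bII") %in% unique(q$events$row_id)))
  # 4c window reads contribute to the TCF4-C isoform group
  iso <- q$isoforms
  expect_true("TCF4-C" %in% unique(iso$row_id))
  expect_false("none" %in% unique(iso$row_id))
  # jpm of 4c equals window count / spliced total * 1e6 for a sample
  id <- sim$meta$sample_id[1]
  wc <- count_window(sim$blocks[[id]], sim$windows[sim$windows$event == "4c", ])
  tot <- q$totals$total_spliced_reads[q$totals$sample == id]
  expect_equal(q$events$jpm[q$events$row_id == "4c" & q$events$sample == id],
               wc / tot * 1e6)
})
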