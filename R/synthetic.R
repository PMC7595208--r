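#' @name synthetic
#' @title Synthetic junction datasets with known ground truth
#' @description
#' The simulator emulates the structure of the two corneal-endothelium
#' RNA-seq cohorts the differential-usage statistics were designed for:
#' two independent experiments with 6 control / 8 disease and
#' 9 control / 6 disease samples, negative-binomial (Gamma-Poisson)
#' junction counts over a TCF4-like multi-promoter gene model,
#' per-sample library-size variation, and a disease effect profile in
#' which events immediately downstream of the repeat tract go down,
#' distal 5' exons go up, and a few events stay flat. Background
#' junctions (an aggregate pseudo-junction plus decoys that hit every
#' filter branch: mitochondrial, non-canonical motif, low-count) make up
#' the junctions-per-million denominator.
#' @keywords internal
NULL

# run expr under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# stable per-stream seed derived from (seed, id); independent of the order
# in which streams are consumed, and always < 2^31
.stable_seed <- function(seed, id) {
  h <- 0
  for (c0 in utf8ToInt(as.character(id))) h <- (h * 131 + c0) %% 2147483647
  # doubles stay exact here: (2^31 - 1) * 48271 < 2^53
  as.integer(((seed %% 2147483647) * 48271 + h) %% 2147483647)
}

#' Default disease effect profile
#'
#' Fold-changes (disease vs control) per event, with the direction
#' structure of an expanded-repeat cohort: events starting immediately
#' downstream of the repeat tract, and 5' exons spliced directly to
#' internal exon 4, are reduced; the extended exon 4c, upstream 5' exons
#' spliced to exon 3, distal 5' exons (8a, 8bII, 8cII, 10a) and the
#' internal 10-16 chain are increased; a few events are unchanged.
#'
#' @param fold_down Fold applied to down events (default 0.3).
#' @param fold_up Fold applied to up events (default 3.0).
#' @return Named numeric vector event -> fold.
#' @export
default_fecd_profile <- function(fold_down = 0.3, fold_up = 3.0) {
  stopifnot(fold_down > 0, fold_up > 0)
  down <- c("4aI-4", "4aIII-4", "3b-4", "3d-4", "6-7", "7-8")
  up <- c("4c", "3b-3", "8a-8", "8bII-8", "8cII-8", "10a-10",
          "10-11", "15-16")
  flat <- c("3c-3", "3d-3", "8-9", "4b-4", "7bII")
  setNames(
    c(rep(fold_down, length(down)), rep(fold_up, length(up)),
      rep(1, length(flat))),
    c(down, up, flat)
  )
}

#' Demo junction annotation for the TCF4-like locus
#'
#' One curated junction per 5'-exon or internal splicing event of
#' [build_demo_gene()] (two donor variants for event `10a-10`, to exercise
#' event-level summation), with the isoform-group assignment used for
#' isoform aggregation. Extended exons (`4c`, `7bII`) have no junction and
#' are quantified through [window_spec()] windows instead.
#'
#' @param gene A [gene_model()] (default [build_demo_gene()]).
#' @return An annotation tibble (see [read_annotation()]).
#' @export
build_demo_annotation <- function(gene = build_demo_gene()) {
  allx <- dplyr::bind_rows(gene$internal_exons, gene$five_prime_exons)
  ex <- function(nm) allx[allx$name == nm, ]
  # minus strand: donor exon is the genomically higher one; the intron is
  # [lower_exon_end, higher_exon_start)
  jx <- function(donor, acceptor, event, isoform, donor_shift = 0L) {
    d <- ex(donor); a <- ex(acceptor)
    tibble::tibble(
      chrom = d$chrom,
      donor_start = a$end,
      acceptor_end = d$start + donor_shift,
      strand = "-",
      event = event, isoform = isoform
    )
  }
  dplyr::bind_rows(
    jx("3b", "3", "3b-3", "TCF4-B"),
    jx("3c", "3", "3c-3", "TCF4-B"),
    jx("3d", "3", "3d-3", "TCF4-B"),
    jx("3b", "4", "3b-4", "TCF4-C"),
    jx("3d", "4", "3d-4", "TCF4-C"),
    jx("4aI", "4", "4aI-4", "TCF4-C"),
    jx("4aIII", "4", "4aIII-4", "TCF4-C"),
    jx("4b", "4", "4b-4", "TCF4-C"),
    jx("8a", "8", "8a-8", "TCF4-D"),
    jx("8bII", "8", "8bII-8", "TCF4-D"),
    jx("8cII", "8", "8cII-8", "TCF4-D"),
    jx("10a", "10", "10a-10", "TCF4-A"),
    jx("10a", "10", "10a-10", "TCF4-A", donor_shift = 40L),
    jx("6", "5", "6-7", "none"),   # placeholder coords, see below
    jx("7", "6", "7-8", "none"),
    jx("8", "7", "8-9", "none"),
    jx("10", "9", "10-11", "none"),
    jx("15", "14", "15-16", "none")
  ) |>
    .fix_internal_junctions(gene) |>
    validate_annotation()
}

# internal-exon junctions N-(N+1): intron between exon N (higher coords on
# the minus strand) and exon N+1 (lower)
.fix_internal_junctions <- function(ann, gene) {
  internal_events <- c("6-7", "7-8", "8-9", "10-11", "15-16")
  for (evt in internal_events) {
    parts <- strsplit(evt, "-")[[1]]
    hi <- gene$internal_exons[gene$internal_exons$name == parts[1], ]
    lo <- gene$internal_exons[gene$internal_exons$name == parts[2], ]
    i <- which(ann$event == evt)
    ann$donor_start[i] <- lo$end
    ann$acceptor_end[i] <- hi$start
  }
  ann
}

#' Simulation configuration
#'
#' Bundles the study conditions for [simulate_dataset()]. The defaults are
#' the conditions the pipeline is designed around: two experiments with
#' 6/8 and 9/6 control/disease samples, negative-binomial counts with size
#' 10, per-sample spliced-read totals between one and three million
#' (baseline junction means are expressed as expected counts at a
#' two-million-read reference depth), and the [default_fecd_profile()]
#' effect directions.
#'
#' @param seed Master seed; per-sample streams are derived from it by
#'   stable hashing of the sample id, so results do not depend on
#'   generation order.
#' @param experiments Tibble `name`, `n_ctrl`, `n_case`.
#' @param baseline_mean Named vector event -> expected count at the
#'   reference depth; defaults chosen as order-of-magnitude realistic
#'   junction support for a moderately expressed locus.
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param library_size_range Length-2 numeric, spliced-read totals
#'   (default 1e6..3e6).
#' @param effect_profile Named vector event -> disease fold-change.
#' @param n_decoys Number of background decoy junctions (default 50).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       experiments = tibble::tibble(
                         name = c("2019", "2020"),
                         n_ctrl = c(6L, 9L),
                         n_case = c(8L, 6L)
                       ),
                       baseline_mean = NULL,
                       dispersion = 10,
                       library_size_range = c(1e6, 3e6),
                       effect_profile = default_fecd_profile(),
                       n_decoys = 50L) {
  default_baseline <- c(
    "4aI-4" = 40, "4aIII-4" = 25, "3b-4" = 15, "3d-4" = 12,
    "6-7" = 120, "7-8" = 110,
    "4c" = 20, "3b-3" = 30, "8a-8" = 25, "8bII-8" = 15, "8cII-8" = 12,
    "10a-10" = 30, "10-11" = 150, "15-16" = 160,
    "3c-3" = 25, "3d-3" = 20, "8-9" = 130, "4b-4" = 8, "7bII" = 10
  )
  baseline_mean <- baseline_mean %||% default_baseline
  stopifnot(all(baseline_mean > 0), all(effect_profile > 0),
            all(experiments$n_ctrl >= 2), all(experiments$n_case >= 2),
            dispersion > 0, length(library_size_range) == 2)
  structure(
    list(seed = as.integer(seed), experiments = experiments,
         baseline_mean = baseline_mean, dispersion = dispersion,
         library_size_range = sort(library_size_range),
         effect_profile = effect_profile, n_decoys = as.integer(n_decoys),
         reference_depth = 2e6),
    class = "sim_config"
  )
}

# fixed decoy junction layout: deterministic coordinates, one quarter each
# mitochondrial / non-canonical motif / low-count / clean passing
.decoy_layout <- function(n_decoys) {
  kind <- rep(c("chrM", "noncanonical", "lowcount", "clean"),
              length.out = n_decoys)
  i <- seq_len(n_decoys)
  tibble::tibble(
    chrom = dplyr::case_when(
      kind == "chrM" ~ "chrM",
      kind == "noncanonical" ~ "chr2",
      kind == "lowcount" ~ "chr3",
      TRUE ~ "chr4"
    ),
    donor_start = 10000L + i * 5000L,
    acceptor_end = 10000L + i * 5000L + 800L,
    strand = rep(c("+", "-"), length.out = n_decoys),
    motif = ifelse(kind == "noncanonical", "non-canonical", "GT/AG"),
    mean = dplyr::case_when(
      kind == "chrM" ~ 50,
      kind == "noncanonical" ~ 40,
      kind == "lowcount" ~ 0.08,
      TRUE ~ 30
    )
  )
}

#' Simulate a two-experiment junction dataset
#'
#' Draws, for every sample, negative-binomial counts for each annotated
#' junction of the demo locus (mean = baseline x disease fold x
#' library-size factor, size = `dispersion`), extended-exon window reads
#' emitted as aligned-block records, decoy background junctions, and one
#' aggregate background pseudo-junction that tops the sample's total
#' junction reads up to a library size drawn uniformly from
#' `library_size_range` — so each written junction file sums exactly to
#' its library size. Everything is deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, per-sample
#'   `<sample>.SJ.out.tab` files (STAR dialect), per-sample
#'   `<sample>.blocks.tsv` files, `meta.tsv`, `annotation.tsv` and
#'   `truth.tsv` are written there.
#' @return A list: `sj` (named list of per-sample junction record
#'   tibbles), `blocks` (named list of aligned-block tibbles), `meta`,
#'   `truth` (`$events` fold/direction, `$samples` library sizes),
#'   `annotation`, `windows`, `gene`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  gene <- build_demo_gene()
  ann <- build_demo_annotation(gene)
  windows <- window_spec(gene)
  window_events <- windows$event
  junction_events <- setdiff(names(cfg$effect_profile), window_events)

  # per-junction expected counts: split an event's baseline over its
  # member junctions (donor variants share the event's mass 70/30)
  ann_mean <- ann |>
    dplyr::group_by(.data$event) |>
    dplyr::mutate(weight = if (dplyr::n() == 1) 1 else c(0.7, 0.3)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      baseline = unname(cfg$baseline_mean[.data$event]) * .data$weight,
      fold = unname(cfg$effect_profile[.data$event])
    )
  if (anyNA(ann_mean$baseline) || anyNA(ann_mean$fold)) {
    stop("baseline_mean/effect_profile must cover every annotated event",
         call. = FALSE)
  }
  decoys <- .decoy_layout(cfg$n_decoys)

  meta <- cfg$experiments |>
    purrr::pmap_dfr(function(name, n_ctrl, n_case) {
      tibble::tibble(
        sample_id = c(paste0(name, "_CTRL_", seq_len(n_ctrl)),
                      paste0(name, "_FECD_", seq_len(n_case))),
        experiment = name,
        disease = c(rep("CTRL", n_ctrl), rep("FECD", n_case))
      )
    })

  one_sample <- function(sample_id, disease) {
    .with_seed(.stable_seed(cfg$seed, sample_id), {
      lib <- round(runif(1, cfg$library_size_range[1],
                         cfg$library_size_range[2]))
      f <- lib / cfg$reference_depth
      mu <- ann_mean$baseline * f *
        (if (disease == "FECD") ann_mean$fold else 1)
      gene_counts <- rnbinom(length(mu), mu = mu, size = cfg$dispersion)
      decoy_counts <- rnbinom(nrow(decoys), mu = decoys$mean * f,
                              size = cfg$dispersion)
      # window (extended-exon) reads, per window event
      wmu <- unname(cfg$baseline_mean[window_events]) * f *
        (if (disease == "FECD") unname(cfg$effect_profile[window_events])
         else 1)
      wcounts <- rnbinom(length(wmu), mu = wmu, size = cfg$dispersion)

      sj <- dplyr::bind_rows(
        tibble::tibble(
          chrom = ann_mean$chrom, donor_start = ann_mean$donor_start,
          acceptor_end = ann_mean$acceptor_end, strand = ann_mean$strand,
          motif = "CT/AC", unique_reads = gene_counts
        ),
        tibble::tibble(
          chrom = decoys$chrom, donor_start = decoys$donor_start,
          acceptor_end = decoys$acceptor_end, strand = decoys$strand,
          motif = decoys$motif, unique_reads = decoy_counts
        )
      )
      filler <- lib - sum(sj$unique_reads)
      if (filler < 0) {
        stop("library_size_range too small for the configured baselines",
             call. = FALSE)
      }
      sj <- dplyr::bind_rows(sj, tibble::tibble(
        chrom = "chr1", donor_start = 500000L, acceptor_end = 501000L,
        strand = "+", motif = "GT/AG", unique_reads = as.integer(filler)
      )) |>
        dplyr::filter(.data$unique_reads > 0) |>
        dplyr::mutate(
          annotated = TRUE, multimapping_reads = 0L, max_overhang = 50L,
          unique_reads = as.integer(.data$unique_reads)
        )

      blocks <- purrr::map2_dfr(window_events, wcounts, function(evt, n) {
        if (n == 0) return(NULL)
        w <- windows[windows$event == evt, ]
        tibble::tibble(
          read_id = paste0(sample_id, "_", evt, "_r", seq_len(n)),
          chrom = w$chrom,
          block_start = w$start - 20L,
          block_end = w$end + 20L
        )
      })
      if (nrow(blocks) == 0) {
        blocks <- tibble::tibble(read_id = character(), chrom = character(),
                                 block_start = integer(),
                                 block_end = integer())
      }
      list(sj = sj, blocks = blocks, lib = lib)
    })
  }

  sims <- purrr::map2(meta$sample_id, meta$disease, one_sample)
  names(sims) <- meta$sample_id

  truth_events <- tibble::tibble(
    event = names(cfg$effect_profile),
    fold = unname(cfg$effect_profile),
    direction = dplyr::case_when(
      cfg$effect_profile > 1 ~ "up",
      cfg$effect_profile < 1 ~ "down",
      TRUE ~ "flat"
    )
  )
  truth_samples <- tibble::tibble(
    sample_id = meta$sample_id,
    library_size = purrr::map_dbl(sims, "lib")
  )

  out <- list(
    sj = purrr::map(sims, "sj"),
    blocks = purrr::map(sims, "blocks"),
    meta = meta,
    truth = list(events = truth_events, samples = truth_samples),
    annotation = ann,
    windows = windows,
    gene = gene
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in meta$sample_id) {
      write_star_sj(out$sj[[id]], file.path(dir, paste0(id, ".SJ.out.tab")))
      readr::write_tsv(out$blocks[[id]],
                       file.path(dir, paste0(id, ".blocks.tsv")))
    }
    readr::write_tsv(meta, file.path(dir, "meta.tsv"))
    write_annotation(ann, file.path(dir, "annotation.tsv"))
    readr::write_tsv(truth_events, file.path(dir, "truth.tsv"))
  }
  out
}

#' Quantify a simulated dataset, per experiment
#'
#' Convenience wrapper running [quantify_usage()] separately on each
#' experiment's samples (filters and denominators are per-dataset), with
#' the simulation's annotation and extended-exon windows.
#'
#' @param sim Output of [simulate_dataset()].
#' @param cfg_filter A [filter_config()].
#' @return Named list of [quantify_usage()] results, one per experiment.
#' @export
quantify_simulated <- function(sim, cfg_filter = filter_config()) {
  window_iso <- tibble::tibble(event = c("4c", "7bII"),
                               isoform = c("TCF4-C", "none"))
  exps <- unique(sim$meta$experiment)
  purrr::map(exps, function(e) {
    ids <- sim$meta$sample_id[sim$meta$experiment == e]
    quantify_usage(
      sim$sj[ids], ann = sim$annotation,
      gene_region = sim$gene$gene_region,
      cfg = cfg_filter,
      windows = sim$windows, blocks_list = sim$blocks[ids],
      window_isoforms = window_iso
    )
  }) |>
    setNames(exps)
}

#' Simulate a dual-luciferase reporter experiment
#'
#' Firefly/Renilla signal pairs for two promoter constructs across a
#' repeat-length series and `n_experiments` independent experiments, with
#' multiplicative log-normal noise of coefficient of variation `noise_cv`
#' on each luminescence signal. Effects are relative promoter activities
#' (fold vs the 11-repeat construct); with `noise_cv = 0`,
#' [normalize_reporter()] returns exactly the configured folds.
#'
#' @param seed Integer seed (deterministic output).
#' @param effects Named list promoter -> named vector repeat_length ->
#'   relative activity. The default is a monotone repeat-length dose
#'   response ending at 0.30 (p4a) and 0.25 (p4abc) for 144 repeats.
#' @param noise_cv Coefficient of variation of the log-normal signal
#'   noise (default 0.10).
#' @param n_experiments Number of independent experiments (default 3).
#' @return A measurement tibble for [normalize_reporter()] /
#'   [analyze_reporter()].
#' @export
simulate_reporter <- function(seed = 1L,
                              effects = list(
                                p4a = c("11" = 1, "25" = 0.95, "31" = 0.9,
                                        "54" = 0.6, "67" = 0.5,
                                        "144" = 0.30),
                                p4abc = c("11" = 1, "25" = 0.95, "31" = 0.9,
                                          "54" = 0.55, "70" = 0.45,
                                          "144" = 0.25)
                              ),
                              noise_cv = 0.10,
                              n_experiments = 3L) {
  stopifnot(all(unlist(effects) > 0), noise_cv >= 0, n_experiments >= 2)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) {
    if (noise_cv == 0) rep(1, n) else rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  .with_seed(.stable_seed(seed, "reporter"), {
    purrr::imap_dfr(effects, function(eff, prom) {
      purrr::map_dfr(seq_len(n_experiments), function(e) {
        k <- length(eff)
        base_ff <- 2e5 * runif(1, 0.5, 1.5)   # experiment-level scale
        base_rn <- 5e4 * runif(1, 0.5, 1.5)
        tibble::tibble(
          promoter = prom,
          repeat_length = as.integer(names(eff)),
          experiment = e,
          firefly = base_ff * unname(eff) * noise(k),
          renilla = base_rn * noise(k)
        )
      })
    })
  })
}

#' Simulate a transcription start site set
#'
#' `n` positions drawn uniformly over
#' `[center - spread/2, center + spread/2]`, sorted; deterministic by
#' seed.
#'
#' @param n Number of TSS positions (>= 1).
#' @param center Central coordinate (0-based).
#' @param spread Width of the initiation region in bp (>= 0).
#' @param strand `"+"` or `"-"`.
#' @param seed Integer seed.
#' @param chrom Chromosome name (default `"chr18"`).
#' @return A [tss_set()].
#' @export
simulate_tss <- function(n, center, spread, strand = "-", seed = 1L,
                         chrom = "chr18") {
  stopifnot(n >= 1, spread >= 0)
  .with_seed(.stable_seed(seed, "tss"), {
    pos <- round(runif(n, center - spread / 2, center + spread / 2))
    tss_set(as.integer(pos), chrom = chrom, strand = strand)
  })
}
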