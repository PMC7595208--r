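test_that("mann_whitney matches hand-derived exact cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 assignments are as extreme
  expect_true(r$exact)
  # identical multisets carry no evidence
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  # U-statistic swap identity
  set.seed(1)
  x <- rnorm(5); y <- rnorm(7)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(b$U, length(x) * length(y) - a$U)
  expect_equal(a$p, b$p)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("mann_whitney exact p equals enumeration on small designs", {
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney(x, y)$p, mwu_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("bh_fdr matches the step-up formula and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)      # m = 1
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  perm <- sample.int(50)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("within_experiment tests CTRL vs FECD per member with family FDR", {
  meta <- demo_meta()
  set.seed(3)
  usage <- tidyr::expand_grid(row_id = c("e1", "e2", "e3"),
                              sample = meta$sample_id) |>
    dplyr::mutate(jpm = runif(dplyr::n(), 1, 100))
  # an event with full separation: all FECD below all CTRL
  usage$jpm[usage$row_id == "e1"] <-
    c(runif(6, 50, 60), runif(8, 1, 10))[match(
      usage$sample[usage$row_id == "e1"], meta$sample_id)]
  res <- within_experiment(usage, meta)
  e1 <- res[res$row_id == "e1", ]
  expect_true(e1$U %in% c(0, 48))           # fully extreme configuration
  expect_equal(e1$p, 2 / choose(14, 6), tolerance = 1e-12)
  expect_equal(e1$direction, "down")
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
  # family of one member: q equals p
  one <- within_experiment(usage, meta, family = "e2")
  expect_equal(one$q, one$p)
  # identical values in both groups: flat
  flat <- usage
  flat$jpm[flat$row_id == "e2"] <- 5
  expect_equal(
    within_experiment(flat, meta, family = "e2")$direction, "flat")
  expect_error(within_experiment(usage, meta, family = "missing_event"),
               "missing_event")
})

test_that("gamma GLM returns a null result on constant data", {
  meta <- dplyr::bind_rows(
    demo_meta(),
    dplyr::mutate(demo_meta(), sample_id = paste0("b_", sample_id),
                  experiment = "2020")
  )
  vals <- tibble::tibble(sample = meta$sample_id, jpm = 7.5)
  r <- gamma_glm_disease(vals, meta)
  expect_lt(abs(r$coef), 1e-8)
  expect_gte(r$p, 0.99)
})

test_that("gamma GLM Wald p is invariant to order-preserving relabels", {
  meta <- dplyr::bind_rows(
    demo_meta(),
    dplyr::mutate(demo_meta(), sample_id = paste0("b_", sample_id),
                  experiment = "2020")
  )
  set.seed(8)
  vals <- tibble::tibble(sample = meta$sample_id,
                         jpm = rgamma(nrow(meta), shape = 5, rate = 0.2))
  a <- gamma_glm_disease(vals, meta)
  meta2 <- dplyr::mutate(meta, experiment = paste0("exp", experiment))
  b <- gamma_glm_disease(vals, meta2)
  expect_equal(a$coef, b$coef, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  # degenerate designs are refused
  expect_error(gamma_glm_disease(vals, dplyr::mutate(meta, experiment = "x")),
               "degenerate")
})

test_that("gamma GLM detects a strong disease effect at study sizes", {
  meta <- dplyr::bind_rows(
    demo_meta(),
    tibble::tibble(sample_id = c(paste0("b_c", 1:9), paste0("b_f", 1:6)),
                   experiment = "2020",
                   disease = c(rep("CTRL", 9), rep("FECD", 6)))
  )
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    mu <- ifelse(meta$disease == "FECD", 40, 10)
    vals <- tibble::tibble(
      sample = meta$sample_id,
      jpm = rgamma(nrow(meta), shape = 8, rate = 8 / mu)
    )
    gamma_glm_disease(vals, meta)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("combined_analysis needs two experiments with disjoint samples", {
  meta <- demo_meta()
  usage <- tidyr::expand_grid(row_id = "e1", sample = meta$sample_id) |>
    dplyr::mutate(jpm = runif(dplyr::n()))
  expect_error(combined_analysis(list(`2019` = usage), meta),
               "at least two")
  expect_error(combined_analysis(list(`2019` = usage, `2020` = usage), meta),
               "disjoint")
})

test_that("combined_analysis fills both tiers and tidies", {
  sim <- simulate_dataset(sim_config(seed = 77))
  q <- quantify_simulated(sim)
  res <- combined_analysis(lapply(q, `[[`, "events"), sim$meta)
  expect_s3_class(res, "usage_difftest")
  expect_setequal(unique(res$experiment), c("2019", "2020"))
  expect_true(all(c("U", "p", "q", "glm_coef", "wald_p", "wald_q",
                    "direction", "direction_combined") %in% names(res)))
  # one glm row per member, constant across that member's experiments
  per <- res |>
    dplyr::group_by(row_id) |>
    dplyr::summarise(n = dplyr::n_distinct(wald_p))
  expect_true(all(per$n == 1))
  g <- glance(res)
  expect_equal(g$n_experiments, 2L)
  expect_s3_class(tidy(res), "tbl_df")
})
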