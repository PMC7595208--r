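test_that("reporter normalization pins the reference to 1 per stratum", {
  ms <- simulate_reporter(seed = 5)
  act <- normalize_reporter(ms)
  ref <- act$value[act$repeat_length == 11]
  expect_equal(ref, rep(1, length(ref)))
  # ratio semantics: firefly/renilla relative to the reference ratio
  one <- ms[ms$promoter == "p4a" & ms$experiment == 1, ]
  r144 <- with(one[one$repeat_length == 144, ], firefly / renilla)
  r11 <- with(one[one$repeat_length == 11, ], firefly / renilla)
  expect_equal(
    act$value[act$promoter == "p4a" & act$experiment == 1 &
                act$repeat_length == 144],
    r144 / r11)
  # scaling all signals of one experiment leaves values unchanged
  ms2 <- ms |>
    dplyr::mutate(firefly = ifelse(experiment == 2, firefly * 10, firefly),
                  renilla = ifelse(experiment == 2, renilla * 10, renilla))
  expect_equal(normalize_reporter(ms2)$value, act$value, tolerance = 1e-12)
  # missing reference is an error naming the stratum
  expect_error(normalize_reporter(ms[ms$repeat_length != 11, ]),
               "p4a / experiment 1")
})

test_that("rm_anova_gg matches the sums-of-squares oracle", {
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rnorm(18, mean = 5), nrow = 3, ncol = 6)
    tab <- tibble::tibble(
      subject = rep(1:3, 6), condition = rep(1:6, each = 3),
      value = as.vector(m)
    )
    fit <- rm_anova_gg(tab)
    oracle <- rm_anova_oracle(m)
    expect_equal(fit$F, oracle$F, tolerance = 1e-8)
    expect_equal(fit$epsilon, oracle$epsilon, tolerance = 1e-8)
    expect_equal(fit$p_gg, oracle$p_gg, tolerance = 1e-8)
  }
})

test_that("rm_anova_gg handles the degenerate and two-level cases", {
  # k = 2: sphericity is automatic, epsilon exactly 1
  tab2 <- tibble::tibble(subject = rep(1:4, 2), condition = rep(1:2, each = 4),
                         value = rnorm(8))
  expect_identical(rm_anova_gg(tab2)$epsilon, 1)
  # identical columns: no condition effect at all
  tab0 <- tibble::tibble(subject = rep(1:3, 4), condition = rep(1:4, each = 3),
                         value = rep(rnorm(3), 4))
  fit0 <- rm_anova_gg(tab0)
  expect_equal(fit0$F, 0)
  expect_equal(fit0$p_gg, 1)
  # epsilon bounds on random tables
  set.seed(13)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    tab <- tibble::tibble(subject = rep(1:4, k),
                          condition = rep(seq_len(k), each = 4),
                          value = rnorm(4 * k))
    eps <- rm_anova_gg(tab)$epsilon
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
  }
  # incomplete tables are refused
  expect_error(rm_anova_gg(tab2[-1, ]), "incomplete")
})

test_that("dunnett adjustment brackets and reduces correctly", {
  set.seed(14)
  m <- matrix(rnorm(18, 5), 3, 6)
  m[, 6] <- m[, 6] - 4  # one strongly shifted condition
  tab <- tibble::tibble(subject = rep(1:3, 6),
                        condition = rep(c(11, 25, 31, 54, 67, 144), each = 3),
                        value = as.vector(m))
  dn <- dunnett_vs_control(tab, control = 11)
  expect_equal(nrow(dn), 5)
  # unadjusted <= Dunnett-adjusted <= Bonferroni for every comparison
  unadj <- 2 * pt(-abs(dn$statistic), dn$df)
  expect_true(all(dn$p_adj >= unadj - 1e-4))
  expect_true(all(dn$p_adj <= pmin(1, 5 * unadj) + 1e-4))
  # monotone in the number of comparisons: dropping conditions lowers p
  sub <- dplyr::filter(tab, condition %in% c(11, 54, 144))
  dn_sub <- dunnett_vs_control(sub, control = 11)
  p_full <- dn$p_adj[dn$condition == "144"]
  p_sub <- dn_sub$p_adj[dn_sub$condition == "144"]
  # note: the error estimate changes too, so compare via the same statistic
  expect_lte(
    1 - promusage:::.pmvt_central(abs(dn$statistic[dn$condition == "144"]),
                                  m = 2, df = dn$df[1]),
    p_full + 1e-4)
  # a condition equal to the control is never significant
  tab_eq <- tab
  tab_eq$value[tab_eq$condition == 25] <- tab_eq$value[tab_eq$condition == 11]
  dn_eq <- dunnett_vs_control(tab_eq, control = 11)
  expect_gte(dn_eq$p_adj[dn_eq$condition == "25"], 0.99)
  expect_error(dunnett_vs_control(tab, control = 99), "not present")
})

test_that("single-comparison dunnett equals the paired comparison", {
  set.seed(15)
  tab <- tibble::tibble(subject = rep(1:5, 2),
                        condition = rep(c(11, 144), each = 5),
                        value = rnorm(10, rep(c(1, 0.4), each = 5), 0.1))
  dn <- dunnett_vs_control(tab, control = 11)
  diffs <- tab$value[tab$condition == 144] - tab$value[tab$condition == 11]
  tt <- t.test(diffs)
  expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-10)
})

test_that("simulate_reporter is deterministic and recovers exact folds", {
  a <- simulate_reporter(seed = 6)
  b <- simulate_reporter(seed = 6)
  expect_identical(a, b)
  expect_true(all(c(11, 25, 31, 54, 144) %in% a$repeat_length))
  noiseless <- simulate_reporter(seed = 6, noise_cv = 0)
  act <- normalize_reporter(noiseless)
  v144 <- act$value[act$promoter == "p4a" & act$repeat_length == 144]
  expect_equal(v144, rep(0.30, 3), tolerance = 1e-12)
  v144b <- act$value[act$promoter == "p4abc" & act$repeat_length == 144]
  expect_equal(v144b, rep(0.25, 3), tolerance = 1e-12)
})
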