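#' Normalize dual-luciferase measurements to a reference construct
#'
#' Two-step normalization of firefly reporter signals: first to the
#' co-transfected Renilla signal of the same well (transfection-efficiency
#' control), then to the firefly/Renilla ratio of the reference construct
#' (default: the 11-repeat construct) measured in the same promoter and
#' the same independent experiment. The reference rows therefore come out
#' exactly 1 in every stratum, and rescaling all signals of an experiment
#' by a common factor leaves the values unchanged.
#'
#' @param ms Tibble `promoter`, `repeat_length`, `experiment`, `firefly`,
#'   `renilla` (signals > 0).
#' @param control Reference repeat length (default 11).
#' @return Tibble `promoter`, `repeat_length`, `experiment`, `value`.
#' @export
normalize_reporter <- function(ms, control = 11L) {
  if (any(ms$firefly <= 0 | ms$renilla <= 0)) {
    stop("firefly and renilla signals must be positive", call. = FALSE)
  }
  out <- ms |>
    dplyr::mutate(ratio = .data$firefly / .data$renilla) |>
    dplyr::group_by(.data$promoter, .data$experiment)
  miss <- out |>
    dplyr::summarise(has_ref = any(.data$repeat_length == control),
                     .groups = "drop") |>
    dplyr::filter(!.data$has_ref)
  if (nrow(miss) > 0) {
    stop("missing ", control, "-repeat reference in stratum ",
         miss$promoter[1], " / experiment ", miss$experiment[1],
         call. = FALSE)
  }
  out |>
    dplyr::mutate(
      value = .data$ratio / .data$ratio[.data$repeat_length == control][1]
    ) |>
    dplyr::ungroup() |>
    dplyr::select("promoter", "repeat_length", "experiment", "value")
}

.rm_table <- function(table) {
  # long (subject, condition, value) -> complete subjects x conditions matrix
  need <- c("subject", "condition", "value")
  if (!all(need %in% names(table))) {
    stop("expected columns subject, condition, value", call. = FALSE)
  }
  wide <- table |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) {
    stop("incomplete subjects x conditions table (no imputation is done)",
         call. = FALSE)
  }
  rownames(m) <- as.character(wide$subject)
  m
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard one-way RM-ANOVA on a complete subjects-by-conditions table:
#' the condition effect is tested against the subject-by-condition
#' residual. The Greenhouse-Geisser sphericity correction factor
#' `epsilon` is estimated from the sample covariance matrix of the
#' conditions and shrinks both degrees of freedom; `epsilon` is bounded in
#' `[1/(k-1), 1]` and equals exactly 1 when `k = 2` (two-level sphericity
#' is automatic).
#'
#' @param table Long tibble with columns `subject`, `condition`, `value`,
#'   complete (every subject measured in every condition; >= 2 of each).
#' @return An `rm_anova_gg` object: `F`, `df_num`, `df_den` (uncorrected),
#'   `epsilon`, `p_uncorrected`, `p_gg` (corrected), `mse` and the error
#'   degrees of freedom `df_error`, plus the design sizes.
#' @export
rm_anova_gg <- function(table) {
  m <- .rm_table(table)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions",
                           call. = FALSE)
  grand <- mean(m)
  col_m <- colMeans(m)
  row_m <- rowMeans(m)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_num <- k - 1
  df_den <- (n - 1) * (k - 1)
  mse <- ss_err / df_den

  if (ss_cond <= 0) {
    f <- 0
  } else if (mse <= 0) {
    f <- Inf
  } else {
    f <- (ss_cond / df_num) / mse
  }

  # Greenhouse-Geisser epsilon from the double-centered condition covariance
  s <- stats::cov(m)
  sc <- s - outer(rowMeans(s), rep(1, k)) -
    outer(rep(1, k), colMeans(s)) + mean(s)
  denom <- (k - 1) * sum(sc^2)
  eps <- if (k == 2 || denom <= .Machine$double.eps * sum(diag(sc))^2 ||
             denom == 0) {
    1
  } else {
    sum(diag(sc))^2 / denom
  }
  eps <- min(max(eps, 1 / (k - 1)), 1)

  p_unc <- pf(f, df_num, df_den, lower.tail = FALSE)
  p_gg <- pf(f, df_num * eps, df_den * eps, lower.tail = FALSE)

  structure(
    list(F = f, df_num = df_num, df_den = df_den, epsilon = eps,
         p_uncorrected = p_unc, p_gg = p_gg,
         mse = mse, df_error = df_den,
         n_subjects = n, n_conditions = k,
         condition_means = col_m),
    class = "rm_anova_gg"
  )
}

#' @export
print.rm_anova_gg <- function(x, ...) {
  cat("One-way repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  cat(sprintf("  F(%g, %g) = %.4g, epsilon = %.4f, p(GG) = %.4g\n",
              x$df_num, x$df_den, x$F, x$epsilon, x$p_gg))
  invisible(x)
}

#' @method tidy rm_anova_gg
#' @export
tidy.rm_anova_gg <- function(x, ...) {
  tibble::tibble(
    term = "condition",
    statistic = x$F,
    df_num = x$df_num * x$epsilon,
    df_den = x$df_den * x$epsilon,
    epsilon = x$epsilon,
    p.value = x$p_gg
  )
}

#' @method glance rm_anova_gg
#' @export
glance.rm_anova_gg <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_conditions = x$n_conditions,
    statistic = x$F, epsilon = x$epsilon,
    p.value = x$p_gg, p.uncorrected = x$p_uncorrected
  )
}

# Two-sided equicoordinate multivariate-t probability used by the Dunnett
# adjustment; deterministic (local RNG state) to the pmvt tolerance.
.pmvt_central <- function(q, m, df, rho = 0.5, abseps = 1e-4) {
  corr <- matrix(rho, m, m)
  diag(corr) <- 1
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20201028L)
  as.numeric(mvtnorm::pmvt(
    lower = rep(-q, m), upper = rep(q, m), df = as.integer(df),
    corr = corr, algorithm = mvtnorm::GenzBretz(abseps = abseps)
  ))
}

#' Dunnett's many-to-one comparisons against a control condition
#'
#' Compares each condition of a complete repeated-measures table with the
#' control condition using the pooled within-subject error of the
#' one-way RM-ANOVA ([rm_anova_gg()]). Two-sided adjusted p-values come
#' from the equicoordinate multivariate-t distribution of the comparison
#' statistics (equicorrelated, correlation 1/2 for equal group sizes),
#' evaluated numerically to an absolute tolerance of 1e-4. With a single
#' non-control condition the adjusted p-value reduces to the unadjusted
#' paired comparison.
#'
#' @param table Long tibble `subject`, `condition`, `value`, complete.
#' @param control The control condition (default `11`). Compared against
#'   `as.character(condition)`.
#' @return Tibble `condition`, `estimate` (condition minus control mean),
#'   `statistic`, `df`, `p_adj`.
#' @export
dunnett_vs_control <- function(table, control = 11L) {
  m <- .rm_table(table)
  conds <- colnames(m)
  ctrl <- as.character(control)
  if (!ctrl %in% conds) {
    stop("control condition ", ctrl, " not present", call. = FALSE)
  }
  an <- rm_anova_gg(table)
  n <- nrow(m)
  others <- setdiff(conds, ctrl)
  mdiff <- colMeans(m)[others] - colMeans(m)[ctrl]
  se <- sqrt(2 * an$mse / n)
  tval <- mdiff / se
  df <- an$df_error
  nc <- length(others)
  p_adj <- vapply(tval, function(t0) {
    if (is.nan(t0)) return(1)   # 0/0: no difference, no error variance
    if (!is.finite(t0)) return(0)
    if (nc == 1) {
      2 * pt(-abs(t0), df)
    } else {
      min(1, 1 - .pmvt_central(abs(t0), m = nc, df = df))
    }
  }, numeric(1))
  tibble::tibble(
    condition = others,
    estimate = unname(mdiff),
    statistic = unname(tval),
    df = df,
    p_adj = unname(p_adj)
  )
}

#' Full reporter-assay analysis per promoter panel
#'
#' [normalize_reporter()], then per promoter (panels analyzed
#' independently): RM-ANOVA with Greenhouse-Geisser correction across
#' repeat-length conditions with independent experiments as subjects,
#' followed by [dunnett_vs_control()] against the reference construct.
#'
#' @param ms Raw measurement tibble (see [normalize_reporter()]).
#' @param control Reference repeat length (default 11).
#' @return A list with `activity` (normalized values), `anova` (one
#'   [rm_anova_gg()] glance row per promoter) and `dunnett` (per-promoter
#'   adjusted comparisons).
#' @export
analyze_reporter <- function(ms, control = 11L) {
  act <- normalize_reporter(ms, control = control)
  per_prom <- act |>
    dplyr::group_by(.data$promoter) |>
    dplyr::group_split()
  anova_rows <- purrr::map_dfr(per_prom, function(d) {
    fit <- rm_anova_gg(dplyr::transmute(
      d, subject = .data$experiment,
      condition = .data$repeat_length, value = .data$value))
    dplyr::bind_cols(tibble::tibble(promoter = d$promoter[1]), glance(fit))
  })
  dunnett_rows <- purrr::map_dfr(per_prom, function(d) {
    dn <- dunnett_vs_control(dplyr::transmute(
      d, subject = .data$experiment,
      condition = .data$repeat_length, value = .data$value),
      control = control)
    dplyr::bind_cols(tibble::tibble(promoter = d$promoter[1]), dn)
  })
  list(activity = act, anova = anova_rows, dunnett = dunnett_rows)
}
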