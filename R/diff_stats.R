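#' Mann-Whitney U test (two-sided)
#'
#' The U statistic for group `x` versus group `y` (number of (x, y) pairs
#' with x > y, ties counted 1/2) and its two-sided p-value. The p-value is
#' exact when `min(length(x), length(y)) <= 8` and the pooled data are
#' tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used. At this package's typical group sizes
#' (6-9 per group) the exact branch applies whenever the normalized values
#' are tie-free.
#'
#' @param x,y Numeric vectors, each nonempty.
#' @return A list with elements `U`, `p`, and `exact` (logical).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop("mann_whitney: both groups must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: sort ascending, `q(i) = min_{j >= i}
#' p(j) * m / j`, restored to input order and capped at 1. Invariant to
#' the order of the input vector (permutation equivariant).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

.direction <- function(ctrl, case) {
  d <- median(case) - median(ctrl)
  if (d > 0) "up" else if (d < 0) "down" else "flat"
}

#' Within-experiment differential usage (Mann-Whitney tier)
#'
#' For every family member and every experiment present in `meta`, tests
#' CTRL versus FECD normalized values with [mann_whitney()], then adjusts
#' p-values with [bh_fdr()] across the family's members *within* each
#' experiment (the test family plays the role of one results figure).
#' Direction is the sign of the FECD-minus-CTRL median difference.
#'
#' @param usage Long tibble `row_id`, `sample`, `jpm` (one aggregation
#'   level of a [quantify_usage()] result).
#' @param meta Sample metadata (`sample_id`, `experiment`, `disease`).
#' @param family Character vector of member row ids; default all rows of
#'   `usage`. A member absent from `usage` is an error.
#' @return Tibble `row_id`, `experiment`, `n_ctrl`, `n_case`, `U`, `p`,
#'   `q`, `direction`.
#' @export
within_experiment <- function(usage, meta, family = NULL) {
  meta <- validate_sample_meta(meta)
  family <- family %||% unique(usage$row_id)
  missing <- setdiff(family, unique(usage$row_id))
  if (length(missing) > 0) {
    stop("family member(s) missing from usage table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- usage |>
    dplyr::filter(.data$row_id %in% family) |>
    dplyr::inner_join(meta, by = c(sample = "sample_id"))
  if (dplyr::n_distinct(dat$disease) != 2) {
    stop("within_experiment: both disease levels must be present",
         call. = FALSE)
  }
  res <- dat |>
    dplyr::group_by(.data$row_id, .data$experiment) |>
    dplyr::summarise(
      n_ctrl = sum(.data$disease == "CTRL"),
      n_case = sum(.data$disease == "FECD"),
      test = list(mann_whitney(.data$jpm[.data$disease == "CTRL"],
                               .data$jpm[.data$disease == "FECD"])),
      direction = .direction(.data$jpm[.data$disease == "CTRL"],
                             .data$jpm[.data$disease == "FECD"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      U = purrr::map_dbl(.data$test, "U"),
      p = purrr::map_dbl(.data$test, "p")
    ) |>
    dplyr::select(-"test") |>
    dplyr::group_by(.data$experiment) |>
    dplyr::mutate(q = bh_fdr(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::select("row_id", "experiment", "n_ctrl", "n_case",
                  "U", "p", "q", "direction")
  res
}

#' Gamma GLM disease test for one usage row (Wald tier)
#'
#' Fits `jpm + shift ~ Experiment + Disease + Experiment:Disease` with a
#' Gamma error distribution to the pooled normalized values of both
#' experiments and returns the Disease main-effect coefficient with its
#' two-sided Wald p-value. With the interaction present, the main effect is
#' the disease effect at the reference experiment level (reference =
#' alphabetically first). The +0.01 shift keeps zero values inside the
#' Gamma support and is applied here only, immediately before fitting.
#'
#' The default link is the inverse (the conventional Gamma GLM default);
#' `link = "log"` is available. Non-convergence yields a flagged result
#' with `p = NA` rather than an error; a degenerate design (a disease
#' level or experiment missing, or an empty cell) is an error.
#'
#' @param values Tibble `sample`, `jpm` for one row.
#' @param meta Sample metadata.
#' @param link `"inverse"` or `"log"`.
#' @param shift Positive shift added before fitting (default 0.01).
#' @return List with `coef` (Disease main effect, link scale), `p`
#'   (two-sided Wald), `converged`.
#' @export
gamma_glm_disease <- function(values, meta, link = c("inverse", "log"),
                              shift = 0.01) {
  link <- match.arg(link)
  meta <- validate_sample_meta(meta)
  dat <- dplyr::inner_join(values, meta, by = c(sample = "sample_id"))
  if (any(dat$jpm <= -shift)) {
    stop("values must exceed -shift so shifted values are positive",
         call. = FALSE)
  }
  cells <- table(dat$experiment, dat$disease)
  if (nrow(cells) < 2 || ncol(cells) < 2 || any(cells == 0)) {
    stop("degenerate design: need both experiments and both disease ",
         "levels in every cell", call. = FALSE)
  }
  dat$experiment <- factor(dat$experiment)
  dat$disease <- factor(dat$disease, levels = c("CTRL", "FECD"))
  if (stats::var(dat$jpm) == 0) {
    # constant response: the saturated fit is exact with zero dispersion;
    # there is no disease effect and no evidence against that
    return(list(coef = 0, p = 1, converged = TRUE))
  }
  fit <- tryCatch(
    glm(I(jpm + shift) ~ experiment + disease + experiment:disease,
        family = Gamma(link = link), data = dat),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    est <- if (!is.null(fit)) unname(coef(fit)["diseaseFECD"]) else NA_real_
    return(list(coef = est, p = NA_real_, converged = FALSE))
  }
  sm <- summary(fit)$coefficients
  est <- unname(sm["diseaseFECD", "Estimate"])
  p <- unname(sm["diseaseFECD", 4])
  if (!is.finite(p)) {
    # zero estimated dispersion (e.g. constant response): no evidence of
    # an effect when the estimate itself is nil, otherwise flag as NA
    p <- if (abs(est) < 1e-8) 1 else NA_real_
  }
  list(coef = est, p = p, converged = TRUE)
}

#' Combined two-experiment differential-usage analysis
#'
#' The full two-tier statistic: per experiment, the within-experiment
#' Mann-Whitney tier ([within_experiment()]); across the pooled
#' experiments, the Gamma GLM Wald tier ([gamma_glm_disease()]) per family
#' member, with Benjamini-Hochberg adjustment of the Wald p-values across
#' the family. Sample sets of the experiments must be disjoint and at
#' least two experiments are required.
#'
#' @param usage_list Named list (one element per experiment) of long
#'   `row_id`/`sample`/`jpm` tibbles, e.g. the `events` element of each
#'   experiment's [quantify_usage()] result.
#' @param meta Sample metadata covering all samples.
#' @param family Member row ids; default = rows present in every
#'   experiment's table.
#' @param link Gamma link passed to [gamma_glm_disease()].
#' @return A `usage_difftest` tibble, one row per member x experiment:
#'   `row_id`, `experiment`, `n_ctrl`, `n_case`, `U`, `p`, `q` (the
#'   within-experiment tier), plus per-member `glm_coef`, `wald_p`,
#'   `wald_q`, `converged` (the combined tier, repeated across that
#'   member's rows), `direction` (within-experiment medians) and
#'   `direction_combined` (pooled medians).
#' @export
combined_analysis <- function(usage_list, meta, family = NULL,
                              link = c("inverse", "log")) {
  link <- match.arg(link)
  if (length(usage_list) < 2) {
    stop("combined_analysis needs at least two experiments", call. = FALSE)
  }
  samples <- purrr::map(usage_list, ~ unique(.x$sample))
  if (length(unlist(samples)) != length(unique(unlist(samples)))) {
    stop("experiment sample sets must be disjoint", call. = FALSE)
  }
  family <- family %||%
    purrr::reduce(purrr::map(usage_list, ~ unique(.x$row_id)), intersect)
  meta <- validate_sample_meta(meta)

  mwu <- purrr::map_dfr(usage_list, within_experiment, meta = meta,
                        family = family)

  pooled <- dplyr::bind_rows(usage_list) |>
    dplyr::filter(.data$row_id %in% family)
  glm_tier <- pooled |>
    dplyr::group_by(.data$row_id) |>
    dplyr::summarise(
      fit = list(gamma_glm_disease(
        dplyr::pick("sample", "jpm"), meta, link = link
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      glm_coef = purrr::map_dbl(.data$fit, "coef"),
      wald_p = purrr::map_dbl(.data$fit, "p"),
      converged = purrr::map_lgl(.data$fit, "converged"),
      wald_q = bh_fdr(.data$wald_p)
    ) |>
    dplyr::select(-"fit")

  pooled_dir <- pooled |>
    dplyr::inner_join(meta, by = c(sample = "sample_id")) |>
    dplyr::group_by(.data$row_id) |>
    dplyr::summarise(
      direction_combined = .direction(.data$jpm[.data$disease == "CTRL"],
                                      .data$jpm[.data$disease == "FECD"]),
      .groups = "drop"
    )

  out <- mwu |>
    dplyr::left_join(glm_tier, by = "row_id") |>
    dplyr::left_join(pooled_dir, by = "row_id") |>
    dplyr::arrange(.data$row_id, .data$experiment)
  class(out) <- c("usage_difftest", class(out))
  out
}

#' @method tidy usage_difftest
#' @export
tidy.usage_difftest <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance usage_difftest
#' @export
glance.usage_difftest <- function(x, ...) {
  tibble::tibble(
    n_members = dplyr::n_distinct(x$row_id),
    n_experiments = dplyr::n_distinct(x$experiment),
    n_mwu_q05 = sum(x$q < 0.05, na.rm = TRUE),
    n_wald_q05 = dplyr::n_distinct(x$row_id[!is.na(x$wald_q) &
                                              x$wald_q < 0.05])
  )
}
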