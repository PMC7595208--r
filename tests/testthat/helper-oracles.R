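# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations from first principles and never call
# the code paths they check.

# exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1) group
# assignments of the pooled (tie-free) values
mwu_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (length(y)) / 2
  # two-sided: configurations at least as extreme in |U - mean|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Benjamini-Hochberg step-up, written directly from the formula
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# one-way RM-ANOVA oracle: F from stats::aov with an Error stratum,
# epsilon from the eigenvalues of the double-centered covariance matrix
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    subject = factor(rep(seq_len(n), k)),
    condition = factor(rep(seq_len(k), each = n)),
    value = as.vector(m)
  )
  fit <- stats::aov(value ~ condition + Error(subject / condition), data = df)
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  f <- tab["condition", "F value"]
  # epsilon via eigenvalues of the centered covariance
  s <- stats::cov(m)
  cmat <- diag(k) - 1 / k
  sc <- cmat %*% s %*% cmat
  lam <- eigen(sc, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  p_gg <- stats::pf(f, (k - 1) * eps, (n - 1) * (k - 1) * eps,
                    lower.tail = FALSE)
  list(F = f, epsilon = eps, p_gg = p_gg)
}

# tiny random junction count table in the long format, with assorted
# chromosomes and motifs so every filter branch can fire
random_jx <- function(n_junctions, n_samples, seed) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n_samples))
  jx <- tibble::tibble(
    chrom = sample(c("chr18", "chr2", "chrM"), n_junctions, replace = TRUE),
    donor_start = sort(sample.int(100000, n_junctions)),
    acceptor_end = 0L,
    strand = sample(c("+", "-"), n_junctions, replace = TRUE),
    motif = sample(c("GT/AG", "CT/AC", "non-canonical"), n_junctions,
                   replace = TRUE)
  )
  jx$acceptor_end <- jx$donor_start + sample(50:5000, n_junctions,
                                             replace = TRUE)
  # anchor junction outside the gene region with solid counts in every
  # sample, so no sample's spliced-read total can be zero
  jx <- dplyr::bind_rows(jx, tibble::tibble(
    chrom = "chr2", donor_start = 900000L, acceptor_end = 905000L,
    strand = "+", motif = "GT/AG"
  ))
  tidyr::expand_grid(jx, sample = samples) |>
    dplyr::mutate(count = rnbinom(dplyr::n(), mu = 5, size = 2) +
                    ifelse(chrom == "chr2" & donor_start == 900000L, 100L, 0L))
}

demo_meta <- function() {
  tibble::tibble(
    sample_id = c(paste0("c", 1:6), paste0("f", 1:8)),
    experiment = "2019",
    disease = c(rep("CTRL", 6), rep("FECD", 8))
  )
}
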