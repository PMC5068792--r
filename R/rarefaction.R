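#' Analytic (hypergeometric) rarefaction
#'
#' Expected phylotype richness and its variance in a random subsample of
#' `n` of the `N` sequenced clones, computed from the hypergeometric
#' formulation: with clone counts `N_i` and
#' `q_i = C(N - N_i, n) / C(N, n)` (the probability that phylotype `i` is
#' missed),
#' `E[S_n] = sum_i (1 - q_i)` and
#' `Var[S_n] = sum_i q_i (1 - q_i) +
#'   2 sum_{i<j} (C(N - N_i - N_j, n)/C(N, n) - q_i q_j)`.
#' Binomial coefficients are evaluated in log space so clone totals in the
#' thousands do not overflow.
#'
#' @param counts positive integer clone counts, one per phylotype.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return List with `expected` and `variance`.
#' @export
rarefy_richness <- function(counts, n) {
  stopifnot(all(counts > 0), all(counts == round(counts)))
  N <- sum(counts)
  if (n < 1 || n > N) stop("subsample size out of range [1, ", N, "]",
                           call. = FALSE)
  lden <- lchoose(N, n)
  q <- ifelse(N - counts >= n, exp(lchoose(N - counts, n) - lden), 0)
  expected <- sum(1 - q)
  s <- length(counts)
  var_term <- sum(q * (1 - q))
  if (s >= 2) {
    for (i in seq_len(s - 1)) {
      for (j in seq(i + 1, s)) {
        rem <- N - counts[i] - counts[j]
        qij <- if (rem >= n) exp(lchoose(rem, n) - lden) else 0
        var_term <- var_term + 2 * (qij - q[i] * q[j])
      }
    }
  }
  list(expected = expected, variance = max(var_term, 0))
}

#' Rarefaction curve with 95% confidence band
#'
#' Applies [rarefy_richness] over a grid of subsample sizes.
#'
#' @param counts positive integer clone counts per phylotype.
#' @param step grid step for the subsample size (default 1).
#' @return Data frame of class `rarefaction_curve` with columns `n`,
#'   `expected`, `variance`, `ci95` (the half-width `1.96 * sqrt(var)`).
#'   The final point (`n = N`, always included) has expected richness equal
#'   to the observed richness and zero variance.
#' @export
rarefaction_curve <- function(counts, step = 1) {
  N <- sum(counts)
  grid <- unique(c(seq(1, N, by = step), N))
  res <- lapply(grid, function(n) rarefy_richness(counts, n))
  out <- data.frame(
    n = grid,
    expected = vapply(res, `[[`, numeric(1), "expected"),
    variance = vapply(res, `[[`, numeric(1), "variance"))
  out$ci95 <- 1.96 * sqrt(out$variance)
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Sampling-sufficiency criterion from the rarefaction confidence band
#'
#' Sequencing depth is judged sufficient when the 95% confidence-interval
#' half-width of rarefied richness falls within a threshold (the study
#' design rule: within +/- 0.4 phylotype). The half-width is evaluated at
#' the penultimate subsample size `n = N - 1` by default (at `n = N` it is
#' identically zero), or at a fixed fraction of `N`.
#'
#' @param counts positive integer clone counts per phylotype.
#' @param threshold half-width threshold in phylotypes (default 0.4).
#' @param at `"penultimate"` or `"fraction"`.
#' @param fraction evaluation point as a fraction of `N` when
#'   `at = "fraction"` (default 0.9).
#' @return List with `sufficient` (logical), `ci_halfwidth`, `at_n`.
#' @export
sufficiency_check <- function(counts, threshold = 0.4,
                              at = c("penultimate", "fraction"),
                              fraction = 0.9) {
  at <- match.arg(at)
  N <- sum(counts)
  stopifnot(N >= 2)
  at_n <- if (at == "penultimate") N - 1 else max(1, floor(fraction * N))
  res <- rarefy_richness(counts, at_n)
  hw <- 1.96 * sqrt(res$variance)
  list(sufficient = hw <= threshold, ci_halfwidth = hw, at_n = at_n)
}
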