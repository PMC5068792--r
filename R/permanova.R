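#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic by permuting
#' group labels. With `a` groups and `N` units,
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `pseudo-F = ((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`.
#' The permutation p-value uses the add-one correction; with
#' `exact = TRUE` all `N!` label permutations are enumerated instead
#' (feasible for `N <= 8`) and the p-value is the exact proportion of
#' permutations with `F >= F_observed` (the identity included).
#'
#' @param d a `stats::dist` object or symmetric distance matrix.
#' @param groups group labels, one per unit.
#' @param n_perm number of random permutations (default 9999).
#' @param seed optional integer seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return Object of class `permanova_result` with a one-row `terms` data
#'   frame (`term`, `df`, `ss`, `pseudo_f`, `p`), plus `n_perm` and `seed`.
#' @export
permanova_oneway <- function(d, groups, n_perm = 9999, seed = NULL,
                             exact = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  a <- length(tab)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  if (all(tab < 2)) stop("need at least one group with >= 2 members",
                         call. = FALSE)
  fstat <- function(perm) {
    g <- groups[perm]
    ss_within <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- dm[idx, idx]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
      }
    }
    ss_total <- sum(dm[upper.tri(dm)]^2) / n
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- fstat(seq_len(n))
  if (exact) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, fstat)
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- replicate(n_perm, fstat(sample.int(n)))
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }
  ss_total <- sum(dm[upper.tri(dm)]^2) / n
  terms <- data.frame(term = "groups", df = a - 1,
                      ss = NA_real_, pseudo_f = f_obs, p = p)
  structure(list(terms = terms, n_perm = n_perm_used,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 exact = exact),
            class = "permanova_result")
}

#' Two-way crossed PERMANOVA on a distance matrix
#'
#' Distance-based partition of a balanced crossed two-factor design into
#' main effects, interaction and residual, via the Gower-centered inner
#' product matrix `G = -1/2 J D2 J` (with `D2` the squared dissimilarities
#' and `J` the centering matrix) and hat matrices of the factor model
#' matrices: `SS(term) = tr(H_term G)` with the interaction taken as the
#' full-model SS minus the main effects. Each term's pseudo-F is its mean
#' square over the residual mean square; p-values come from unrestricted
#' permutation of the units (rows/columns of the distance matrix), with
#' the add-one correction.
#'
#' @param d a `stats::dist` or symmetric distance matrix.
#' @param factor_a,factor_b factor labels, one per unit; the design must be
#'   balanced and fully crossed.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @return Object of class `permanova_result`; `terms` has one row per
#'   term (A, B, interaction, residual) with `df`, `ss`, `pseudo_f`, `p`.
#' @export
permanova_twoway <- function(d, factor_a, factor_b, n_perm = 9999,
                             seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  stopifnot(length(fa) == n, length(fb) == n)
  cell <- table(fa, fb)
  if (length(unique(as.vector(cell))) != 1 || any(cell == 0)) {
    stop("design must be balanced and fully crossed", call. = FALSE)
  }
  a <- nlevels(fa)
  b <- nlevels(fb)
  df_a <- a - 1
  df_b <- b - 1
  df_ab <- df_a * df_b
  df_res <- n - a * b
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (dm^2) %*% J
  hat <- function(X) X %*% solve(crossprod(X), t(X))
  H_a <- hat(stats::model.matrix(~fa))
  H_b <- hat(stats::model.matrix(~fb))
  H_full <- hat(stats::model.matrix(~ fa * fb))
  ss <- function(G) {
    ss_tot <- sum(diag(G))
    ss_a <- sum(diag(H_a %*% G))
    ss_b <- sum(diag(H_b %*% G))
    ss_full <- sum(diag(H_full %*% G))
    c(a = ss_a, b = ss_b, ab = ss_full - ss_a - ss_b, res = ss_tot - ss_full)
  }
  fstats <- function(s) {
    ms_res <- s[["res"]] / df_res
    c(s[["a"]] / df_a, s[["b"]] / df_b, s[["ab"]] / df_ab) / ms_res
  }
  s_obs <- ss(G)
  f_obs <- fstats(s_obs)
  if (!is.null(seed)) set.seed(seed)
  exceed <- c(0L, 0L, 0L)
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    f_p <- fstats(ss(G[perm, perm]))
    exceed <- exceed + (f_p >= f_obs - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)
  terms <- data.frame(
    term = c("factor_a", "factor_b", "interaction", "residual"),
    df = c(df_a, df_b, df_ab, df_res),
    ss = unname(s_obs),
    pseudo_f = c(f_obs, NA_real_),
    p = c(p, NA_real_))
  structure(list(terms = terms, n_perm = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 exact = FALSE),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (", x$n_perm, if (isTRUE(x$exact)) " exact" else "",
      " permutations)\n", sep = "")
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices over the same units, tested by permuting the unit labels of
#' the second matrix. The add-one-corrected p-value is one-sided for
#' positive association; with `exact = TRUE` all `N!` permutations are
#' enumerated and the exact proportion reported.
#'
#' @param d1,d2 `stats::dist` objects or symmetric matrices on the same
#'   units (at least 4).
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @param exact enumerate all permutations (feasible for `N <= 8`).
#' @return Object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL, exact = FALSE) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  n <- nrow(m1)
  stopifnot(nrow(m2) == n)
  if (n < 4) stop("need at least 4 units", call. = FALSE)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (stats::sd(v1) == 0 || stats::sd(m2[lt]) == 0) {
    stop("zero variance in a distance triangle", call. = FALSE)
  }
  rstat <- function(perm) stats::cor(v1, m2[perm, perm][lt])
  r_obs <- rstat(seq_len(n))
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, rstat)
    p <- mean(r_perm >= r_obs - 1e-12)
    n_perm_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- replicate(n_perm, rstat(sample.int(n)))
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm_used,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d%s permutations)\n",
              x$r, x$p, x$n_perm, if (isTRUE(x$exact)) " exact" else ""))
  invisible(x)
}

# all n! permutations of 1..n as rows (n <= 8)
all_permutations <- function(n) {
  stopifnot(n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}
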