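#' Fixed-fixed null-model samples of a binary matrix
#'
#' Draws randomized binary matrices with both row and column marginal
#' totals identical to the input ("fixed-fixed" constraint), using a
#' Markov chain started at the observed matrix. Two samplers are provided:
#' the curveball algorithm (default), which trades the non-shared elements
#' of two randomly chosen rows, and the classic checkerboard swap, which
#' flips randomly located 2x2 checkerboard submatrices. Successive returned
#' matrices are separated by `thin` accepted perturbations after a burn-in.
#'
#' @param m binary matrix (0/1) without all-zero rows or columns.
#' @param n number of matrices to return.
#' @param seed optional integer seed.
#' @param algorithm `"curveball"` or `"swap"`.
#' @param burn_in accepted perturbations before the first sample; default
#'   `5 * max(nrow, ncol)`.
#' @param thin accepted perturbations between samples (default 10).
#' @return List of `n` binary matrices, each with the input's margins. If
#'   the matrix admits no perturbation (e.g. a full matrix), `n` copies of
#'   the input are returned with a warning.
#' @export
sample_fixed_fixed <- function(m, n, seed = NULL,
                               algorithm = c("curveball", "swap"),
                               burn_in = NULL, thin = 10) {
  algorithm <- match.arg(algorithm)
  b <- as.matrix(m)
  if (!all(b %in% c(0, 1))) stop("matrix must be binary", call. = FALSE)
  if (any(rowSums(b) == 0) || any(colSums(b) == 0)) {
    stop("matrix must have no all-zero rows or columns", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- 5 * max(dim(b))
  if (!has_checkerboard(b)) {
    warning("matrix admits no margin-preserving perturbation; ",
            "returning copies of the input")
    return(replicate(n, b, simplify = FALSE))
  }
  if (algorithm == "curveball") {
    curveball_chain(b, n, burn_in, thin)
  } else {
    swap_chain(b, n, burn_in, thin)
  }
}

# a fixed-fixed ensemble has >1 member iff some 2x2 checkerboard exists,
# i.e. two rows each hold a presence the other lacks
has_checkerboard <- function(b) {
  nr <- nrow(b)
  if (nr < 2 || ncol(b) < 2) return(FALSE)
  for (i in seq_len(nr - 1)) {
    for (j in seq(i + 1, nr)) {
      if (any(b[i, ] > b[j, ]) && any(b[j, ] > b[i, ])) return(TRUE)
    }
  }
  FALSE
}

curveball_chain <- function(b, n, burn_in, thin) {
  nr <- nrow(b)
  rows <- lapply(seq_len(nr), function(i) which(b[i, ] > 0))
  trade <- function() {
    ij <- sample.int(nr, 2)
    a <- rows[[ij[1]]]
    d <- rows[[ij[2]]]
    shared <- intersect(a, d)
    only_a <- setdiff(a, shared)
    only_d <- setdiff(d, shared)
    pool <- c(only_a, only_d)
    if (length(only_a) == 0 || length(only_d) == 0) return(FALSE)
    pick <- sample(pool)
    rows[[ij[1]]] <<- c(shared, pick[seq_along(only_a)])
    rows[[ij[2]]] <<- c(shared, pick[-seq_along(only_a)])
    TRUE
  }
  advance <- function(k) {
    done <- 0
    while (done < k) if (trade()) done <- done + 1
  }
  out <- vector("list", n)
  advance(burn_in)
  for (s in seq_len(n)) {
    advance(thin)
    mat <- matrix(0, nrow = nr, ncol = ncol(b), dimnames = dimnames(b))
    for (i in seq_len(nr)) mat[i, rows[[i]]] <- 1
    out[[s]] <- mat
  }
  out
}

swap_chain <- function(b, n, burn_in, thin) {
  nr <- nrow(b)
  nc <- ncol(b)
  cur <- b
  swap_once <- function() {
    ij <- sample.int(nr, 2)
    kl <- sample.int(nc, 2)
    sub <- cur[ij, kl]
    if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
        sub[1, 1] != sub[1, 2]) {
      cur[ij, kl] <<- sub[, 2:1]
      return(TRUE)
    }
    FALSE
  }
  advance <- function(k) {
    done <- 0
    while (done < k) if (swap_once()) done <- done + 1
  }
  out <- vector("list", n)
  advance(burn_in)
  for (s in seq_len(n)) {
    advance(thin)
    out[[s]] <- cur
  }
  out
}

#' Quantitative null-model samples of a count matrix
#'
#' Extends the fixed-fixed constraint to quantitative matrices. The
#' default scheme, `"margins_fixed"`, draws random count tables with the
#' observed row and column totals (Patefield's algorithm via
#' [stats::r2dtable]) -- the direct quantitative analogue of the
#' both-margins-fixed binary null. When the observed matrix is a
#' percentage-normalized transform of an underlying count matrix, pass the
#' counts via `counts`; draws are taken on the counts and rescaled
#' column-wise onto the observed matrix's scale. Alternative schemes:
#' `"skeleton_shuffle"` randomizes the binary skeleton under the binary
#' fixed-fixed constraint with [sample_fixed_fixed] and scatters the
#' multiset of observed positive values uniformly over the occupied cells
#' (preserving the zero-cell count and the value multiset);
#' `"cell_permute_within_rows"` permutes each row's cells within the row.
#'
#' @param m non-negative matrix.
#' @param n number of matrices.
#' @param seed optional integer seed.
#' @param scheme `"margins_fixed"` (default), `"skeleton_shuffle"` or
#'   `"cell_permute_within_rows"`.
#' @param counts for `"margins_fixed"` on a non-integer matrix: the
#'   underlying integer count matrix from which `m` was derived by
#'   column-wise scaling.
#' @param ... further arguments passed to [sample_fixed_fixed]
#'   (skeleton scheme only).
#' @return List of `n` matrices on the scale of `m`.
#' @export
sample_weighted_null <- function(m, n, seed = NULL,
                                 scheme = c("margins_fixed",
                                            "skeleton_shuffle",
                                            "cell_permute_within_rows"),
                                 counts = NULL, ...) {
  scheme <- match.arg(scheme)
  mat <- as.matrix(m)
  if (any(mat < 0)) stop("matrix must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (scheme == "cell_permute_within_rows") {
    return(lapply(seq_len(n), function(s) {
      out <- t(apply(mat, 1, sample))
      dimnames(out) <- dimnames(mat)
      out
    }))
  }
  if (scheme == "margins_fixed") {
    base <- if (is.null(counts)) mat else as.matrix(counts)
    if (any(base != round(base))) {
      stop("margins_fixed requires an integer count matrix; for a ",
           "normalized matrix supply the underlying counts via 'counts'",
           call. = FALSE)
    }
    draws <- stats::r2dtable(n, rowSums(base), colSums(base))
    fac <- colSums(base) / colSums(mat)  # column scale back to m's units
    return(lapply(draws, function(d) {
      out <- sweep(d, 2, fac, "/")
      dimnames(out) <- dimnames(mat)
      out
    }))
  }
  skel <- (mat > 0) * 1
  vals <- mat[mat > 0]
  skels <- sample_fixed_fixed(skel, n, seed = NULL, ...)
  lapply(skels, function(s) {
    out <- s
    out[s > 0] <- sample(vals)
    out
  })
}

#' Monte-Carlo nestedness test with Z-score
#'
#' Computes the observed NODF or weighted NODF of a hypothesis-ordered
#' community matrix and compares it to `n_null` null matrices: the
#' fixed-fixed ensemble ([sample_fixed_fixed]) for NODF on presence data,
#' and the quantitative null ([sample_weighted_null]) for weighted NODF.
#' Null indices are computed under the same imposed row/column order as the
#' observed matrix. The Z-score is
#' `(observed - null mean) / null SD`; Monte-Carlo p-values use the
#' add-one correction `p_upper = (#\{null >= obs\} + 1) / (n_null + 1)`
#' (and analogously `p_lower`), so a significantly positive Z indicates
#' nestedness and a significantly negative Z anti-nestedness.
#'
#' @param m a [community_matrix], ordered per hypothesis (see
#'   [sort_columns_by_gradient], [sort_rows_by_occurrence]).
#' @param metric `"nodf"` or `"wnodf"`.
#' @param axis `"columns"`, `"rows"` or `"both"`.
#' @param n_null number of null matrices (default 1000).
#' @param seed optional integer seed.
#' @param counts for a weighted test on a normalized (non-integer) matrix:
#'   the underlying count matrix, ordered identically to `m` (see
#'   [sample_weighted_null]).
#' @param ... further arguments passed to the null sampler (e.g. `scheme`
#'   for the weighted null, `algorithm` for the binary one).
#' @return An object of class `nestedness_result`: a list with elements
#'   `metric`, `axis`, `observed`, `null_mean`, `null_sd`, `z`, `p_upper`,
#'   `p_lower`, `n_null`, `sampler`, `seed`. `z` is `NA` when the null SD
#'   is zero.
#' @export
nestedness_test <- function(m, metric = c("nodf", "wnodf"),
                            axis = c("columns", "rows", "both"),
                            n_null = 1000, seed = NULL, counts = NULL,
                            ...) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  if (metric == "nodf") {
    if (inherits(m, "community_matrix") && cell_kind(m) != "presence") {
      stop("NODF test requires a presence matrix; use to_presence_absence()",
           call. = FALSE)
    }
    observed <- nodf(m, axis = axis, ordering = "as_given")
    nulls <- sample_fixed_fixed(as.matrix(m), n_null, seed = seed, ...)
    sampler <- "fixed-fixed (curveball)"
    null_vals <- vapply(nulls, function(x) nodf_engine(x, axis, "as_given",
                                                       paired_nodf),
                        numeric(1))
  } else {
    if (inherits(m, "community_matrix") && cell_kind(m) == "presence") {
      stop("weighted NODF test requires a quantitative matrix", call. = FALSE)
    }
    observed <- wnodf(m, axis = axis, ordering = "as_given")
    nulls <- sample_weighted_null(as.matrix(m), n_null, seed = seed,
                                  counts = counts, ...)
    scheme <- list(...)$scheme
    sampler <- paste0("weighted null (",
                      if (is.null(scheme)) "margins_fixed" else scheme, ")")
    null_vals <- vapply(nulls, function(x) nodf_engine(x, axis, "as_given",
                                                       paired_wnodf),
                        numeric(1))
  }
  null_mean <- mean(null_vals)
  null_sd <- stats::sd(null_vals)
  structure(list(
    metric = toupper(metric), axis = axis, observed = observed,
    null_mean = null_mean, null_sd = null_sd,
    z = if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_,
    p_upper = (sum(null_vals >= observed) + 1) / (n_null + 1),
    p_lower = (sum(null_vals <= observed) + 1) / (n_null + 1),
    n_null = n_null, sampler = sampler,
    seed = if (is.null(seed)) NA_integer_ else seed,
    null_values = null_vals
  ), class = "nestedness_result")
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf("%s (%s): observed = %.2f, null = %.2f +/- %.2f\n",
              x$metric, x$axis, x$observed, x$null_mean, x$null_sd))
  cat(sprintf("Z = %s, p(nested) = %.4g, p(anti-nested) = %.4g  [n_null = %d, %s]\n",
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)),
              x$p_upper, x$p_lower, x$n_null, x$sampler))
  invisible(x)
}
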