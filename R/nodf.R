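#' Paired nestedness term for two binary vectors
#'
#' The elementary term of the NODF index for one ordered pair, with the
#' earlier (left) element of the imposed order acting as the nesting
#' reference. Decreasing fill is required strictly: if the right vector's
#' fill is greater than or equal to the left's, the pair contributes 0.
#' Otherwise the term is the percentage of the right vector's presences
#' that also occur in the left vector ("paired overlap").
#'
#' @param left,right binary vectors of equal length; `left` is the
#'   column/row placed earlier in the imposed order.
#' @return A value in `[0, 100]`. An all-zero `right` vector yields 0.
#' @export
paired_nodf <- function(left, right) {
  stopifnot(length(left) == length(right))
  fl <- sum(left > 0)
  fr <- sum(right > 0)
  if (fr == 0 || fr >= fl) return(0)
  100 * sum(left > 0 & right > 0) / fr
}

#' Paired weighted nestedness term for two quantitative vectors
#'
#' Weighted counterpart of [paired_nodf]: the pair contributes 0 unless the
#' right vector's marginal total is strictly smaller than the left's;
#' otherwise the term is the percentage of the right vector's nonzero cells
#' that are strictly smaller than the corresponding left cell. Ties
#' (`right == left > 0`) do not count as nested.
#'
#' @inheritParams paired_nodf
#' @return A value in `[0, 100]`. An all-zero `right` vector yields 0.
#' @export
paired_wnodf <- function(left, right) {
  stopifnot(length(left) == length(right))
  if (sum(right) >= sum(left)) return(0)
  pos <- right > 0
  if (!any(pos)) return(0)
  100 * sum(pos & right < left) / sum(pos)
}

#' NODF nestedness index under an imposed ordering
#'
#' Mean of [paired_nodf] over all ordered pairs along the chosen axis, the
#' earlier element of each pair acting as the nesting reference. With
#' `ordering = "as_given"` the matrix is taken in its current
#' (hypothesis-imposed) row/column order -- e.g. columns sorted by
#' decreasing site pH; with `"by_marginal_total"` rows and columns are
#' first sorted by their marginal totals (descending), the classic
#' definition. `axis = "both"` pools all row pairs and column pairs into a
#' single mean.
#'
#' @param m a presence/absence [community_matrix] (or plain 0/1 matrix).
#' @param axis `"columns"`, `"rows"` or `"both"`.
#' @param ordering `"as_given"` or `"by_marginal_total"`.
#' @return The index, a value in `[0, 100]`.
#' @examples
#' m <- community_matrix(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)),
#'                       cell_kind = "presence")
#' nodf(m, axis = "columns")  # 100: fully nested triangular matrix
#' @export
nodf <- function(m, axis = c("columns", "rows", "both"),
                 ordering = c("as_given", "by_marginal_total")) {
  axis <- match.arg(axis)
  ordering <- match.arg(ordering)
  if (inherits(m, "community_matrix") && cell_kind(m) != "presence") {
    stop("NODF requires a presence/absence matrix; use to_presence_absence()",
         call. = FALSE)
  }
  b <- (as.matrix(m) > 0) * 1
  if (!all(m == b)) stop("NODF requires a 0/1 matrix", call. = FALSE)
  nodf_engine(b, axis, ordering, paired_nodf)
}

#' Weighted NODF index under an imposed ordering
#'
#' Mean of [paired_wnodf] over all ordered pairs along the chosen axis.
#' Arguments as in [nodf]; the matrix holds counts or relative abundances.
#'
#' @inheritParams nodf
#' @param m a quantitative [community_matrix] (counts or percentages) or
#'   plain non-negative matrix.
#' @return The index, a value in `[0, 100]`.
#' @export
wnodf <- function(m, axis = c("columns", "rows", "both"),
                  ordering = c("as_given", "by_marginal_total")) {
  axis <- match.arg(axis)
  ordering <- match.arg(ordering)
  nodf_engine(as.matrix(m), axis, ordering, paired_wnodf)
}

nodf_engine <- function(mat, axis, ordering, pair_fun) {
  if (ordering == "by_marginal_total") {
    mat <- mat[order(-rowSums(mat)), order(-colSums(mat)), drop = FALSE]
  }
  binary <- identical(pair_fun, paired_nodf)
  vals <- numeric(0)
  if (axis %in% c("columns", "both")) {
    if (ncol(mat) < 2 && axis == "columns") {
      stop("need at least 2 columns for column-wise nestedness", call. = FALSE)
    }
    if (ncol(mat) >= 2) {
      vals <- c(vals, if (binary) paired_terms_binary(mat) else
        paired_terms_weighted(mat))
    }
  }
  if (axis %in% c("rows", "both")) {
    if (nrow(mat) < 2 && axis == "rows") {
      stop("need at least 2 rows for row-wise nestedness", call. = FALSE)
    }
    if (nrow(mat) >= 2) {
      vals <- c(vals, if (binary) paired_terms_binary(t(mat)) else
        paired_terms_weighted(t(mat)))
    }
  }
  if (length(vals) == 0) stop("no pairs along the requested axis", call. = FALSE)
  mean(vals)
}

# all column-pair terms (i < j, i as nesting reference), vectorized
paired_terms_binary <- function(b) {
  nc <- ncol(b)
  shared <- crossprod(b)
  fill <- colSums(b)
  out <- numeric(nc * (nc - 1) / 2)
  k <- 0L
  for (i in seq_len(nc - 1)) {
    j <- seq(i + 1, nc)
    v <- ifelse(fill[j] > 0 & fill[j] < fill[i], 100 * shared[i, j] / fill[j], 0)
    out[k + seq_along(j)] <- v
    k <- k + length(j)
  }
  out
}

paired_terms_weighted <- function(m) {
  nc <- ncol(m)
  tot <- colSums(m)
  out <- numeric(nc * (nc - 1) / 2)
  k <- 0L
  for (i in seq_len(nc - 1)) {
    for (j in seq(i + 1, nc)) {
      k <- k + 1L
      if (tot[j] >= tot[i]) next
      pos <- m[, j] > 0
      npos <- sum(pos)
      if (npos == 0) next
      out[k] <- 100 * sum(m[pos, j] < m[pos, i]) / npos
    }
  }
  out
}
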