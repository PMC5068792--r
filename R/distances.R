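#' Pairwise community dissimilarities
#'
#' Elementary dissimilarities between two assemblages:
#' `jaccard_distance` on presence/absence (`1 - a/(a+b+c)`),
#' `morisita_horn_distance` on counts (insensitive to total abundance), and
#' `ruzicka_distance` on abundances (`1 - sum(min)/sum(max)`, the
#' quantitative Jaccard analogue). All lie in `[0, 1]`, are symmetric, and
#' are zero for identical (or, for Morisita-Horn, proportional)
#' assemblages.
#'
#' @param x,y non-negative vectors of equal length.
#' @return A dissimilarity in `[0, 1]`.
#' @export
jaccard_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  px <- x > 0
  py <- y > 0
  n <- sum(px | py)
  if (n == 0) stop("empty union: distance undefined", call. = FALSE)
  1 - sum(px & py) / n
}

#' @rdname jaccard_distance
#' @export
morisita_horn_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  X <- sum(x)
  Y <- sum(y)
  if (X == 0 || Y == 0) stop("zero total: distance undefined", call. = FALSE)
  1 - 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' @rdname jaccard_distance
#' @export
ruzicka_distance <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  denom <- sum(pmax(x, y))
  if (denom == 0) stop("both vectors all-zero: distance undefined",
                       call. = FALSE)
  1 - sum(pmin(x, y)) / denom
}

#' Distance matrix between the units of a community matrix
#'
#' Applies one of the pairwise dissimilarities to every pair of columns
#' (default; sites/groups) or rows of a matrix, returning a `dist` object.
#'
#' @param m matrix (units along the chosen margin).
#' @param method `"jaccard"`, `"morisita_horn"` or `"ruzicka"`.
#' @param along `"columns"` or `"rows"`: which margin holds the units.
#' @return A `stats::dist` object with unit labels.
#' @export
community_distance <- function(m,
                               method = c("jaccard", "morisita_horn",
                                          "ruzicka"),
                               along = c("columns", "rows")) {
  method <- match.arg(method)
  along <- match.arg(along)
  mat <- as.matrix(m)
  if (along == "columns") mat <- t(mat)
  f <- switch(method, jaccard = jaccard_distance,
              morisita_horn = morisita_horn_distance,
              ruzicka = ruzicka_distance)
  nu <- nrow(mat)
  out <- matrix(0, nu, nu, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(nu - 1)) {
    for (j in seq(i + 1, nu)) {
      out[i, j] <- out[j, i] <- f(mat[i, ], mat[j, ])
    }
  }
  stats::as.dist(out)
}

#' Absolute-difference distance for an environmental variable
#'
#' @param values named numeric vector (e.g. site mean pH, treated as a
#'   plain real number).
#' @return A `stats::dist` of absolute pairwise differences.
#' @export
env_distance <- function(values) {
  stats::dist(matrix(values, dimnames = list(names(values), NULL)),
              method = "manhattan")
}
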