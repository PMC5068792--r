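#' Similarity-difference-replacement decomposition of one pair
#'
#' For two presence/absence vectors, let `a` be the number of shared
#' species, `b` and `c` the numbers unique to each side, and
#' `n = a + b + c`. Then similarity `S = a/n` (the Jaccard index),
#' richness difference `D = |b - c|/n`, and replacement
#' `R = 2 min(b, c)/n`. The three components always sum to 1, placing each
#' pair on a simplex; their complements `1 - S` (turnover), `1 - D`
#' (agreement) and `1 - R` (nestedness) are the interpretive axes.
#'
#' @param x,y binary vectors of equal length with a non-empty union.
#' @return A list with components `s`, `d`, `r`.
#' @export
sdr_binary_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  px <- x > 0
  py <- y > 0
  a <- sum(px & py)
  b <- sum(px & !py)
  cc <- sum(!px & py)
  n <- a + b + cc
  if (n == 0) stop("empty union: pair undefined", call. = FALSE)
  list(s = a / n, d = abs(b - cc) / n, r = 2 * min(b, cc) / n)
}

#' Abundance-based similarity-difference-replacement of one pair
#'
#' Quantitative analogue of [sdr_binary_pair] built on the Ruzicka index:
#' with `A = sum(min(x, y))`, `B = sum(max(x - y, 0))`,
#' `C = sum(max(y - x, 0))` and `n = A + B + C`, similarity `S = A/n`
#' (Ruzicka), difference `D = |B - C|/n`, replacement `R = 2 min(B, C)/n`.
#' On 0/1 vectors this reduces exactly to the binary form.
#'
#' @param x,y non-negative vectors of equal length, not both all-zero.
#' @return A list with components `s`, `d`, `r`.
#' @export
sdr_abundance_pair <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  a <- sum(pmin(x, y))
  b <- sum(pmax(x - y, 0))
  cc <- sum(pmax(y - x, 0))
  n <- a + b + cc
  if (n == 0) stop("both vectors all-zero: pair undefined", call. = FALSE)
  list(s = a / n, d = abs(b - cc) / n, r = 2 * min(b, cc) / n)
}

#' S-D-R simplex decomposition over all column pairs
#'
#' Computes the similarity/difference/replacement triple for every
#' unordered pair of columns (sites) of a community matrix and summarizes
#' the mean percentage contributions of turnover (`1 - S`), agreement
#' (`1 - D`) and nestedness (`1 - R`). Because `(1-S) + (1-D) + (1-R) = 2`
#' for every pair, the three summary percentages sum to 200.
#'
#' @param m a [community_matrix] with at least two columns.
#' @param mode `"binary"` (presence/absence components) or `"abundance"`
#'   (Ruzicka-based components). Binary mode binarizes the matrix first.
#' @param aggregate `"mean"` (default): unweighted mean of the pairwise
#'   relativized indices; `"pooled"`: components summed over pairs before
#'   relativizing (a totals-weighted variant).
#' @return An object of class `sdr_result`: list with `pairs` (data frame
#'   of per-pair triples), `pct_turnover`, `pct_agreement`,
#'   `pct_nestedness`, `mode`. Degenerate pairs (empty union) are excluded
#'   with a message.
#' @export
sdr_simplex <- function(m, mode = c("binary", "abundance"),
                        aggregate = c("mean", "pooled")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  mat <- as.matrix(m)
  if (ncol(mat) < 2) stop("need at least 2 columns", call. = FALSE)
  if (mode == "binary") mat <- (mat > 0) * 1
  pair_fun <- if (mode == "binary") sdr_binary_pair else sdr_abundance_pair
  nc <- ncol(mat)
  rows <- list()
  raw <- list()
  dropped <- 0L
  for (i in seq_len(nc - 1)) {
    for (j in seq(i + 1, nc)) {
      x <- mat[, i]
      y <- mat[, j]
      if (all(x == 0) && all(y == 0)) {
        dropped <- dropped + 1L
        next
      }
      tr <- pair_fun(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        group_i = colnames(mat)[i], group_j = colnames(mat)[j],
        s = tr$s, d = tr$d, r = tr$r)
      raw[[length(raw) + 1L]] <- c(a = sum(pmin(x, y)),
                                   b = sum(pmax(x - y, 0)),
                                   c = sum(pmax(y - x, 0)))
    }
  }
  if (dropped > 0) message("excluded ", dropped, " degenerate pair(s)")
  pairs <- do.call(rbind, rows)
  if (aggregate == "mean") {
    pct_turn <- mean(1 - pairs$s) * 100
    pct_agree <- mean(1 - pairs$d) * 100
    pct_nest <- mean(1 - pairs$r) * 100
  } else {
    # totals-weighted: pool the unrelativized components, then relativize
    tot <- Reduce(`+`, raw)
    n <- sum(tot)
    pct_turn <- (1 - tot[["a"]] / n) * 100
    pct_agree <- (1 - abs(tot[["b"]] - tot[["c"]]) / n) * 100
    pct_nest <- (1 - 2 * min(tot[["b"]], tot[["c"]]) / n) * 100
  }
  structure(list(pairs = pairs, pct_turnover = pct_turn,
                 pct_agreement = pct_agree, pct_nestedness = pct_nest,
                 mode = mode, aggregate = aggregate),
            class = "sdr_result")
}

#' @export
print.sdr_result <- function(x, ...) {
  cat(sprintf("S-D-R simplex (%s mode, %d pairs):\n", x$mode, nrow(x$pairs)))
  cat(sprintf("  turnover (1-S): %.1f%%  agreement (1-D): %.1f%%  nestedness (1-R): %.1f%%\n",
              x$pct_turnover, x$pct_agreement, x$pct_nestedness))
  invisible(x)
}
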