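# Independent brute-force oracles, written straight from the definitions
# and kept free of the package's vectorized code paths.

# NODF: mean over ordered pairs of 100 * overlap / fill(right), zeroed
# unless fill decreases strictly.
oracle_nodf <- function(mat, axis = "columns") {
  pair_term <- function(l, r) {
    fl <- sum(l > 0)
    fr <- sum(r > 0)
    if (fr == 0 || fr >= fl) return(0)
    shared <- 0
    for (k in seq_along(l)) if (l[k] > 0 && r[k] > 0) shared <- shared + 1
    100 * shared / fr
  }
  terms <- c()
  if (axis %in% c("columns", "both")) {
    for (i in seq_len(ncol(mat) - 1)) {
      for (j in seq(i + 1, ncol(mat))) {
        terms <- c(terms, pair_term(mat[, i], mat[, j]))
      }
    }
  }
  if (axis %in% c("rows", "both")) {
    for (i in seq_len(nrow(mat) - 1)) {
      for (j in seq(i + 1, nrow(mat))) {
        terms <- c(terms, pair_term(mat[i, ], mat[j, ]))
      }
    }
  }
  mean(terms)
}

# weighted NODF: zeroed unless the marginal total decreases strictly;
# counts right cells that are positive and strictly below the left cell.
oracle_wnodf <- function(mat, axis = "columns") {
  pair_term <- function(l, r) {
    if (sum(r) >= sum(l)) return(0)
    npos <- sum(r > 0)
    if (npos == 0) return(0)
    cnt <- 0
    for (k in seq_along(r)) if (r[k] > 0 && r[k] < l[k]) cnt <- cnt + 1
    100 * cnt / npos
  }
  terms <- c()
  if (axis %in% c("columns", "both")) {
    for (i in seq_len(ncol(mat) - 1)) {
      for (j in seq(i + 1, ncol(mat))) {
        terms <- c(terms, pair_term(mat[, i], mat[, j]))
      }
    }
  }
  if (axis %in% c("rows", "both")) {
    for (i in seq_len(nrow(mat) - 1)) {
      for (j in seq(i + 1, nrow(mat))) {
        terms <- c(terms, pair_term(mat[i, ], mat[j, ]))
      }
    }
  }
  mean(terms)
}

# exact rarefaction by enumerating every size-n subsample of the N clones
oracle_rarefy <- function(counts, n) {
  ids <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(ids), n)
  rich <- apply(subs, 2, function(ix) length(unique(ids[ix])))
  list(expected = mean(rich),
       variance = mean(rich^2) - mean(rich)^2)
}

# all n! permutations of 1..n, small n only
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# one-way PERMANOVA pseudo-F computed straight from the printed formula
oracle_pseudo_f <- function(dm, g) {
  n <- nrow(dm)
  lev <- unique(g)
  a <- length(lev)
  ss_tot <- sum(dm[upper.tri(dm)]^2) / n
  ss_w <- 0
  for (l in lev) {
    ix <- which(g == l)
    if (length(ix) > 1) {
      sub <- dm[ix, ix]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(ix)
    }
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# all 0/1 matrices with the given margins, by exhaustive search
oracle_fixed_fixed_ensemble <- function(rs, cs) {
  nr <- length(rs)
  nc <- length(cs)
  out <- list()
  for (code in 0:(2^(nr * nc) - 1)) {
    m <- matrix(as.integer(intToBits(code)[seq_len(nr * nc)]), nr, nc)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) {
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

# random binary matrix with no all-zero rows or columns
random_binary_matrix <- function(nr, nc, fill = 0.5) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, fill), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# small sample table used across core-data tests
toy_sample_table <- function() {
  sample_table(data.frame(
    sample_id = c("a1", "a1", "a2", "b1", "b1", "b2"),
    group = c("acid", "acid", "acid", "neutral", "neutral", "neutral"),
    ph = c(3.5, 3.5, 3.8, 6.8, 6.8, 7.0),
    phylotype = c("Rhz1", "Glo1", "Rhz1", "Rhz1", "Aca1", "Aca1"),
    count = c(3, 2, 4, 1, 5, 2)))
}

# strip community_matrix attributes for raw-cell comparisons
unclass_cells <- function(m) {
  matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
}
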