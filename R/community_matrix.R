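#' Phylotype-by-group community matrix
#'
#' Rows are phylotypes, columns are groups (sites or treatments). Cells hold
#' occurrence counts (number of samples in the group in which a phylotype
#' occurred), percentage relative abundances, or 0/1 presences, recorded in
#' the `cell_kind` attribute. Two further attributes drive the
#' hypothesis-imposed ordering used by the nestedness indices:
#' `col_gradient` (one gradient value per column, e.g. the site mean pH) and
#' `row_occurrence` (total number of samples, over all groups, in which each
#' phylotype occurred). All-zero rows and columns are dropped at
#' construction with a message.
#'
#' @param cells non-negative numeric matrix with row and column names.
#' @param cell_kind one of `"count"`, `"relative_abundance_percent"`,
#'   `"presence"`.
#' @param col_gradient numeric vector, one value per column (optional).
#' @param row_occurrence non-negative integer vector, one per row (optional).
#' @return A matrix of class `community_matrix`.
#' @export
community_matrix <- function(cells,
                             cell_kind = c("count",
                                           "relative_abundance_percent",
                                           "presence"),
                             col_gradient = NULL, row_occurrence = NULL) {
  cell_kind <- match.arg(cell_kind)
  cells <- as.matrix(cells)
  if (is.null(rownames(cells))) rownames(cells) <- paste0("p", seq_len(nrow(cells)))
  if (is.null(colnames(cells))) colnames(cells) <- paste0("g", seq_len(ncol(cells)))
  if (any(cells < 0)) stop("community matrix cells must be non-negative",
                           call. = FALSE)
  if (cell_kind == "presence" && !all(cells %in% c(0, 1))) {
    stop("presence matrix cells must be 0 or 1", call. = FALSE)
  }
  if (cell_kind == "relative_abundance_percent" && any(cells > 100)) {
    stop("relative abundances must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(col_gradient)) {
    stopifnot(length(col_gradient) == ncol(cells))
    names(col_gradient) <- colnames(cells)
  }
  if (!is.null(row_occurrence)) {
    stopifnot(length(row_occurrence) == nrow(cells), all(row_occurrence >= 0))
    names(row_occurrence) <- rownames(cells)
  }
  empty_r <- rowSums(cells) == 0
  empty_c <- colSums(cells) == 0
  if (any(empty_r)) {
    message("dropping ", sum(empty_r), " all-zero row(s): ",
            paste(rownames(cells)[empty_r], collapse = ", "))
    cells <- cells[!empty_r, , drop = FALSE]
    if (!is.null(row_occurrence)) row_occurrence <- row_occurrence[!empty_r]
  }
  if (any(empty_c)) {
    message("dropping ", sum(empty_c), " all-zero column(s): ",
            paste(colnames(cells)[empty_c], collapse = ", "))
    cells <- cells[, !empty_c, drop = FALSE]
    if (!is.null(col_gradient)) col_gradient <- col_gradient[!empty_c]
  }
  structure(cells, cell_kind = cell_kind, col_gradient = col_gradient,
            row_occurrence = row_occurrence,
            class = c("community_matrix", class(cells)))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("Community matrix (", attr(x, "cell_kind"), "): ",
      nrow(x), " phylotypes x ", ncol(x), " groups\n", sep = "")
  print(unclass_cm(x))
  invisible(x)
}

unclass_cm <- function(x) {
  attr(x, "cell_kind") <- NULL
  attr(x, "col_gradient") <- NULL
  attr(x, "row_occurrence") <- NULL
  class(x) <- setdiff(class(x), "community_matrix")
  x
}

cell_kind <- function(m) attr(m, "cell_kind")

#' Pool sample-level presences into a group-by-phylotype frequency matrix
#'
#' Presence/absence records of the individual samples are pooled within
#' each group: cell (phylotype, group) is the number of distinct samples in
#' the group in which the phylotype occurred. These pooled frequencies are
#' the "abundance" data of the downstream weighted analyses. The column
#' gradient is the group mean pH, and the row occurrence is the total
#' number of samples (across all groups) in which each phylotype occurred.
#'
#' @param table a [sample_table].
#' @param grouping optional named character vector mapping `sample_id` to a
#'   group, overriding the table's own `group` column (every sample must be
#'   covered).
#' @return A [community_matrix] with `cell_kind = "count"`.
#' @export
pool_to_matrix <- function(table, grouping = NULL) {
  stopifnot(inherits(table, "sample_table"))
  if (nrow(table) == 0) stop("empty sample table", call. = FALSE)
  df <- as.data.frame(table)
  if (!is.null(grouping)) {
    unmapped <- setdiff(unique(df$sample_id), names(grouping))
    if (length(unmapped) > 0) {
      stop("sample(s) not covered by grouping: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    df$group <- unname(grouping[df$sample_id])
  }
  phylos <- unique(df$phylotype)
  grps <- unique(df$group)
  cells <- matrix(0, nrow = length(phylos), ncol = length(grps),
                  dimnames = list(phylos, grps))
  # distinct samples per (phylotype, group); records are unique pairs already
  tab <- table(factor(df$phylotype, levels = phylos),
               factor(df$group, levels = grps))
  cells[] <- as.numeric(tab)
  occ <- rowSums(cells)
  per_sample <- unique(df[, c("sample_id", "group", "ph")])
  grad <- vapply(split(per_sample$ph, factor(per_sample$group, levels = grps)),
                 mean, numeric(1))
  community_matrix(cells, "count", col_gradient = grad, row_occurrence = occ)
}

#' Convert pooled counts to percentage relative abundance
#'
#' Each column is divided by the total number of samples in the group and
#' expressed as a percentage, so that groups with unequal sample numbers
#' become comparable.
#'
#' @param m a [community_matrix] with `cell_kind = "count"`.
#' @param sizes data frame with columns `group` and `n_samples` covering
#'   every column of `m`.
#' @return A [community_matrix] with `cell_kind =
#'   "relative_abundance_percent"`.
#' @export
normalize_relative_abundance <- function(m, sizes) {
  stopifnot(inherits(m, "community_matrix"))
  if (cell_kind(m) != "count") {
    stop("normalization requires a count matrix, got ", cell_kind(m),
         call. = FALSE)
  }
  stopifnot(is.data.frame(sizes), all(c("group", "n_samples") %in% names(sizes)))
  idx <- match(colnames(m), sizes$group)
  if (anyNA(idx)) {
    stop("group size missing for column(s): ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  n <- sizes$n_samples[idx]
  if (any(n == 0)) stop("group size of zero", call. = FALSE)
  cells <- sweep(unclass_cm(m), 2, n, "/") * 100
  community_matrix(cells, "relative_abundance_percent",
                   col_gradient = attr(m, "col_gradient"),
                   row_occurrence = attr(m, "row_occurrence"))
}

#' Convert a community matrix to presence/absence
#'
#' @param m a [community_matrix].
#' @return A [community_matrix] with `cell_kind = "presence"`; cells are 1
#'   where the input was positive. Idempotent.
#' @export
to_presence_absence <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  cells <- (unclass_cm(m) > 0) * 1
  community_matrix(cells, "presence",
                   col_gradient = attr(m, "col_gradient"),
                   row_occurrence = attr(m, "row_occurrence"))
}

#' Impose the gradient hypothesis on the column order
#'
#' Columns are permuted by their gradient value; the default descending
#' order places the highest-pH group leftmost, so that the nestedness
#' hypothesis "lower-pH communities are subsets of higher-pH communities"
#' corresponds to later columns nesting inside earlier ones. Ties are broken
#' by column marginal total (descending), then by label, so the resulting
#' order is deterministic.
#'
#' @param m a [community_matrix] with a `col_gradient` attribute.
#' @param descending sort highest gradient first (default `TRUE`).
#' @return The permuted [community_matrix].
#' @export
sort_columns_by_gradient <- function(m, descending = TRUE) {
  stopifnot(inherits(m, "community_matrix"))
  grad <- attr(m, "col_gradient")
  if (is.null(grad) || anyNA(grad)) {
    stop("column gradient missing", call. = FALSE)
  }
  tot <- colSums(m)
  key <- if (descending) order(-grad, -tot, colnames(m)) else
    order(grad, -tot, colnames(m))
  permute_cm(m, rows = seq_len(nrow(m)), cols = key)
}

#' Sort rows by phylotype occurrence
#'
#' Rows are permuted by total occurrence (number of samples in which the
#' phylotype occurred), descending; ties broken by row marginal total
#' (descending), then label.
#'
#' @param m a [community_matrix] with a `row_occurrence` attribute.
#' @return The permuted [community_matrix].
#' @export
sort_rows_by_occurrence <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  occ <- attr(m, "row_occurrence")
  if (is.null(occ)) stop("row occurrence missing", call. = FALSE)
  key <- order(-occ, -rowSums(m), rownames(m))
  permute_cm(m, rows = key, cols = seq_len(ncol(m)))
}

#' Impose an explicit column order
#'
#' Reorders columns to a given label sequence while keeping the gradient
#' and occurrence attributes aligned. Used for composite hypothesis
#' layouts that a single gradient sort cannot express, e.g. a combined
#' matrix with one soil-origin block on the left and the other on the
#' right, each block sorted by pH internally.
#'
#' @param m a [community_matrix].
#' @param labels character vector: a permutation of `colnames(m)`.
#' @return The reordered [community_matrix].
#' @export
arrange_columns <- function(m, labels) {
  stopifnot(inherits(m, "community_matrix"))
  if (!setequal(labels, colnames(m)) || length(labels) != ncol(m)) {
    stop("'labels' must be a permutation of the column names", call. = FALSE)
  }
  permute_cm(m, rows = seq_len(nrow(m)), cols = match(labels, colnames(m)))
}

permute_cm <- function(m, rows, cols) {
  cells <- unclass_cm(m)[rows, cols, drop = FALSE]
  grad <- attr(m, "col_gradient")
  occ <- attr(m, "row_occurrence")
  community_matrix(cells, cell_kind(m),
                   col_gradient = if (!is.null(grad)) grad[cols],
                   row_occurrence = if (!is.null(occ)) occ[rows])
}

#' Read or write a community matrix as tab-separated text
#'
#' Layout: first column holds phylotype ids, remaining columns one group
#' each. An optional leading comment line `#gradient:<tab>v1<tab>v2...`
#' carries the per-column gradient (e.g. mean pH); an optional
#' `#occurrence:` line on write carries row occurrences (restored on read).
#'
#' @param path file path.
#' @param cell_kind cell kind to stamp on the read matrix.
#' @return `read_community_matrix` returns a [community_matrix].
#' @export
read_community_matrix <- function(path, cell_kind = "count") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  grad <- NULL
  occ <- NULL
  hdr <- grep("^#", lines)
  for (i in hdr) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (parts[1] == "#gradient:") grad <- as.numeric(parts[-1])
    if (parts[1] == "#occurrence:") occ <- as.numeric(parts[-1])
  }
  body <- if (length(hdr) > 0) lines[-hdr] else lines
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- as.character(df[[1]])
  community_matrix(cells, cell_kind, col_gradient = grad,
                   row_occurrence = occ)
}

#' @rdname read_community_matrix
#' @param m a [community_matrix].
#' @export
write_community_matrix <- function(m, path) {
  stopifnot(inherits(m, "community_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  grad <- attr(m, "col_gradient")
  if (!is.null(grad)) {
    writeLines(paste(c("#gradient:", format(grad, trim = TRUE)),
                     collapse = "\t"), con)
  }
  occ <- attr(m, "row_occurrence")
  if (!is.null(occ)) {
    writeLines(paste(c("#occurrence:", format(occ, trim = TRUE)),
                     collapse = "\t"), con)
  }
  df <- data.frame(phylotype = rownames(m), unclass_cm(m),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
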