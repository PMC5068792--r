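#' Sample-level community occurrence table
#'
#' A `sample_table` is the raw input of the pipeline: one row per
#' sample-by-phylotype occurrence, with the group (site or treatment) the
#' sample belongs to, the soil pH of the sample, and an optional clone count.
#' pH is stored and compared as a plain real number throughout, even though
#' it is a logarithmic quantity (-log10 of the proton activity).
#'
#' @param records data frame with columns `sample_id`, `group`, `ph`,
#'   `phylotype` and optionally `count` (positive integers; defaults to 1,
#'   i.e. presence only).
#' @param groups optional data frame of group metadata with a `group` column
#'   and any of `n_samples`, `mean_ph`, `label`. When omitted, it is derived
#'   from the records (`n_samples` = number of distinct samples seen,
#'   `mean_ph` = mean pH over those samples).
#'
#' @return A data frame of class `sample_table` with a `groups` attribute.
#' @examples
#' rec <- data.frame(
#'   sample_id = c("a", "a", "b"), group = "site1", ph = 6.5,
#'   phylotype = c("Rhz1", "Glo1", "Rhz1")
#' )
#' st <- sample_table(rec)
#' attr(st, "groups")
#' @export
sample_table <- function(records, groups = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("sample_id", "group", "ph", "phylotype")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("sample table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$sample_id <- as.character(records$sample_id)
  records$group <- as.character(records$group)
  records$phylotype <- as.character(records$phylotype)
  if (!is.numeric(records$ph)) {
    stop("'ph' must be numeric", call. = FALSE)
  }
  bad_ph <- which(!is.na(records$ph) & (records$ph < 0 | records$ph > 14))
  if (length(bad_ph) > 0) {
    stop("pH outside [0, 14] at record(s) ", paste(bad_ph, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(records$count)) {
    records$count <- 1L
  }
  if (any(is.na(records$count)) || any(records$count < 1) ||
      any(records$count != round(records$count))) {
    bad <- which(is.na(records$count) | records$count < 1 |
                 records$count != round(records$count))
    stop("'count' must be a positive integer (zero-count records are ",
         "rejected); offending record(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  records$count <- as.integer(records$count)
  key <- paste(records$sample_id, records$phylotype, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop("duplicated (sample_id, phylotype) pair(s): ",
         paste(unique(paste0("(", d$sample_id, ", ", d$phylotype, ")")),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- derive_group_metadata(records)
  } else {
    stopifnot(is.data.frame(groups), "group" %in% names(groups))
    groups$group <- as.character(groups$group)
    orphan <- setdiff(unique(records$group), groups$group)
    if (length(orphan) > 0) {
      stop("record group(s) absent from group metadata: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    if (!is.null(groups$n_samples) && any(groups$n_samples < 1)) {
      stop("group 'n_samples' must be >= 1", call. = FALSE)
    }
  }
  structure(records, groups = groups,
            class = c("sample_table", "data.frame"))
}

derive_group_metadata <- function(records) {
  per_sample <- unique(records[, c("sample_id", "group", "ph")])
  split_ph <- split(per_sample$ph, per_sample$group)
  grp <- unique(records$group)  # keep first-appearance order
  data.frame(
    group = grp,
    n_samples = vapply(split_ph[grp], length, integer(1)),
    mean_ph = vapply(split_ph[grp], function(p) mean(p), numeric(1)),
    row.names = NULL
  )
}

#' Read a sample table from delimited text
#'
#' Expects a UTF-8 header row naming the columns `sample_id`, `group`, `ph`,
#' `phylotype` and optionally `count`; unknown columns are preserved. Row
#' order is preserved.
#'
#' @param path path to the file.
#' @param sep field delimiter (default tab).
#' @return A [sample_table].
#' @export
read_sample_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = NA, check.names = FALSE)
  if ("ph" %in% names(raw) && !is.numeric(raw$ph)) {
    suppressWarnings(ph_num <- as.numeric(raw$ph))
    bad <- which(is.na(ph_num) & !is.na(raw$ph) & raw$ph != "NA")
    if (length(bad) > 0) {
      stop("non-numeric pH value at data line ", bad[1], " of ", path,
           call. = FALSE)
    }
    raw$ph <- ph_num
  }
  sample_table(raw)
}

#' Write a sample table to delimited text
#'
#' @param x a [sample_table].
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write group metadata sidecars
#'
#' Group metadata (sample count, mean pH and optional soil chemistry per
#' group) travels beside matrix files as a JSON sidecar.
#'
#' @param path JSON file path.
#' @return `read_group_metadata` returns a data frame with one row per group.
#' @export
read_group_metadata <- function(path) {
  out <- jsonlite::fromJSON(path)
  stopifnot(is.data.frame(out), "group" %in% names(out))
  out
}

#' @rdname read_group_metadata
#' @param groups data frame of group metadata.
#' @export
write_group_metadata <- function(groups, path) {
  jsonlite::write_json(groups, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Sample-by-phylotype presence matrix
#'
#' Expands a [sample_table] into a samples (rows) x phylotypes (columns)
#' matrix of clone counts (or presences). Used for sample-level distance
#' matrices feeding PERMANOVA.
#'
#' @param table a [sample_table].
#' @param presence if `TRUE` (default) cells are 0/1, else clone counts.
#' @return Integer matrix with sample ids as rownames; attributes `group`
#'   and `ph` give the per-sample factor and pH in row order.
#' @export
sample_matrix <- function(table, presence = TRUE) {
  stopifnot(inherits(table, "sample_table"))
  samples <- unique(table$sample_id)
  phylos <- unique(table$phylotype)
  m <- matrix(0L, nrow = length(samples), ncol = length(phylos),
              dimnames = list(samples, phylos))
  m[cbind(match(table$sample_id, samples), match(table$phylotype, phylos))] <-
    if (presence) 1L else table$count
  meta <- unique(as.data.frame(table)[, c("sample_id", "group", "ph")])
  meta <- meta[match(samples, meta$sample_id), ]
  attr(m, "group") <- meta$group
  attr(m, "ph") <- meta$ph
  m
}

#' @export
print.sample_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat("Sample table: ", nrow(x), " occurrence records, ",
      length(unique(x$sample_id)), " samples, ",
      length(unique(x$phylotype)), " phylotypes, ",
      nrow(g), " groups\n", sep = "")
  NextMethod()
}
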