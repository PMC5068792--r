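#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a plain list, fills defaults, and validates
#' every field, collecting all violations into a single error rather than
#' stopping at the first.
#'
#' Recognized fields: `samples` (path to a sample table, or omitted when a
#' table is passed to [run_pipeline] directly), `descending` (gradient
#' sort direction, default `TRUE`), `n_null` (default 1000), `n_perm`
#' (default 999), `seed` (default 1), `min_occurrences` (default 3),
#' `mantel_distance` (`"morisita_horn"`, default, or `"ruzicka"`),
#' `output_dir` (optional; when set, the report and per-stage TSVs are
#' written there).
#'
#' @param x YAML path or list.
#' @return Validated config list of class `pipeline_config`.
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    yaml::read_yaml(x)
  } else if (is.list(x)) x else {
    stop("config must be a YAML path or a list", call. = FALSE)
  }
  defaults <- list(descending = TRUE, n_null = 1000, n_perm = 999,
                   seed = 1L, min_occurrences = 3,
                   mantel_distance = "morisita_horn", output_dir = NULL,
                   samples = NULL)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[nm] <- defaults[nm]
  }
  errors <- character(0)
  if (!is.null(cfg$samples) && !file.exists(cfg$samples)) {
    errors <- c(errors, paste0("samples: file not found: ", cfg$samples))
  }
  if (!is.numeric(cfg$n_null) || cfg$n_null < 1) {
    errors <- c(errors, "n_null: must be a positive integer")
  }
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 1) {
    errors <- c(errors, "n_perm: must be a positive integer")
  }
  if (!is.numeric(cfg$seed)) errors <- c(errors, "seed: must be an integer")
  if (!is.numeric(cfg$min_occurrences) || cfg$min_occurrences < 1) {
    errors <- c(errors, "min_occurrences: must be >= 1")
  }
  if (!cfg$mantel_distance %in% c("morisita_horn", "ruzicka", "jaccard")) {
    errors <- c(errors, "mantel_distance: unknown distance")
  }
  if (!is.logical(cfg$descending)) {
    errors <- c(errors, "descending: must be TRUE or FALSE")
  }
  if (length(errors) > 0) {
    stop("invalid pipeline config:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full gradient-nestedness analysis
#'
#' Executes the analysis sequence on a sample table: pool sample presences
#' into a group-by-phylotype frequency matrix, normalize to percentage
#' relative abundance, impose the gradient ordering (columns by descending
#' mean pH, rows by occurrence), test column-wise NODF on the
#' presence/absence matrix and row-wise weighted NODF on the abundance
#' matrix against their null models, decompose pairwise site comparisons
#' on the S-D-R simplex in both modes, run one-way PERMANOVA on
#' sample-level Jaccard distances and a Mantel test of site-level
#' community dissimilarity against pH difference, profile phylotype pH
#' generality, and summarize per-group rarefaction sufficiency.
#'
#' @param config a [validate_config] result, YAML path, or list.
#' @param samples optionally, a [sample_table] (overrides `config$samples`).
#' @return Object of class `analysis_report`: a list of per-stage results
#'   plus a `provenance` block (config echo, seeds, package version,
#'   timestamp). When `config$output_dir` is set the report is also
#'   written as JSON plus per-stage TSVs.
#' @export
run_pipeline <- function(config, samples = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (is.null(samples)) {
    if (is.null(config$samples)) {
      stop("no input: supply 'samples' or config$samples", call. = FALSE)
    }
    samples <- read_sample_table(config$samples)
  }
  stopifnot(inherits(samples, "sample_table"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  groups <- attr(samples, "groups")
  pooled <- stage("pool", pool_to_matrix(samples))
  pooled <- stage("sort", sort_rows_by_occurrence(
    sort_columns_by_gradient(pooled, descending = config$descending)))
  rel <- stage("normalize", normalize_relative_abundance(pooled, groups))
  pres <- to_presence_absence(rel)
  nodf_res <- stage("nodf", nestedness_test(
    pres, "nodf", "columns", n_null = config$n_null, seed = config$seed))
  wnodf_res <- stage("wnodf", nestedness_test(
    rel, "wnodf", "rows", n_null = config$n_null, seed = config$seed + 1L,
    counts = pooled))
  sdr_bin <- stage("sdr", sdr_simplex(pres, mode = "binary"))
  sdr_abn <- stage("sdr", sdr_simplex(rel, mode = "abundance"))
  sm <- sample_matrix(samples, presence = TRUE)
  perm <- stage("permanova", permanova_oneway(
    community_distance(sm, "jaccard", along = "rows"),
    attr(sm, "group"), n_perm = config$n_perm, seed = config$seed + 2L))
  site_ph <- stats::setNames(groups$mean_ph, groups$group)[colnames(rel)]
  mantel <- stage("mantel", mantel_test(
    community_distance(rel, config$mantel_distance, along = "columns"),
    env_distance(site_ph), n_perm = config$n_perm,
    seed = config$seed + 3L))
  profiles <- stage("generality", generality_profiles(
    samples, min_occurrences = config$min_occurrences))
  gencor <- stage("generality", generality_correlation(profiles))
  raref <- stage("rarefaction", {
    df <- as.data.frame(samples)
    per_group <- lapply(split(df, df$group), function(g) {
      counts <- tapply(g$count, g$phylotype, sum)
      chk <- sufficiency_check(counts, threshold = 0.4)
      data.frame(group = g$group[1], n_clones = sum(counts),
                 richness = length(counts),
                 ci95_halfwidth = chk$ci_halfwidth,
                 sufficient = chk$sufficient)
    })
    out <- do.call(rbind, per_group)
    rownames(out) <- NULL
    out
  })
  report <- structure(list(
    matrix_presence = pres, matrix_abundance = rel,
    nodf_columns = nodf_res, wnodf_rows = wnodf_res,
    sdr_binary = sdr_bin, sdr_abundance = sdr_abn,
    permanova = perm, mantel = mantel,
    generality_profiles = profiles, generality_correlation = gencor,
    rarefaction = raref,
    provenance = list(
      config = unclass(config),
      seeds = c(nodf = config$seed, wnodf = config$seed + 1L,
                permanova = config$seed + 2L, mantel = config$seed + 3L),
      package_version = as.character(utils::packageVersion("nestgrad")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "analysis_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write an analysis report to disk
#'
#' Emits a consolidated JSON report plus per-stage TSV artifacts (ordered
#' matrices, S-D-R pair tables, generality profiles, rarefaction summary).
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_community_matrix(report$matrix_presence,
                         file.path(dir, "matrix_presence.tsv"))
  write_community_matrix(report$matrix_abundance,
                         file.path(dir, "matrix_abundance.tsv"))
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$sdr_binary$pairs, "sdr_binary_pairs.tsv")
  tsv(report$sdr_abundance$pairs, "sdr_abundance_pairs.tsv")
  tsv(report$generality_profiles, "generality_profiles.tsv")
  tsv(report$rarefaction, "rarefaction_summary.tsv")
  strip <- function(x) x[setdiff(names(x), "null_values")]
  json <- list(
    nodf_columns = strip(unclass(report$nodf_columns)),
    wnodf_rows = strip(unclass(report$wnodf_rows)),
    sdr_binary = unclass(report$sdr_binary)[c("pct_turnover",
                                              "pct_agreement",
                                              "pct_nestedness", "mode")],
    sdr_abundance = unclass(report$sdr_abundance)[c("pct_turnover",
                                                    "pct_agreement",
                                                    "pct_nestedness",
                                                    "mode")],
    permanova = unclass(report$permanova),
    mantel = unclass(report$mantel),
    generality_correlation = report$generality_correlation,
    rarefaction = report$rarefaction,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Gradient-nestedness analysis report\n")
  cat(sprintf("  matrix: %d phylotypes x %d groups\n",
              nrow(x$matrix_abundance), ncol(x$matrix_abundance)))
  print(x$nodf_columns)
  print(x$wnodf_rows)
  print(x$sdr_binary)
  print(x$sdr_abundance)
  print(x$permanova)
  print(x$mantel)
  gc <- x$generality_correlation
  cat(sprintf("Generality: r = %.3f, p = %.3g (n = %d profiles)\n",
              gc$r, gc$p, gc$n))
  invisible(x)
}
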