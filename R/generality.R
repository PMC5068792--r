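#' pH-generality profiles of phylotypes
#'
#' For each phylotype, summarizes the soil pH of the samples in which it
#' occurred: the number of occupied samples, the lowest occupied pH (its
#' acid-tolerance limit as observed), and the standard deviation of the
#' occupied pH values (the width of its realized pH range). Profiles
#' occurring in fewer than `min_occurrences` samples are flagged as
#' excluded from the downstream correlation; the SD is undefined (`NA`)
#' for single-sample phylotypes.
#'
#' @param table a [sample_table]; every occupied sample must carry a pH.
#' @param min_occurrences minimum samples for inclusion in the correlation
#'   set (default 3).
#' @return Data frame with columns `phylotype`, `n_samples_present`,
#'   `min_ph`, `sd_ph`, `included`.
#' @export
generality_profiles <- function(table, min_occurrences = 3) {
  stopifnot(inherits(table, "sample_table"))
  df <- as.data.frame(table)
  if (anyNA(df$ph)) {
    bad <- unique(df$sample_id[is.na(df$ph)])
    stop("missing pH on occupied sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sp <- split(df$ph, df$phylotype)
  out <- data.frame(
    phylotype = names(sp),
    n_samples_present = vapply(sp, length, integer(1)),
    min_ph = vapply(sp, min, numeric(1)),
    sd_ph = vapply(sp, function(p) if (length(p) >= 2) stats::sd(p)
                   else NA_real_, numeric(1)),
    row.names = NULL)
  out$included <- out$n_samples_present >= min_occurrences
  out
}

#' Correlation between pH range width and acid tolerance
#'
#' Pearson correlation between the SD of occupied pH and the lowest
#' occupied pH over the included profiles, with the two-sided p-value from
#' the t distribution on `n - 2` degrees of freedom. A significantly
#' negative correlation means more acid-tolerant phylotypes occupy wider
#' pH ranges, i.e. they are pH generalists.
#'
#' @param profiles output of [generality_profiles].
#' @return List with `r`, `p`, `n`.
#' @export
generality_correlation <- function(profiles) {
  keep <- profiles[profiles$included & !is.na(profiles$sd_ph), ]
  if (nrow(keep) < 3) stop("need at least 3 included profiles", call. = FALSE)
  if (stats::sd(keep$sd_ph) == 0 || stats::sd(keep$min_ph) == 0) {
    stop("zero variance in a correlation variable", call. = FALSE)
  }
  ct <- stats::cor.test(keep$sd_ph, keep$min_ph, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(keep))
}
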