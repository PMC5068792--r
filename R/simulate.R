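#' Configuration for the synthetic community generator
#'
#' Encodes the study conditions the generator emulates: six sites spanning
#' strongly acidic to neutral soil (site means evenly spaced over pH
#' 3.2-7.2, emulating a field span of 3.0-7.4), about a dozen samples per
#' site, and ~50 phylotypes whose occurrence is governed by a lower pH
#' tolerance limit drawn uniformly on 3.0-7.0. Under the `"nested"` regime
#' a phylotype can occupy any sample at or above its limit (so
#' acid-tolerant phylotypes are pH generalists and incidence is nested by
#' construction, thinned by `p_occ`); under `"turnover"` occupancy is
#' confined to a window of `niche_width` pH units above the limit; under
#' `"random"` occupancy ignores pH. Clone counts allocate
#' `clones_per_sample` clones multinomially among the phylotypes present
#' in a sample; with `dominance_shift` the weights peak at a per-phylotype
#' abundance optimum just above its tolerance limit, producing dominance
#' turnover along the gradient (anti-nested abundance over a nested
#' incidence skeleton).
#'
#' @param n_sites number of sites (default 6).
#' @param site_mean_ph site mean pH values, strictly increasing (default
#'   evenly spaced 3.2-7.2).
#' @param samples_per_site samples per site (default 12).
#' @param sample_ph_sd SD of sample pH around the site mean (default 0.4,
#'   the scale of the within-site pH spread the field sites show).
#' @param n_phylotypes number of phylotypes (default 50).
#' @param tolerance_range range of the uniform lower-tolerance-limit
#'   distribution (default `c(3.0, 7.0)`).
#' @param regime `"nested"`, `"turnover"` or `"random"`.
#' @param p_occ occupancy probability within range (default 0.6).
#' @param establishment_slope decline of the per-site establishment
#'   probability per pH unit of tolerance limit above the pool minimum
#'   (default 0.2): acid-tolerant generalists establish at almost every
#'   site they tolerate, acid-sensitive phylotypes are patchy.
#' @param establishment_floor lower bound of the establishment probability
#'   (default 0.2). Set both `establishment_floor = 1` and `p_occ = 1` for
#'   deterministic occupancy.
#' @param niche_width occupancy window width in pH units for the turnover
#'   regime (default 1.5).
#' @param clones_per_sample sequenced clones per sample (default 25).
#' @param dominance_shift create pH-dependent abundance optima (default
#'   `FALSE`).
#' @param dominance_offset optimum position above the tolerance limit in
#'   pH units (default 0.5).
#' @param dominance_width Gaussian width of the abundance weighting in pH
#'   units (default 1.0).
#' @param seed integer seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 6,
                              site_mean_ph = seq(3.2, 7.2,
                                                 length.out = n_sites),
                              samples_per_site = 12,
                              sample_ph_sd = 0.4,
                              n_phylotypes = 50,
                              tolerance_range = c(3.0, 7.0),
                              regime = c("nested", "turnover", "random"),
                              p_occ = 0.6,
                              establishment_slope = 0.2,
                              establishment_floor = 0.2,
                              niche_width = 1.5,
                              clones_per_sample = 25,
                              dominance_shift = FALSE,
                              dominance_offset = 0.5,
                              dominance_width = 1.0,
                              seed = 1L) {
  regime <- match.arg(regime)
  cfg <- list(n_sites = n_sites, site_mean_ph = site_mean_ph,
              samples_per_site = samples_per_site,
              sample_ph_sd = sample_ph_sd, n_phylotypes = n_phylotypes,
              tolerance_range = tolerance_range, regime = regime,
              p_occ = p_occ, establishment_slope = establishment_slope,
              establishment_floor = establishment_floor,
              niche_width = niche_width,
              clones_per_sample = clones_per_sample,
              dominance_shift = dominance_shift,
              dominance_offset = dominance_offset,
              dominance_width = dominance_width, seed = as.integer(seed))
  stopifnot(length(cfg$site_mean_ph) == cfg$n_sites,
            !is.unsorted(cfg$site_mean_ph, strictly = TRUE),
            cfg$p_occ >= 0, cfg$p_occ <= 1,
            cfg$samples_per_site >= 1, cfg$n_phylotypes >= 2,
            cfg$tolerance_range[1] < cfg$tolerance_range[2],
            cfg$establishment_slope >= 0,
            cfg$establishment_floor >= 0, cfg$establishment_floor <= 1,
            cfg$niche_width > 0, cfg$clones_per_sample >= 1,
            cfg$sample_ph_sd >= 0)
  structure(cfg, class = "simulation_config")
}

#' Simulate a sample-level community dataset with known structure
#'
#' Draws a dataset under a [simulation_config] and returns both the
#' observable [sample_table] and the generating truth (per-phylotype
#' tolerance limits and abundance optima, per-sample true pH). The draw is
#' deterministic given the config's seed. Occupancy is hierarchical: a
#' phylotype first establishes at a site (Bernoulli, probability declining
#' with its tolerance limit -- generalists reach almost every site,
#' specialists are patchy), then occupies each sample of an established
#' site within its tolerated pH range with probability `p_occ`. A sample
#' left empty by the thinning receives the most acid-tolerant phylotype
#' eligible at its pH (every sequenced sample contains at least one
#' phylotype).
#'
#' @param config a [simulation_config].
#' @return List with `samples` (a [sample_table]) and `truth` (list of
#'   data frames `phylotypes` and `samples`).
#' @export
simulate_communities <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  np <- config$n_phylotypes
  lower <- stats::runif(np, config$tolerance_range[1],
                        config$tolerance_range[2])
  upper <- switch(config$regime,
                  nested = rep(max(config$site_mean_ph) + 1,
                               np),  # acid-tolerant = generalist
                  turnover = lower + config$niche_width,
                  random = rep(Inf, np))
  optimum <- pmin(lower + config$dominance_offset,
                  max(config$site_mean_ph))
  p_establish <- pmax(1 - config$establishment_slope *
                        (lower - config$tolerance_range[1]),
                      config$establishment_floor)
  phylo_id <- sprintf("Phy%02d", seq_len(np))
  sites <- sprintf("site%02d", seq_len(config$n_sites))
  records <- list()
  sample_rows <- list()
  for (i in seq_len(config$n_sites)) {
    established <- stats::runif(np) < p_establish
    ph_s <- stats::rnorm(config$samples_per_site, config$site_mean_ph[i],
                         config$sample_ph_sd)
    ph_s <- pmin(pmax(ph_s, 0), 14)
    for (k in seq_len(config$samples_per_site)) {
      sid <- sprintf("%s_s%02d", sites[i], k)
      ph <- ph_s[k]
      eligible <- switch(config$regime,
                         nested = ph >= lower,
                         turnover = ph >= lower & ph <= upper,
                         random = rep(TRUE, np))
      occ <- eligible & established & stats::runif(np) < config$p_occ
      if (!any(occ)) {
        pick <- if (any(eligible)) which(eligible)[which.min(lower[eligible])]
        else which.min(lower)
        occ[pick] <- TRUE
      }
      present <- which(occ)
      w <- if (config$dominance_shift) {
        exp(-0.5 * ((ph - optimum[present]) / config$dominance_width)^2)
      } else rep(1, length(present))
      cnt <- as.vector(stats::rmultinom(1, config$clones_per_sample,
                                        prob = w))
      keep <- cnt > 0
      # a present phylotype may draw zero clones; it is then unobserved
      if (!any(keep)) next
      records[[length(records) + 1L]] <- data.frame(
        sample_id = sid, group = sites[i], ph = ph,
        phylotype = phylo_id[present[keep]], count = cnt[keep])
      sample_rows[[length(sample_rows) + 1L]] <- data.frame(
        sample_id = sid, group = sites[i], ph = ph)
    }
  }
  samples <- sample_table(do.call(rbind, records))
  truth <- list(
    phylotypes = data.frame(phylotype = phylo_id, lower_limit = lower,
                            upper_limit = upper, optimum = optimum,
                            p_establish = p_establish),
    samples = do.call(rbind, sample_rows))
  list(samples = samples, truth = truth)
}

#' Simulate the pH-manipulation glasshouse design
#'
#' Emulates a two-inoculum by three-pH glasshouse experiment with `n`
#' replicate pots per cell: the neutral-soil inoculum carries the full
#' phylotype pool while the acidic-soil inoculum carries only the
#' acid-tolerant subset (lower tolerance limit at or below
#' `acid_pool_max`), and occupancy in a pot requires the growth-medium pH
#' to be at or above the phylotype's limit (thinned by `p_occ`). This
#' yields an inoculum main effect, a pH effect expressed mostly in the
#' neutral-soil communities, and their interaction -- the structure the
#' crossed two-factor analysis expects. As in [simulate_communities],
#' colonization of a treatment's pots succeeds with a probability that
#' declines with the phylotype's tolerance limit, so pooled frequencies
#' vary over 0..n and group-level incidence is nested with noise rather
#' than saturating into a margin-determined matrix.
#'
#' @param ph_levels growth-medium pH levels (default `c(3.4, 4.0, 5.5)`).
#' @param n_per_cell replicate pots per inoculum-by-pH cell (default 5).
#' @param n_phylotypes phylotype pool size (default 24, the scale of a
#'   single-experiment pool).
#' @param acid_pool_max highest tolerance limit present in the acidic-soil
#'   inoculum (default 4.0).
#' @param p_occ occupancy probability when eligible (default 0.6).
#' @param establishment_slope,establishment_floor decline and floor of the
#'   per-treatment colonization probability with the tolerance limit
#'   (defaults 0.2 and 0.2, as in [simulation_config]).
#' @param clones_per_sample clones per pot (default 25).
#' @param seed integer seed.
#' @return List with `samples` (a [sample_table] whose groups are
#'   inoculum-pH cells), `inoculum` and `ph_level` (per-sample factors in
#'   the order of `unique(samples$sample_id)`), and `truth`.
#' @export
simulate_ph_experiment <- function(ph_levels = c(3.4, 4.0, 5.5),
                                   n_per_cell = 5, n_phylotypes = 24,
                                   acid_pool_max = 4.0, p_occ = 0.6,
                                   establishment_slope = 0.2,
                                   establishment_floor = 0.2,
                                   clones_per_sample = 25, seed = 1L) {
  set.seed(seed)
  lower <- stats::runif(n_phylotypes, 3.0, 7.0)
  # guarantee the acidic pool is non-empty at the lowest medium pH
  lower[1] <- min(lower[1], min(ph_levels) - 0.1)
  p_est <- pmax(1 - establishment_slope * (lower - 3.0),
                establishment_floor)
  phylo_id <- sprintf("Phy%02d", seq_len(n_phylotypes))
  pools <- list(neutral = rep(TRUE, n_phylotypes),
                acidic = lower <= acid_pool_max)
  records <- list()
  fac <- list()
  for (inoc in names(pools)) {
    for (ph in ph_levels) {
      grp <- sprintf("%s_pH%.1f", inoc, ph)
      established <- stats::runif(n_phylotypes) < p_est
      for (r in seq_len(n_per_cell)) {
        sid <- sprintf("%s_r%d", grp, r)
        eligible <- pools[[inoc]] & ph >= lower & established
        occ <- eligible & stats::runif(n_phylotypes) < p_occ
        if (!any(occ)) {
          # never leave a pot empty: fall back to the most acid-tolerant
          # member of the inoculum pool tolerating the medium pH
          pool_ok <- pools[[inoc]] & ph >= lower
          pick <- if (any(pool_ok)) which(pool_ok)[which.min(lower[pool_ok])]
          else which(pools[[inoc]])[which.min(lower[pools[[inoc]]])]
          occ[pick] <- TRUE
        }
        present <- which(occ)
        cnt <- as.vector(stats::rmultinom(1, clones_per_sample,
                                          rep(1, length(present))))
        keep <- cnt > 0
        if (!any(keep)) next
        records[[length(records) + 1L]] <- data.frame(
          sample_id = sid, group = grp, ph = ph,
          phylotype = phylo_id[present[keep]], count = cnt[keep])
        fac[[length(fac) + 1L]] <- data.frame(sample_id = sid,
                                              inoculum = inoc,
                                              ph_level = ph)
      }
    }
  }
  samples <- sample_table(do.call(rbind, records))
  fac <- do.call(rbind, fac)
  list(samples = samples,
       inoculum = fac$inoculum, ph_level = fac$ph_level,
       truth = data.frame(phylotype = phylo_id, lower_limit = lower))
}

#' Parameter-recovery runs of the full pipeline on simulated data
#'
#' Repeatedly simulates a dataset under `config` (re-seeding each
#' replicate from `seed`), runs the pooling, normalization, ordering,
#' nestedness tests, S-D-R decomposition and generality correlation, and
#' tabulates the recovered quantities against the generating truth.
#'
#' @param config a [simulation_config]; its seed is overridden per
#'   replicate.
#' @param n_replicates number of replicates (default 20).
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param n_null null-model draws per nestedness test (default 199, enough
#'   to resolve p at the 0.05 level).
#' @return Data frame, one row per replicate: `nodf_col`, `nodf_col_z`,
#'   `nodf_col_p`, `wnodf_row`, `wnodf_row_z`, `wnodf_row_p_lower`,
#'   `sdr_pct_turnover`, `sdr_pct_nestedness` (abundance mode),
#'   `generality_r`, `generality_p`, `minph_truth_r` (correlation between
#'   estimated minimum occupied pH and the true tolerance limit).
#' @export
recovery_suite <- function(config, n_replicates = 20, seed = 1L,
                           n_null = 199) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- simulate_communities(cfg)
    pooled <- pool_to_matrix(sim$samples)
    sizes <- attr(sim$samples, "groups")
    pooled <- sort_rows_by_occurrence(sort_columns_by_gradient(pooled))
    rel <- normalize_relative_abundance(pooled, sizes)
    pres <- to_presence_absence(rel)
    nt <- nestedness_test(pres, "nodf", "columns", n_null = n_null,
                          seed = cfg$seed)
    wt <- nestedness_test(rel, "wnodf", "rows", n_null = n_null,
                          seed = cfg$seed, counts = pooled)
    sdr <- sdr_simplex(rel, mode = "abundance")
    prof <- generality_profiles(sim$samples)
    gc <- generality_correlation(prof)
    est <- prof[prof$n_samples_present >= 1, ]
    tr <- sim$truth$phylotypes
    both <- merge(est, tr, by = "phylotype")
    rows[[r]] <- data.frame(
      replicate = r, nodf_col = nt$observed, nodf_col_z = nt$z,
      nodf_col_p = nt$p_upper, wnodf_row = wt$observed,
      wnodf_row_z = wt$z, wnodf_row_p_lower = wt$p_lower,
      sdr_pct_turnover = sdr$pct_turnover,
      sdr_pct_nestedness = sdr$pct_nestedness,
      generality_r = gc$r, generality_p = gc$p,
      minph_truth_r = stats::cor(both$min_ph, both$lower_limit))
  }
  do.call(rbind, rows)
}
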