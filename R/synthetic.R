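#' Glacial-to-interglacial temperature forcing curve
#'
#' Builds a piecewise-smooth global mean surface temperature (GMST) anomaly
#' curve: a cold glacial plateau before the deglaciation, a monotone
#' (cosine-ramp) warming across the deglaciation interval, and a near-flat
#' warm period after it. The anomaly is referenced so that its mean over
#' the past two millennia (0–2 ka) is zero.
#'
#' @param glacial Glacial plateau anomaly in degrees C (default -6).
#' @param deglaciation Length-2 numeric, the warming interval in kyr BP
#'   (default `c(11, 17)`: warming from 17 ka to 11 ka).
#' @param holocene Warm-period level in degrees C before referencing
#'   (default 0).
#' @param ages Age grid in kyr BP (default `seq(0, 24, 0.1)`).
#' @return Object of class `forcing_curve`: list with `ages` and `anomaly`.
#' @export
make_forcing <- function(glacial = -6, deglaciation = c(11, 17),
                         holocene = 0, ages = seq(0, 24, by = 0.1)) {
  if (length(deglaciation) != 2 || !(deglaciation[1] < deglaciation[2])) {
    stop("deglaciation must be an increasing (start, end) interval in ka")
  }
  t1 <- deglaciation[1]; t2 <- deglaciation[2]
  frac <- pmin(1, pmax(0, (ages - t1) / (t2 - t1)))
  anomaly <- holocene + (glacial - holocene) * (1 - cos(pi * frac)) / 2
  recent <- ages <= 2
  if (!any(recent)) stop("age grid must cover the 0-2 ka reference interval")
  anomaly <- anomaly - mean(anomaly[recent])
  structure(list(ages = ages, anomaly = anomaly), class = "forcing_curve")
}

#' Evaluate a forcing curve at arbitrary ages
#'
#' Linear interpolation on the curve's grid; extrapolation is an error.
#'
#' @param forcing A [make_forcing()] curve.
#' @param age Ages in kyr BP.
#' @return Anomaly values in degrees C.
#' @export
forcing_at <- function(forcing, age) {
  rng <- range(forcing$ages)
  if (any(age < rng[1] | age > rng[2])) {
    stop("age outside the forcing curve range [", rng[1], ", ", rng[2], "] ka")
  }
  stats::approx(forcing$ages, forcing$anomaly, xout = age)$y
}

#' Local sea-surface temperature history of a site
#'
#' Local SST = modern SST + site cooling scale x global anomaly, plus a
#' transient Heinrich-like offset while the age lies inside the event
#' window. The cooling scale expresses polar amplification: high-latitude
#' sites cool more than the global mean, tropical sites less.
#'
#' @param site A site configuration (see [synthetic_sites()]).
#' @param forcing A [make_forcing()] curve.
#' @param age Ages in kyr BP (vectorized).
#' @return Local SST in degrees C.
#' @export
local_sst <- function(site, forcing, age) {
  sst <- site$modern_sst + site$glacial_cooling_scale * forcing_at(forcing, age)
  ev <- site$heinrich_event
  if (!is.null(ev)) {
    inside <- age >= ev$t_start & age <= ev$t_end
    sst[inside] <- sst[inside] + ev$delta_T
  }
  sst
}

#' Default Gaussian thermal niches
#'
#' Each species responds to temperature through a Gaussian (bell-shaped)
#' curve — the standard species-response model — with optima spread evenly
#' across the glacial-to-tropical SST range. A subset of mid-thermal
#' species additionally carries a sensitivity (alternating sign) to a
#' second, non-temperature environmental axis; that axis is zero unless
#' the simulator's secondary driver is active, so the default community is
#' controlled by temperature alone.
#'
#' @param n_species Number of species (default 41, matching the harmonized
#'   taxonomy).
#' @param optimum_range Range of thermal optima in degrees C.
#' @param tolerance Gaussian niche width in degrees C (default 3).
#' @param secondary_strength Magnitude of the secondary-axis sensitivity
#'   for responsive species (default 2).
#' @param taxonomy Optional [foram_taxonomy()] used to name the species;
#'   if `NULL`, species are named `sp01`, `sp02`, ...
#' @return data.frame with columns `name`, `optimum`, `tolerance`,
#'   `amplitude`, `secondary_sensitivity`.
#' @export
synthetic_niches <- function(n_species = 41, optimum_range = c(-4, 30),
                             tolerance = 3, secondary_strength = 2,
                             taxonomy = foram_taxonomy()) {
  optima <- seq(optimum_range[1], optimum_range[2], length.out = n_species)
  names <- if (!is.null(taxonomy) && length(taxonomy$species) >= n_species) {
    taxonomy$species[seq_len(n_species)]
  } else {
    sprintf("sp%02d", seq_len(n_species))
  }
  responsive <- optima >= 8 & optima <= 24
  sens <- ifelse(responsive,
                 secondary_strength * (-1)^seq_len(n_species), 0)
  data.frame(name = names, optimum = optima, tolerance = tolerance,
             amplitude = 1, secondary_sensitivity = sens,
             stringsAsFactors = FALSE)
}

#' Expected relative abundances under the niche model
#'
#' Species weights are `amplitude * exp(-(sst - optimum)^2 / (2 tol^2)) *
#' exp(secondary_sensitivity * secondary)`, normalized to proportions.
#'
#' @param niches Niche table (see [synthetic_niches()]).
#' @param sst Local SST in degrees C (scalar).
#' @param secondary Value of the secondary environmental axis
#'   (dimensionless, default 0).
#' @return Proportion vector over species, summing to 1.
#' @export
expected_proportions <- function(niches, sst, secondary = 0) {
  if (any(niches$tolerance <= 0) || any(niches$amplitude <= 0)) {
    stop("niche tolerances and amplitudes must be positive")
  }
  w <- niches$amplitude *
    exp(-(sst - niches$optimum)^2 / (2 * niches$tolerance^2)) *
    exp(niches$secondary_sensitivity * secondary)
  if (!any(w > 1e-300)) {
    stop("degenerate environment: all species responses underflow at sst = ",
         sst)
  }
  p <- w / sum(w)
  stats::setNames(p, niches$name)
}

#' Default synthetic site layout
#'
#' Emulates a meridional transect: sites spaced evenly along the northern
#' latitudinal gradient, a linear modern SST gradient, polar-amplified
#' glacial cooling, and an optional Heinrich-like transient cooling at
#' mid-latitude sites.
#'
#' @param n_sites Number of sites (default 25).
#' @param lat_range Latitude range in degrees N (default `c(2.5, 62.5)`).
#' @param sampling_ages Census ages in kyr BP (default `seq(0, 24, 0.6)`).
#' @param count_depth Individuals counted per census (default 300, a
#'   typical micropaleontological census size).
#' @param heinrich Logical: add the transient cooling event? Default TRUE.
#' @param heinrich_lat Latitude band affected (default 40–55 N).
#' @param heinrich_window Event interval in kyr BP (default 15–17 ka).
#' @param heinrich_delta Event cooling in degrees C (default -4).
#' @param id_prefix Site id prefix.
#' @return List of site configurations; each has `site_id`, `latitude`,
#'   `longitude`, `modern_sst`, `glacial_cooling_scale`, `heinrich_event`
#'   (or `NULL`), `sampling_ages`, `count_depth`.
#' @export
synthetic_sites <- function(n_sites = 25, lat_range = c(2.5, 62.5),
                            sampling_ages = seq(0, 24, by = 0.6),
                            count_depth = 300,
                            heinrich = TRUE, heinrich_lat = c(40, 55),
                            heinrich_window = c(15, 17), heinrich_delta = -4,
                            id_prefix = "SITE") {
  lats <- seq(lat_range[1], lat_range[2], length.out = n_sites)
  lapply(seq_len(n_sites), function(i) {
    lat <- lats[i]
    ev <- NULL
    if (heinrich && lat >= heinrich_lat[1] && lat <= heinrich_lat[2]) {
      ev <- list(t_start = heinrich_window[1], t_end = heinrich_window[2],
                 delta_T = heinrich_delta)
    }
    list(site_id = sprintf("%s%02d", id_prefix, i),
         latitude = lat,
         longitude = -30,
         modern_sst = 28.5 - 0.42 * lat,
         glacial_cooling_scale = 1.5 * lat / 65,
         heinrich_event = ev,
         sampling_ages = sampling_ages,
         count_depth = count_depth)
  })
}

# Secondary-axis value at a given age: 0 before onset, ramping linearly to
# 1 over `ramp` kyr after onset (ages decrease toward the present).
.secondary_value <- function(age, onset, ramp) {
  if (is.null(onset)) return(rep(0, length(age)))
  pmin(1, pmax(0, (onset - age) / ramp))
}

# Deterministic per-site random stream derived from (seed, site index);
# kept below 2^31.
.site_seed <- function(seed, i) {
  (as.integer(seed) %% 94906249L) * 22L + 7L * i
}

#' Simulate one census time series
#'
#' For each sampling age the local SST is evaluated, expected proportions
#' are computed from the niche model, and counts are drawn from a
#' multinomial with `count_depth` trials. Deterministic given the seed.
#'
#' @param site Site configuration (see [synthetic_sites()]).
#' @param niches Niche table.
#' @param forcing Forcing curve.
#' @param seed Integer seed.
#' @param secondary_onset Age (kyr) at which the secondary axis activates
#'   at this site, or `NULL` for none.
#' @param secondary_ramp Ramp duration of the secondary axis in kyr.
#' @return Assemblage table (counts) with one row per sampling age.
#' @export
simulate_series <- function(site, niches, forcing, seed,
                            secondary_onset = NULL, secondary_ramp = 1) {
  set.seed(seed)
  ages <- site$sampling_ages
  sst <- local_sst(site, forcing, ages)
  sec <- .secondary_value(ages, secondary_onset, secondary_ramp)
  counts <- t(vapply(seq_along(ages), function(j) {
    p <- expected_proportions(niches, sst[j], sec[j])
    as.numeric(stats::rmultinom(1, site$count_depth, p))
  }, numeric(nrow(niches))))
  colnames(counts) <- niches$name
  cbind(data.frame(site_id = site$site_id, latitude = site$latitude,
                   longitude = site$longitude, age_ka = ages),
        as.data.frame(counts, check.names = FALSE),
        row.names = NULL)
}

#' Configuration for the synthetic dataset generator
#'
#' Collects every tunable of the simulated study design with defaults
#' emulating the analysed North Atlantic setting: 25 sites along a 2.5 to
#' 62.5 degrees N gradient sampled every 0.6 kyr over 0-24 ka, a glacial
#' (-6 C) to Holocene forcing with deglaciation at 11-17 ka, a mid-latitude
#' Heinrich-like cooling, a spatially dense pool of reference-only glacial
#' sites standing in for the external LGM compilation, and an optional
#' Holocene-only secondary driver that creates no-analogue compositions at
#' mid-latitude sites.
#'
#' @param n_sites,lat_range,sampling_ages,count_depth,heinrich,heinrich_lat,heinrich_window,heinrich_delta
#'   Passed to [synthetic_sites()].
#' @param n_species,tolerance,secondary_strength Passed to
#'   [synthetic_niches()].
#' @param glacial,deglaciation Passed to [make_forcing()].
#' @param secondary_driver Logical: activate the no-analogue mechanism?
#'   Default FALSE.
#' @param secondary_lat Latitude band of affected sites (default 30-50 N).
#' @param secondary_onset Activation age in kyr BP (default 11).
#' @param secondary_ramp Ramp duration in kyr (default 1).
#' @param n_reference_sites Number of additional reference-only glacial
#'   sites (default 60).
#' @param reference_ages Sampling ages of the reference-only sites
#'   (default `c(19.5, 20.5, 21.5, 22.5)`).
#' @param lgm_window Reference window in kyr (default `c(19, 23)`).
#' @return A named list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 25, lat_range = c(2.5, 62.5),
                             sampling_ages = seq(0, 24, by = 0.6),
                             count_depth = 300,
                             n_species = 41, tolerance = 3,
                             secondary_strength = 2,
                             glacial = -6, deglaciation = c(11, 17),
                             heinrich = TRUE, heinrich_lat = c(40, 55),
                             heinrich_window = c(15, 17), heinrich_delta = -4,
                             secondary_driver = FALSE,
                             secondary_lat = c(30, 50),
                             secondary_onset = 11, secondary_ramp = 1,
                             n_reference_sites = 60,
                             reference_ages = c(19.5, 20.5, 21.5, 22.5),
                             lgm_window = c(19, 23)) {
  if (n_sites < 2) stop("at least 2 sites are required")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a full synthetic study dataset
#'
#' Generates all site time series, a pool of reference-only glacial sites,
#' the LGM reference set (external pool plus in-window series samples), and
#' a ground-truth record for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer master seed; all per-site streams derive from it.
#' @return List of class `synthetic_dataset` with elements `samples`
#'   (assemblage table of all series, counts), `reference` (a
#'   `reference_set`), and `truth` (niches, forcing, per-site SST history
#'   and expected proportions, and `no_analogue_onset`, a named vector
#'   with the activation age per site or `NA`).
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  forcing <- make_forcing(glacial = config$glacial,
                          deglaciation = config$deglaciation)
  niches <- synthetic_niches(n_species = config$n_species,
                             tolerance = config$tolerance,
                             secondary_strength = config$secondary_strength)
  sites <- synthetic_sites(n_sites = config$n_sites,
                           lat_range = config$lat_range,
                           sampling_ages = config$sampling_ages,
                           count_depth = config$count_depth,
                           heinrich = config$heinrich,
                           heinrich_lat = config$heinrich_lat,
                           heinrich_window = config$heinrich_window,
                           heinrich_delta = config$heinrich_delta)

  onset <- vapply(sites, function(s) {
    if (config$secondary_driver &&
        s$latitude >= config$secondary_lat[1] &&
        s$latitude <= config$secondary_lat[2]) config$secondary_onset else NA_real_
  }, numeric(1))
  names(onset) <- vapply(sites, `[[`, character(1), "site_id")

  series <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    simulate_series(s, niches, forcing, seed = .site_seed(seed, i),
                    secondary_onset = if (is.na(onset[i])) NULL else onset[i],
                    secondary_ramp = config$secondary_ramp)
  })
  samples <- do.call(rbind, series)

  # reference-only glacial sites: the spatially dense external compilation
  ref_sites <- synthetic_sites(n_sites = config$n_reference_sites,
                               lat_range = config$lat_range +
                                 c(-1, 1) * 0.5,
                               sampling_ages = config$reference_ages,
                               count_depth = config$count_depth,
                               heinrich = FALSE, id_prefix = "REF")
  extra <- do.call(rbind, lapply(seq_along(ref_sites), function(i) {
    simulate_series(ref_sites[[i]], niches, forcing,
                    seed = .site_seed(seed, 100000L + i))
  }))

  reference <- build_reference_set(series = samples, extra = extra,
                                   window = config$lgm_window)

  sst_hist <- lapply(sites, function(s) local_sst(s, forcing, s$sampling_ages))
  names(sst_hist) <- names(onset)
  expected <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    sec <- .secondary_value(s$sampling_ages,
                            if (is.na(onset[i])) NULL else onset[i],
                            config$secondary_ramp)
    t(vapply(seq_along(s$sampling_ages), function(j) {
      expected_proportions(niches, sst_hist[[i]][j], sec[j])
    }, numeric(nrow(niches))))
  })
  names(expected) <- names(onset)

  truth <- list(niches = niches, forcing = forcing, sites = sites,
                local_sst = sst_hist, expected_proportions = expected,
                no_analogue_onset = onset)
  structure(list(samples = samples, reference = reference, truth = truth),
            class = "synthetic_dataset")
}

#' Simulate a series with an imposed linear richness trend
#'
#' A calibration scenario for rate-of-change recovery: true richness
#' changes linearly through time (slope in species per kyr toward the
#' present), the present species form a nested subset with uniform true
#' proportions, and censuses add multinomial count noise.
#'
#' @param slope Richness change in species per kyr toward the present.
#' @param base_richness Richness of the oldest sample (default 20).
#' @param ages Sampling ages in kyr BP (default `seq(0, 24, 0.6)`).
#' @param n_species Species pool size (default 41).
#' @param count_depth Multinomial count depth (default 300).
#' @param seed Integer seed.
#' @param site_id Site identifier.
#' @return Assemblage table (counts) for one site.
#' @export
simulate_richness_ramp <- function(slope, base_richness = 20,
                                   ages = seq(0, 24, by = 0.6),
                                   n_species = 41, count_depth = 300,
                                   seed = 1, site_id = "RAMP") {
  set.seed(seed)
  oldest <- max(ages)
  rich <- round(base_richness + slope * (oldest - ages))
  rich <- pmin(n_species, pmax(1, rich))
  counts <- t(vapply(rich, function(r) {
    p <- c(rep(1 / r, r), rep(0, n_species - r))
    as.numeric(stats::rmultinom(1, count_depth, p))
  }, numeric(n_species)))
  colnames(counts) <- sprintf("sp%02d", seq_len(n_species))
  cbind(data.frame(site_id = site_id, latitude = 45, longitude = -30,
                   age_ka = ages),
        as.data.frame(counts, check.names = FALSE),
        row.names = NULL)
}
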