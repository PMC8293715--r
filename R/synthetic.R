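#' Configuration for the synthetic elevational community generator
#'
#' Builds and validates the parameter set controlling every synthetic input:
#' the plot grid, the species pool with a planted range-size--elevation slope,
#' station climate series, the glacial--interglacial climate offsets, and the
#' village population surface. Defaults emulate a 96-plot survey of a
#' Himalayan valley gradient spanning 1,800--5,400 m a.s.l. with roughly 545
#' vascular plant species.
#'
#' The species model is midpoint-parameterized: species `i` gets a midpoint
#' `m_i ~ Uniform(domain)` and a latent range size
#' `r_i = max(0, a + b * (m_i - domain_low) + eps_i)` with
#' `eps_i ~ N(0, range_noise_sd)`. When `truncate_ranges` is `TRUE` the
#' occupied interval `[m_i - r_i/2, m_i + r_i/2]` is shifted minimally so it
#' fits inside the domain (sizes are preserved, so the planted slope stays
#' interpretable, matching the feasible-placement geometry of the mid-domain
#' null); setting it to `FALSE` leaves intervals hanging over the domain
#' edges, a useful null for false-positive calibration.
#'
#' @param domain_low,domain_high Domain bounds in m a.s.l.
#' @param n_plots Number of survey plots (evenly spaced over the domain).
#' @param n_species Species-pool size.
#' @param rapoport_slope_b Planted slope: metres of latent range size gained
#'   per metre of midpoint elevation (dimensionless). `0` plants no trend.
#' @param base_range_a Latent range size (m) at the domain floor.
#' @param range_noise_sd SD (m) of the latent range-size noise.
#' @param detection_prob Per-(species, plot) Bernoulli detection probability.
#' @param group_proportions Named proportions over biogeographical affinities
#'   (`temperate`, `tropical`, `cosmopolitan`); must sum to 1.
#' @param woody_fraction Fraction of the pool assigned the woody life form.
#' @param group_slopes Optional named list overriding `rapoport_slope_b` per
#'   affinity group (plants group-specific trends); `NULL` keeps geometry
#'   independent of the labels.
#' @param plot_jitter_sd SD (m) of optional jitter on the even plot grid
#'   (jittered elevations are clamped to the domain). `0` keeps the grid exact.
#' @param truncate_ranges Clip occupied intervals to the domain (default).
#' @param t0 Reference mean annual temperature (deg C) at 0 m a.s.l.
#' @param lapse_rate Temperature lapse rate, K per km of elevation.
#' @param seasonal_amplitude Half-range (K) of the annual temperature cycle.
#' @param temp_noise_sd,precip_noise_sd Monthly observation noise SDs
#'   (deg C, mm).
#' @param precip_base Annual precipitation (mm) at 0 m a.s.l.
#' @param precip_gradient Change in annual precipitation per metre of
#'   elevation (mm/m; negative = drier uphill).
#' @param monsoon_strength Relative amplitude (0--1) of the annual
#'   precipitation cycle peaking in July.
#' @param station_elevations Elevations (m) of the climate stations; the
#'   default six are 2457, 2792, 3368, 3740, 4140 and 5230 m.
#' @param n_years Number of simulated station years.
#' @param lgm_cooling Mean present-minus-LGM temperature offset (K).
#' @param lgm_drying Mean present-minus-LGM annual precipitation offset (mm).
#' @param pop_centers Data frame (`name`, `elevation_m`, `population`) of
#'   the population centers; the default two towns sit at 2,700 and 4,200 m.
#' @param background_villages Additional small settlements along the valley;
#'   together with the two towns they make the interpolated population
#'   surface bimodal with peaks at the towns (a surface interpolated from
#'   the towns alone would be flat or monotone between them).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(domain_low = 1800,
                             domain_high = 5400,
                             n_plots = 96,
                             n_species = 545,
                             rapoport_slope_b = 0.25,
                             base_range_a = 350,
                             range_noise_sd = 150,
                             detection_prob = 0.9,
                             group_proportions = c(temperate = 0.62,
                                                   tropical = 0.21,
                                                   cosmopolitan = 0.17),
                             woody_fraction = 0.29,
                             group_slopes = NULL,
                             plot_jitter_sd = 0,
                             truncate_ranges = TRUE,
                             t0 = 20,
                             lapse_rate = 5.5,
                             seasonal_amplitude = 9,
                             temp_noise_sd = 0.3,
                             precip_noise_sd = 4,
                             precip_base = 1500,
                             precip_gradient = -0.2,
                             monsoon_strength = 0.8,
                             station_elevations = c(2457, 2792, 3368,
                                                    3740, 4140, 5230),
                             n_years = 3,
                             lgm_cooling = 5,
                             lgm_drying = 180,
                             pop_centers = data.frame(
                               name = c("gyirong_town", "zongga_town"),
                               elevation_m = c(2700, 4200),
                               population = c(4500, 3800)),
                             background_villages = data.frame(
                               name = sprintf("village_%d", 1:6),
                               elevation_m = c(1900, 2250, 3300, 3750,
                                               4800, 5300),
                               population = c(220, 380, 300, 260, 140, 60)),
                             seed = 1L) {
  cfg <- list(domain_low = domain_low, domain_high = domain_high,
              n_plots = n_plots, n_species = n_species,
              rapoport_slope_b = rapoport_slope_b,
              base_range_a = base_range_a,
              range_noise_sd = range_noise_sd,
              detection_prob = detection_prob,
              group_proportions = group_proportions,
              woody_fraction = woody_fraction,
              group_slopes = group_slopes,
              plot_jitter_sd = plot_jitter_sd,
              truncate_ranges = isTRUE(truncate_ranges),
              t0 = t0, lapse_rate = lapse_rate,
              seasonal_amplitude = seasonal_amplitude,
              temp_noise_sd = temp_noise_sd,
              precip_noise_sd = precip_noise_sd,
              precip_base = precip_base,
              precip_gradient = precip_gradient,
              monsoon_strength = monsoon_strength,
              station_elevations = station_elevations,
              n_years = n_years,
              lgm_cooling = lgm_cooling, lgm_drying = lgm_drying,
              pop_centers = pop_centers,
              background_villages = background_villages,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @param config Object to validate.
#' @export
validate_synthetic_config <- function(config) {
  fail <- function(field, why) {
    abort_("invalid synthetic config field '", field, "': ", why)
  }
  for (f in c("domain_low", "domain_high", "rapoport_slope_b", "base_range_a",
              "range_noise_sd", "detection_prob", "woody_fraction",
              "plot_jitter_sd", "t0", "lapse_rate", "seasonal_amplitude",
              "temp_noise_sd", "precip_noise_sd", "precip_base",
              "precip_gradient", "monsoon_strength", "lgm_cooling",
              "lgm_drying")) {
    if (!is_num1(config[[f]])) fail(f, "must be a single finite number")
  }
  if (config$domain_low >= config$domain_high)
    fail("domain_low", "domain_low must be < domain_high")
  if (!is_num1(config$n_plots) || config$n_plots < 2)
    fail("n_plots", "need at least 2 plots")
  if (!is_num1(config$n_species) || config$n_species < 1)
    fail("n_species", "need at least 1 species")
  if (config$detection_prob < 0 || config$detection_prob > 1)
    fail("detection_prob", "must lie in [0, 1]")
  gp <- config$group_proportions
  if (is.null(names(gp)) || any(names(gp) == "") || any(gp < 0) ||
      abs(sum(gp) - 1) > 1e-8)
    fail("group_proportions", "must be named, nonnegative and sum to 1")
  if (config$woody_fraction < 0 || config$woody_fraction > 1)
    fail("woody_fraction", "must lie in [0, 1]")
  if (config$range_noise_sd < 0) fail("range_noise_sd", "must be >= 0")
  if (!is.numeric(config$station_elevations) ||
      length(config$station_elevations) < 2)
    fail("station_elevations", "need >= 2 station elevations")
  if (!is_num1(config$n_years) || config$n_years < 1)
    fail("n_years", "need >= 1 year")
  pc <- config$pop_centers
  if (!is.data.frame(pc) || nrow(pc) < 1 ||
      !all(c("elevation_m", "population") %in% names(pc)))
    fail("pop_centers", "must be a nonempty data frame with elevation_m and population")
  if (any(pc$elevation_m < config$domain_low |
          pc$elevation_m > config$domain_high))
    fail("pop_centers", "village elevations must lie inside the domain")
  bg <- config$background_villages
  if (!is.null(bg) && nrow(bg) &&
      any(bg$elevation_m < config$domain_low |
          bg$elevation_m > config$domain_high))
    fail("background_villages", "village elevations must lie inside the domain")
  if (!is_num1(config$seed)) fail("seed", "must be a single integer")
  config
}

# even plot grid over the domain, optionally jittered, always inside the domain
plot_grid <- function(config) {
  elev <- seq(config$domain_low, config$domain_high,
              length.out = config$n_plots)
  if (config$plot_jitter_sd > 0) {
    elev <- elev + stats::rnorm(config$n_plots, 0, config$plot_jitter_sd)
    elev <- pmin(pmax(elev, config$domain_low), config$domain_high)
    elev <- sort(elev)
  }
  data.frame(plot_id = sprintf("P%03d", seq_len(config$n_plots)),
             elevation_m = elev)
}

#' Generate a synthetic plot-by-species community with a planted range slope
#'
#' Draws species midpoints uniformly over the domain, latent range sizes from
#' the planted linear model, shifts occupied intervals into the domain
#' (unless disabled), and thins presences with i.i.d. Bernoulli detection. Group
#' labels (life form, areal type) are drawn independently of the range
#' geometry unless `group_slopes` is set in the config.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements
#'   * `occ`: an [occurrence_data()] object (plot table + presence matrix),
#'   * `traits`: data frame `species_id`, `life_form`, `areal_type`,
#'   * `latent`: data frame of true midpoints, latent and clipped interval
#'     bounds and sizes (for diagnostics and parameter-recovery tests).
#' @export
generate_community <- function(config) {
  config <- validate_synthetic_config(config)
  set.seed(config$seed)

  plots <- plot_grid(config)
  ns <- config$n_species
  species_id <- sprintf("sp%04d", seq_len(ns))

  # trait labels first so optional per-group slopes can apply
  gp <- config$group_proportions
  affinity <- sample(names(gp), ns, replace = TRUE, prob = gp)
  life_form <- sample(c("woody", "herbaceous"), ns, replace = TRUE,
                      prob = c(config$woody_fraction,
                               1 - config$woody_fraction))
  lut <- areal_type_lookup()
  areal_type <- vapply(affinity, function(a) {
    pool <- lut$areal_type[lut$affinity == a]
    if (!length(pool)) a else sample(pool, 1)
  }, character(1), USE.NAMES = FALSE)

  b <- rep(config$rapoport_slope_b, ns)
  if (!is.null(config$group_slopes)) {
    for (g in names(config$group_slopes)) b[affinity == g] <- config$group_slopes[[g]]
  }

  width <- config$domain_high - config$domain_low
  midpoint <- stats::runif(ns, config$domain_low, config$domain_high)
  latent_size <- pmax(0, config$base_range_a +
                        b * (midpoint - config$domain_low) +
                        stats::rnorm(ns, 0, config$range_noise_sd))
  lo <- midpoint - latent_size / 2
  hi <- midpoint + latent_size / 2
  if (config$truncate_ranges) {
    # shift the interval minimally so it fits inside the domain, preserving
    # the planted size (sizes wider than the domain collapse to the domain)
    size_in <- pmin(latent_size, width)
    lo <- pmin(pmax(lo, config$domain_low), config$domain_high - size_in)
    hi <- lo + size_in
  }

  # presence: plot inside the (closed) occupied interval, then detection
  inside <- outer(plots$elevation_m, lo, ">=") & outer(plots$elevation_m, hi, "<=")
  if (config$detection_prob < 1) {
    seen <- matrix(stats::runif(length(inside)) <= config$detection_prob,
                   nrow = nrow(inside))
    inside <- inside & seen
  }
  mat <- matrix(as.integer(inside), nrow = nrow(plots),
                dimnames = list(plots$plot_id, species_id))

  traits <- data.frame(species_id = species_id, life_form = life_form,
                       areal_type = areal_type)
  latent <- data.frame(species_id = species_id, midpoint_m = midpoint,
                       latent_size_m = latent_size,
                       interval_low_m = lo, interval_high_m = hi,
                       clipped_size_m = hi - lo)
  list(occ = occurrence_data(plots, mat), traits = traits, latent = latent)
}

# annual temperature cycle centred on July (month 7)
seasonal_cycle <- function(month) cos(2 * pi * (month - 7) / 12)

#' Generate monthly climate series for the valley's weather stations
#'
#' Temperature follows a linear lapse with elevation plus a July-peaked cosine
#' annual cycle; precipitation declines linearly with elevation, carries a
#' monsoon-peaked annual cycle and is floored at zero. Both get i.i.d.
#' Gaussian monthly noise.
#'
#' @param config A [synthetic_config()].
#' @return Data frame `station_id`, `elevation_m`, `year`, `month`, `temp_c`,
#'   `precip_mm` with `n_years` * 12 rows per station.
#' @export
generate_station_climate <- function(config) {
  config <- validate_synthetic_config(config)
  set.seed(config$seed + 1L)
  z <- config$station_elevations
  grid <- expand.grid(month = 1:12,
                      year = 2015L + seq_len(config$n_years),
                      station = seq_along(z))
  zz <- z[grid$station]
  temp <- config$t0 - config$lapse_rate * zz / 1000 +
    config$seasonal_amplitude * seasonal_cycle(grid$month) +
    stats::rnorm(nrow(grid), 0, config$temp_noise_sd)
  annual_precip <- pmax(0, config$precip_base + config$precip_gradient * zz)
  precip <- pmax(0, annual_precip / 12 *
                   (1 + config$monsoon_strength * seasonal_cycle(grid$month)) +
                   stats::rnorm(nrow(grid), 0, config$precip_noise_sd))
  data.frame(station_id = sprintf("S%d", grid$station),
             elevation_m = zz,
             year = grid$year,
             month = grid$month,
             temp_c = temp,
             precip_mm = precip)
}

# smooth present-minus-LGM offsets along elevation: overall decline with a
# trough near 2,700 m, mirroring the valley's glacial-refugium signature
lgm_offset_curves <- function(config, elev) {
  width <- config$domain_high - config$domain_low
  rel <- (elev - config$domain_low) / width
  trough <- exp(-((elev - 2700) / 300)^2)
  shape <- 1.25 - 0.5 * rel - 0.25 * trough
  list(tc = config$lgm_cooling * shape, pc = config$lgm_drying * shape)
}

#' Generate the LGM climate scenario and the village population table
#'
#' The Last Glacial Maximum layer is the present climate minus a smooth
#' elevation-dependent offset, emitted for three synthetic stand-in climate
#' models whose offsets straddle the mean (so downstream model averaging is
#' exercised). Villages default to two towns at 2,700 and 4,200 m a.s.l.,
#' which makes the inverse-distance-weighted population surface bimodal.
#'
#' @param config A [synthetic_config()].
#' @param plots Data frame with `plot_id` and `elevation_m` (defaults to the
#'   config's even grid).
#' @param present_mat,present_map Optional per-plot present-day mean annual
#'   temperature (deg C) and precipitation (mm); default to the config's
#'   noiseless lapse/precipitation curves.
#' @return A list with `villages` (name, elevation_m, population) and `lgm`
#'   (plot_id, model, mat_c, map_mm), one row per plot x model.
#' @export
generate_env_scenario <- function(config, plots = plot_grid(config),
                                  present_mat = NULL, present_map = NULL) {
  config <- validate_synthetic_config(config)
  elev <- plots$elevation_m
  if (is.null(present_mat))
    present_mat <- config$t0 - config$lapse_rate * elev / 1000
  if (is.null(present_map))
    present_map <- pmax(0, config$precip_base + config$precip_gradient * elev)
  off <- lgm_offset_curves(config, elev)
  # per-model shifts average to zero, so the 3-model mean recovers the curve
  model_shift_t <- c(gcm_synth_a = -0.5, gcm_synth_b = 0, gcm_synth_c = 0.5)
  model_shift_p <- c(gcm_synth_a = -20, gcm_synth_b = 0, gcm_synth_c = 20)
  lgm <- do.call(rbind, lapply(names(model_shift_t), function(m) {
    data.frame(plot_id = plots$plot_id, model = m,
               mat_c = present_mat - (off$tc + model_shift_t[[m]]),
               map_mm = present_map - (off$pc + model_shift_p[[m]]))
  }))
  towns <- data.frame(name = as.character(config$pop_centers$name %||%
                                            sprintf("v%d", seq_len(nrow(config$pop_centers)))),
                      elevation_m = config$pop_centers$elevation_m,
                      population = config$pop_centers$population)
  bg <- config$background_villages
  villages <- if (!is.null(bg) && nrow(bg)) {
    rbind(towns, bg[c("name", "elevation_m", "population")])
  } else towns
  list(villages = villages, lgm = lgm)
}

#' Write all synthetic inputs as the CSV files the pipeline reads
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comm <- generate_community(config)
  clim <- generate_station_climate(config)
  scen <- generate_env_scenario(config, plots = comm$occ$plots)
  paths <- c(plots = file.path(dir, "plots.csv"),
             matrix = file.path(dir, "occurrence_matrix.csv"),
             traits = file.path(dir, "species_traits.csv"),
             stations = file.path(dir, "station_climate.csv"),
             villages = file.path(dir, "villages.csv"),
             lgm = file.path(dir, "lgm_climate.csv"))
  write_table_csv(comm$occ$plots, paths[["plots"]])
  mat_df <- data.frame(plot_id = rownames(comm$occ$matrix),
                       comm$occ$matrix, check.names = FALSE)
  write_table_csv(mat_df, paths[["matrix"]])
  write_table_csv(comm$traits, paths[["traits"]])
  write_table_csv(clim, paths[["stations"]])
  write_table_csv(scen$villages, paths[["villages"]])
  write_table_csv(scen$lgm, paths[["lgm"]])
  invisible(paths)
}
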