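#' Per-station climate summaries from monthly series
#'
#' For every station-year: MAT is the mean of the 12 monthly mean
#' temperatures; MAP the sum of monthly precipitation; TS the standard
#' deviation of the monthly means (population form, n = 12, in deg C, by
#' default); MATR the warmest-month minus coldest-month monthly mean. Each
#' summary is then averaged across years per station.
#'
#' @param series Data frame `station_id`, `elevation_m`, `year`, `month`,
#'   `temp_c`, `precip_mm`, with complete 12-month years.
#' @param ts_form `"population"` (divide by n) or `"sample"` (n - 1) for the
#'   temperature-seasonality SD.
#' @return Data frame `station_id`, `elevation_m`, `mat`, `map`, `ts`,
#'   `matr`, one row per station, ordered by elevation.
#' @export
station_summaries <- function(series, ts_form = c("population", "sample")) {
  ts_form <- match.arg(ts_form)
  need <- c("station_id", "elevation_m", "year", "month", "temp_c", "precip_mm")
  if (!all(need %in% names(series)))
    abort_("station series must have columns ", paste(need, collapse = ", "))
  sd_fun <- if (ts_form == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else stats::sd

  per_year <- lapply(split(series, list(series$station_id, series$year),
                           drop = TRUE), function(d) {
    if (!setequal(d$month, 1:12) || nrow(d) != 12)
      abort_("incomplete monthly series for station ", d$station_id[1],
             ", year ", d$year[1])
    data.frame(station_id = d$station_id[1], elevation_m = d$elevation_m[1],
               mat = mean(d$temp_c), map = sum(d$precip_mm),
               ts = sd_fun(d$temp_c), matr = max(d$temp_c) - min(d$temp_c))
  })
  yearly <- do.call(rbind, per_year)
  agg <- stats::aggregate(yearly[c("mat", "map", "ts", "matr")],
                          by = yearly[c("station_id", "elevation_m")], mean)
  agg[order(agg$elevation_m), , drop = FALSE]
}

# variogram evaluators; the linear model's scale cancels in the weights
variogram_fun <- function(model = c("linear", "spherical"), range = NULL,
                          sill = 1) {
  model <- match.arg(model)
  if (model == "linear") return(function(h) h)
  function(h) {
    h <- pmin(h / range, 1)
    sill * (1.5 * h - 0.5 * h^3)
  }
}

#' One-dimensional ordinary kriging along the elevation axis
#'
#' Solves the ordinary-kriging system (variogram matrix bordered by the
#' unbiasedness constraint) for each target elevation. The default linear
#' variogram `gamma(h) = h` is parameter-free up to a scale that cancels in
#' the weights; a spherical model is available when a range parameter can be
#' justified. The interpolator is exact at station elevations; extrapolation
#' beyond the station span is permitted and reported with a message.
#'
#' @param station_elevs,station_values Station elevations (m) and the values
#'   observed there (duplicate elevations must carry identical values).
#' @param target_elevs Elevations (m) at which to predict.
#' @param variogram `"linear"` or `"spherical"`.
#' @param vario_range,vario_sill Spherical-variogram parameters (range
#'   defaults to the station span).
#' @return Numeric vector of predictions at `target_elevs`.
#' @export
krige_1d <- function(station_elevs, station_values, target_elevs,
                     variogram = c("linear", "spherical"),
                     vario_range = NULL, vario_sill = 1) {
  variogram <- match.arg(variogram)
  if (length(station_elevs) != length(station_values))
    abort_("station elevations and values differ in length")
  if (anyDuplicated(station_elevs)) {
    for (z in unique(station_elevs[duplicated(station_elevs)])) {
      vals <- station_values[station_elevs == z]
      if (length(unique(vals)) > 1)
        abort_("conflicting values at duplicated station elevation ", z)
    }
    keep <- !duplicated(station_elevs)
    station_elevs <- station_elevs[keep]
    station_values <- station_values[keep]
  }
  k <- length(station_elevs)
  if (k < 2) abort_("need >= 2 stations with distinct elevations")
  if (is.null(vario_range))
    vario_range <- diff(range(station_elevs))
  gamma <- variogram_fun(variogram, range = vario_range, sill = vario_sill)

  out_span <- target_elevs < min(station_elevs) | target_elevs > max(station_elevs)
  if (any(out_span))
    message(sum(out_span), " target(s) outside the station span ",
            min(station_elevs), "-", max(station_elevs),
            " m: kriging extrapolates there")

  G <- gamma(abs(outer(station_elevs, station_elevs, "-")))
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  rhs <- rbind(gamma(abs(outer(station_elevs, target_elevs, "-"))),
               rep(1, length(target_elevs)))
  sol <- solve(A, rhs)
  as.numeric(crossprod(sol[seq_len(k), , drop = FALSE], station_values))
}

#' Inverse-distance-weighted interpolation of village populations
#'
#' `POP(t) = sum w_i pop_i / sum w_i` with `w_i = d(t, v_i)^(-power)`. A
#' target coincident with a village takes that village's population (the
#' limit convention); if several villages share the location, the first in
#' input order wins.
#'
#' @param villages Data frame with `population` and either `elevation_m` or
#'   `x`/`y` coordinates.
#' @param targets Numeric vector of target elevations, or a data frame /
#'   matrix of `x`/`y` coordinates matching the village coordinates.
#' @param power Positive IDW exponent (default 2).
#' @return Numeric vector of interpolated populations at the targets.
#' @export
idw_population <- function(villages, targets, power = 2) {
  if (!is.data.frame(villages) || !nrow(villages) ||
      !"population" %in% names(villages))
    abort_("villages must be a nonempty data frame with a population column")
  if (!is_num1(power) || power <= 0) abort_("power must be > 0")
  if (all(c("x", "y") %in% names(villages)) && !is.numeric(targets)) {
    tx <- as.matrix(targets[, c("x", "y")])
    vx <- as.matrix(villages[, c("x", "y")])
    D <- sqrt(outer(tx[, 1], vx[, 1], "-")^2 + outer(tx[, 2], vx[, 2], "-")^2)
  } else {
    if (!"elevation_m" %in% names(villages))
      abort_("villages need elevation_m (or x/y) coordinates")
    D <- abs(outer(as.numeric(targets), villages$elevation_m, "-"))
  }
  pop <- villages$population
  apply(D, 1, function(d) {
    hit <- which(d == 0)
    if (length(hit)) return(pop[hit[1]])
    w <- d^(-power)
    sum(w * pop) / sum(w)
  })
}

#' Present-minus-LGM climate deltas per plot
#'
#' When several LGM models are supplied they are averaged per plot first
#' (mirroring the use of a multi-model mean), then `TC = present MAT - LGM
#' MAT` and `PC = present MAP - LGM MAP`; positive values mean the present is
#' warmer/wetter than the Last Glacial Maximum.
#'
#' @param present Data frame `plot_id`, `mat`, `map` (present day).
#' @param lgm Data frame `plot_id`, `mat_c`, `map_mm`, optionally `model`
#'   (one row per plot per model).
#' @return Data frame `plot_id`, `tc`, `pc` in the order of `present`.
#' @export
lgm_deltas <- function(present, lgm) {
  if (!all(c("plot_id", "mat", "map") %in% names(present)))
    abort_("present table needs plot_id, mat, map")
  if (!all(c("plot_id", "mat_c", "map_mm") %in% names(lgm)))
    abort_("lgm table needs plot_id, mat_c, map_mm")
  avg <- stats::aggregate(lgm[c("mat_c", "map_mm")],
                          by = lgm["plot_id"], mean)
  idx <- match(present$plot_id, avg$plot_id)
  if (anyNA(idx))
    abort_("LGM layer missing plot(s): ",
           paste(utils::head(present$plot_id[is.na(idx)], 5), collapse = ", "))
  data.frame(plot_id = present$plot_id,
             tc = present$mat - avg$mat_c[idx],
             pc = present$map - avg$map_mm[idx])
}

#' Assemble the per-plot environmental predictor table
#'
#' Joins the kriged climate summaries, population surface, glacial deltas and
#' mid-domain prediction into one complete row per plot, in the fixed column
#' order MAT, MAP, MATR, TS, TC, PC, MDE, POP. Any plot missing from any
#' component is an error naming the plot and the variable -- the table never
#' carries silent missing values.
#'
#' @param plots Data frame `plot_id`, `elevation_m`.
#' @param climate Data frame `plot_id`, `mat`, `map`, `matr`, `ts`.
#' @param pop Data frame `plot_id`, `pop`.
#' @param deltas Data frame `plot_id`, `tc`, `pc` (see [lgm_deltas()]).
#' @param mde [simulate_mde()] result or data frame with `plot_id`,
#'   `mde_predicted_mean_m`.
#' @return Data frame `plot_id`, `elevation_m`, `mat`, `map`, `matr`, `ts`,
#'   `tc`, `pc`, `mde`, `pop`.
#' @export
assemble_env_table <- function(plots, climate, pop, deltas, mde) {
  pull <- function(tab, cols, what) {
    idx <- match(plots$plot_id, tab$plot_id)
    if (anyNA(idx))
      abort_("missing plot '", plots$plot_id[which(is.na(idx))[1]],
             "' in component '", what, "'")
    out <- tab[idx, cols, drop = FALSE]
    for (cl in cols) if (anyNA(out[[cl]]))
      abort_("missing value of '", cl, "' for plot '",
             plots$plot_id[which(is.na(out[[cl]]))[1]], "'")
    out
  }
  cli <- pull(climate, c("mat", "map", "matr", "ts"), "climate")
  de <- pull(deltas, c("tc", "pc"), "lgm deltas")
  md <- pull(as.data.frame(mde), "mde_predicted_mean_m", "mde")
  po <- pull(pop, "pop", "population")
  data.frame(plot_id = plots$plot_id, elevation_m = plots$elevation_m,
             mat = cli$mat, map = cli$map, matr = cli$matr, ts = cli$ts,
             tc = de$tc, pc = de$pc, mde = md$mde_predicted_mean_m,
             pop = po$pop, row.names = NULL)
}
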