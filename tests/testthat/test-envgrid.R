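make_series <- function(temp_fun, precip_fun, years = 2016:2017,
                        elevs = c(1000, 2000)) {
  g <- expand.grid(month = 1:12, year = years, station = seq_along(elevs))
  data.frame(station_id = paste0("S", g$station),
             elevation_m = elevs[g$station], year = g$year, month = g$month,
             temp_c = temp_fun(g$month, elevs[g$station]),
             precip_mm = precip_fun(g$month, elevs[g$station]))
}

test_that("station summaries compute MAT, MAP, TS and MATR as defined", {
  s <- make_series(function(m, z) rep(10, length(m)),
                   function(m, z) rep(100, length(m)))
  out <- station_summaries(s)
  expect_equal(out$mat, c(10, 10))
  expect_equal(out$map, c(1200, 1200))
  expect_equal(out$ts, c(0, 0))
  expect_equal(out$matr, c(0, 0))

  # sinusoidal monthlies with amplitude A give MATR = 2A
  A <- 7
  s2 <- make_series(function(m, z) A * cos(2 * pi * (m - 7) / 12),
                    function(m, z) rep(1, length(m)))
  out2 <- station_summaries(s2)
  expect_equal(out2$matr, c(2 * A, 2 * A))
  expect_equal(out2$ts, rep(sqrt(mean((A * cos(2 * pi * (1:12 - 7) / 12))^2)), 2))

  s3 <- s[!(s$station_id == "S1" & s$year == 2016 & s$month == 5), ]
  expect_error(station_summaries(s3), "S1.*2016")
})

test_that("ordinary kriging is exact at stations and averages midpoints", {
  st_z <- c(2457, 2792, 3368, 3740, 4140, 5230)
  st_v <- c(8.4, 6.5, 3.4, 1.3, -0.9, -6.9)
  expect_equal(krige_1d(st_z, st_v, st_z), st_v, tolerance = 1e-9)
  # two stations: midpoint prediction is the arithmetic mean
  expect_equal(krige_1d(c(1000, 2000), c(4, 10), 1500), 7, tolerance = 1e-12)
  # monotone between two stations with the linear variogram
  between <- krige_1d(c(1000, 2000), c(4, 10), seq(1000, 2000, by = 100))
  expect_true(all(diff(between) > 0))
})

test_that("three-station kriging solves the bordered linear system", {
  st_z <- c(1000, 1800, 2600)
  st_v <- c(12, 9, 2)
  target <- 1450
  # independent oracle: write the ordinary-kriging equations literally
  G <- abs(outer(st_z, st_z, "-"))
  A <- rbind(cbind(G, 1), c(1, 1, 1, 0))
  b <- c(abs(target - st_z), 1)
  w <- solve(A, b)[1:3]
  expect_equal(krige_1d(st_z, st_v, target), sum(w * st_v),
               tolerance = 1e-10)
})

test_that("kriging is linear in the data and validates duplicates", {
  st_z <- c(1000, 1500, 2200, 3000)
  st_v <- c(5, 3, 8, 1)
  targets <- c(900, 1250, 2600, 3300)
  expect_equal(krige_1d(st_z, 2 * st_v, targets),
               2 * krige_1d(st_z, st_v, targets), tolerance = 1e-9)
  expect_error(krige_1d(c(1000, 1000, 2000), c(1, 2, 3), 1500),
               "conflicting")
  expect_equal(krige_1d(c(1000, 1000, 2000), c(1, 1, 3), 2000), 3,
               tolerance = 1e-9)
  expect_error(krige_1d(1000, 5, 1500), ">= 2 stations")
})

test_that("IDW reproduces villages exactly and respects its bounds", {
  v <- data.frame(name = c("a", "b"), elevation_m = c(2700, 4200),
                  population = c(100, 300))
  expect_equal(idw_population(v, c(2700, 4200)), c(100, 300))
  expect_equal(idw_population(v, 3450), 200)  # equidistant: plain mean
  # distances 1 and 2, power 2: (100*1 + 300*0.25) / 1.25 = 140
  v2 <- data.frame(elevation_m = c(101, 104), population = c(100, 300))
  expect_equal(idw_population(v2, 102), 140)
  grid <- idw_population(v, seq(1800, 5400, by = 100))
  expect_true(all(grid >= 100 & grid <= 300))
  # coincident villages: first in input order wins
  v3 <- data.frame(elevation_m = c(2000, 2000), population = c(10, 90))
  expect_equal(idw_population(v3, 2000), 10)
})

test_that("LGM deltas subtract the multi-model mean from the present", {
  present <- data.frame(plot_id = c("A", "B"), mat = c(10, 5),
                        map = c(800, 500))
  same <- data.frame(plot_id = c("A", "B"), mat_c = c(10, 5),
                     map_mm = c(800, 500))
  d0 <- lgm_deltas(present, same)
  expect_equal(d0$tc, c(0, 0)); expect_equal(d0$pc, c(0, 0))

  colder <- transform(same, mat_c = mat_c - 5)
  expect_equal(lgm_deltas(present, colder)$tc, c(5, 5))

  three <- do.call(rbind, lapply(c(-4, -5, -6), function(o)
    data.frame(plot_id = c("A", "B"), model = paste0("m", o),
               mat_c = present$mat + o, map_mm = present$map)))
  expect_equal(lgm_deltas(present, three)$tc, c(5, 5))
  expect_error(lgm_deltas(present, same[1, ]), "B")
})

test_that("env table assembly is complete, ordered, and CSV round-trips", {
  cfg <- synthetic_config(n_plots = 10, n_species = 40, seed = 77)
  comm <- generate_community(cfg)
  plots <- comm$occ$plots
  summ <- station_summaries(generate_station_climate(cfg))
  climate <- data.frame(
    plot_id = plots$plot_id,
    mat = krige_1d(summ$elevation_m, summ$mat, plots$elevation_m),
    map = krige_1d(summ$elevation_m, summ$map, plots$elevation_m),
    ts = krige_1d(summ$elevation_m, summ$ts, plots$elevation_m),
    matr = krige_1d(summ$elevation_m, summ$matr, plots$elevation_m))
  scen <- generate_env_scenario(cfg, plots = plots,
                                present_mat = climate$mat,
                                present_map = climate$map)
  pop <- data.frame(plot_id = plots$plot_id,
                    pop = idw_population(scen$villages, plots$elevation_m))
  deltas <- lgm_deltas(
    data.frame(plot_id = plots$plot_id, mat = climate$mat, map = climate$map),
    scen$lgm)
  rng <- species_ranges(comm$occ)
  mde <- simulate_mde(setNames(rng$size, rng$species_id), c(1800, 5400),
                      plots$elevation_m, n_sims = 50, seed = 5,
                      plot_id = plots$plot_id)
  env <- assemble_env_table(plots, climate, pop, deltas, mde)
  expect_identical(nrow(env), 10L)
  expect_identical(names(env), c("plot_id", "elevation_m", "mat", "map",
                                 "matr", "ts", "tc", "pc", "mde", "pop"))
  expect_false(anyNA(env))
  # kriged MAT never increases with elevation under the lapse generator
  expect_true(all(diff(env$mat) <= 1e-9))
  # round trip
  f <- tempfile(fileext = ".csv")
  write.csv(env, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$mat, env$mat)
  expect_equal(back$mde, env$mde)
  # dropping a plot from any component is an error naming it
  expect_error(assemble_env_table(plots, climate, pop[-3, ], deltas, mde),
               paste0(plots$plot_id[3], ".*population|population.*",
                      plots$plot_id[3]))
})
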