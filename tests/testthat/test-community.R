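test_that("occurrence loading validates its contracts", {
  dir <- file.path(tempdir(), "load_fixture")
  cfg <- synthetic_config(n_plots = 6, n_species = 5, seed = 12)
  paths <- write_synthetic_inputs(cfg, dir)
  loaded <- load_occurrences(paths[["plots"]], paths[["matrix"]],
                             paths[["traits"]])
  expect_s3_class(loaded$occ, "occurrence_data")
  expect_identical(dim(loaded$occ$matrix), c(6L, 5L))
  expect_true(all(loaded$traits$affinity %in%
                    c("temperate", "tropical", "cosmopolitan")))

  # two plots, one species present in both
  occ <- occurrence_data(
    data.frame(plot_id = c("A", "B"), elevation_m = c(100, 200)),
    matrix(c(1L, 1L), 2, 1, dimnames = list(NULL, "sp1")))
  expect_identical(dim(occ$matrix), c(2L, 1L))
  expect_identical(sum(occ$matrix), 2L)

  expect_error(occurrence_data(
    data.frame(plot_id = c("A", "A"), elevation_m = c(1, 2)),
    matrix(0L, 2, 1, dimnames = list(NULL, "sp1"))), "A")
  expect_error(occurrence_data(
    data.frame(plot_id = c("A", "B"), elevation_m = c(1, 2)),
    matrix(c(0, 2), 2, 1, dimnames = list(NULL, "sp1"))),
    "plot 'B', species 'sp1'")
})

test_that("species missing from the traits table are kept as unclassified", {
  dir <- file.path(tempdir(), "load_fixture2")
  cfg <- synthetic_config(n_plots = 5, n_species = 4, seed = 13)
  paths <- write_synthetic_inputs(cfg, dir)
  tr <- read.csv(paths[["traits"]])
  write.csv(tr[-1, ], paths[["traits"]], row.names = FALSE)
  expect_message(
    loaded <- load_occurrences(paths[["plots"]], paths[["matrix"]],
                               paths[["traits"]]),
    "unclassified")
  expect_identical(nrow(loaded$traits), 4L)
  expect_true("unclassified" %in% loaded$traits$affinity)
})

test_that("areal types map to the published affinities", {
  expect_identical(classify_affinity("East Asia"), "temperate")
  expect_identical(classify_affinity("tropical Asia"), "tropical")
  expect_identical(classify_affinity("Cosmopolitan"), "cosmopolitan")
  # case/whitespace insensitive
  expect_identical(classify_affinity("  OLD world   TEMPERATE "), "temperate")
  expect_warning(out <- classify_affinity("Endemic to Mars"), "Mars")
  expect_identical(out, "unclassified")
})

test_that("elevational range is max minus min occupied elevation", {
  plots <- data.frame(plot_id = paste0("P", 1:4),
                      elevation_m = c(2000, 2600, 3100, 5400))
  mat <- cbind(sp_wide = c(1L, 1L, 1L, 0L),
               sp_single = c(0L, 1L, 0L, 0L),
               sp_full = c(1L, 0L, 0L, 1L))
  occ <- occurrence_data(plots, mat)
  rng <- species_ranges(occ)
  expect_equal(rng$size[rng$species_id == "sp_wide"], 1100)
  expect_equal(rng$size[rng$species_id == "sp_single"], 0)
  expect_equal(rng$size[rng$species_id == "sp_full"], 3400)
  # zero-occurrence species excluded with a warning naming them
  mat2 <- cbind(mat, sp_ghost = 0L)
  expect_warning(rng2 <- species_ranges(occurrence_data(plots, mat2)),
                 "sp_ghost")
  expect_false("sp_ghost" %in% rng2$species_id)
})

test_that("range size is monotone in the occupied plot set", {
  set.seed(31)
  for (i in 1:20) {
    occ <- random_occurrence_fixture()
    rng <- species_ranges(occ)
    sp <- sample(colnames(occ$matrix), 1)
    occupied <- occ$matrix[, sp] == 1L
    # add a plot outside the species' occupied interval
    free <- which(!occupied)
    if (!length(free)) next
    occ2 <- occ
    occ2$matrix[sample(free, 1), sp] <- 1L
    rng2 <- species_ranges(occ2)
    expect_gte(rng2$size[rng2$species_id == sp],
               rng$size[rng$species_id == sp])
  }
})

test_that("stevens_profile equals the literal brute-force mean", {
  set.seed(17)
  for (i in 1:10) {
    occ <- random_occurrence_fixture()
    rng <- species_ranges(occ)
    traits <- random_traits_fixture(colnames(occ$matrix))
    traits$affinity <- classify_affinity(traits$areal_type)
    for (g in c("overall", "woody", "temperate")) {
      ids <- switch(g, overall = traits$species_id,
                    woody = traits$species_id[traits$life_form == "woody"],
                    temperate = traits$species_id[traits$affinity == "temperate"])
      prof <- stevens_profile(occ, rng, traits, group = g)
      expect_equal(prof$mean_range_m, brute_force_stevens(occ, rng, ids))
    }
  }
})

test_that("plots without species of the group are missing, not zero", {
  plots <- data.frame(plot_id = c("A", "B"), elevation_m = c(1000, 2000))
  mat <- cbind(sp1 = c(1L, 0L))
  occ <- occurrence_data(plots, mat)
  rng <- species_ranges(occ)
  traits <- data.frame(species_id = "sp1", life_form = "woody",
                       areal_type = "East Asia",
                       affinity = "temperate")
  prof <- stevens_profile(occ, rng, traits, group = "woody")
  expect_true(is.na(prof$mean_range_m[prof$plot_id == "B"]))
  expect_error(stevens_profile(occ, rng, traits, group = "alpine"),
               "unknown group")
})

test_that("overall profile reconstructs from the life-form group profiles", {
  set.seed(23)
  occ <- random_occurrence_fixture(n_plots = 15, n_species = 12)
  rng <- species_ranges(occ)
  traits <- random_traits_fixture(colnames(occ$matrix))
  traits$affinity <- classify_affinity(traits$areal_type)
  overall <- stevens_profile(occ, rng, traits, group = "overall")
  woody <- stevens_profile(occ, rng, traits, group = "woody")
  herb <- stevens_profile(occ, rng, traits, group = "herbaceous")
  n_w <- woody$n_species; n_h <- herb$n_species
  recon <- (ifelse(n_w > 0, n_w * woody$mean_range_m, 0) +
            ifelse(n_h > 0, n_h * herb$mean_range_m, 0)) / (n_w + n_h)
  expect_equal(overall$mean_range_m, ifelse(n_w + n_h > 0, recon, NA_real_))
})

test_that("group percentages follow the count/total formula to two decimals", {
  traits <- data.frame(
    species_id = sprintf("s%03d", 1:545),
    life_form = rep(c("woody", "herbaceous"), c(158, 387)),
    areal_type = NA,
    affinity = rep(c("temperate", "tropical", "cosmopolitan"),
                   c(337, 112, 96)))
  pct <- group_percentages(traits)
  get <- function(g) pct$percentage[pct$group == g]
  expect_equal(get("woody"), 28.99)
  expect_equal(get("herbaceous"), 71.01)
  expect_equal(get("temperate"), 61.83)
  expect_equal(get("tropical"), 20.55)
  one <- group_percentages(data.frame(species_id = "a", life_form = "woody",
                                      affinity = "temperate"))
  expect_equal(one$percentage[one$group == "woody"], 100)
})
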