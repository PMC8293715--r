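# Fixture builders and independent brute-force oracles used across tests.

# small random occurrence fixture (every species guaranteed >= 1 occurrence)
random_occurrence_fixture <- function(n_plots = 12, n_species = 8,
                                      domain = c(1000, 3000)) {
  plots <- data.frame(plot_id = sprintf("P%02d", seq_len(n_plots)),
                      elevation_m = sort(runif(n_plots, domain[1], domain[2])))
  mat <- matrix(rbinom(n_plots * n_species, 1, 0.4), n_plots,
                dimnames = list(plots$plot_id,
                                sprintf("sp%02d", seq_len(n_species))))
  for (j in seq_len(n_species))
    if (sum(mat[, j]) == 0) mat[sample.int(n_plots, 1), j] <- 1L
  occurrence_data(plots, mat)
}

random_traits_fixture <- function(species_ids) {
  data.frame(species_id = species_ids,
             life_form = sample(c("woody", "herbaceous"),
                                length(species_ids), replace = TRUE),
             areal_type = sample(c("East Asia", "Tropical Asia",
                                   "Cosmopolitan", "North Temperate"),
                                 length(species_ids), replace = TRUE))
}

# literal per-plot species loop: the Stevens oracle
brute_force_stevens <- function(occ, ranges, species_ids) {
  sapply(seq_len(nrow(occ$plots)), function(p) {
    sizes <- c()
    for (sp in species_ids) {
      if (sp %in% colnames(occ$matrix) && occ$matrix[p, sp] == 1L) {
        sizes <- c(sizes, ranges$size[ranges$species_id == sp])
      }
    }
    if (length(sizes)) mean(sizes) else NA_real_
  })
}

# literal min/max loop: the range oracle
brute_force_ranges <- function(occ) {
  do.call(rbind, lapply(colnames(occ$matrix), function(sp) {
    e <- occ$plots$elevation_m[occ$matrix[, sp] == 1L]
    if (!length(e)) return(NULL)
    data.frame(species_id = sp, size = max(e) - min(e))
  }))
}

# simulate a SAR error process y = x*beta + (I - lambda W)^-1 eps
simulate_sar_data <- function(n, lambda, W, beta = 1) {
  x <- rnorm(n)
  u <- solve(diag(n) - lambda * weights_mat(W), rnorm(n))
  list(x = x, y = beta * x + u)
}

weights_mat <- function(W) if (inherits(W, "spatial_weights")) W$W else W

plot_grid_elev <- function(cfg)
  seq(cfg$domain_low, cfg$domain_high, length.out = cfg$n_plots)
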