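#' Plot-by-species occurrence data
#'
#' Container pairing the plot table (id, elevation, optional x/y coordinates)
#' with a binary plot-by-species presence matrix. Invariants are enforced at
#' construction: unique plot ids, numeric elevations, 0/1 cells, and matching
#' dimensions.
#'
#' @param plots Data frame with columns `plot_id`, `elevation_m` and
#'   optionally `x`, `y`.
#' @param matrix Integer/numeric matrix, plots in rows (rownames = plot ids),
#'   species in columns (colnames = species ids), cells 0/1.
#' @return An object of class `occurrence_data`: a list with `plots` and
#'   `matrix`.
#' @export
occurrence_data <- function(plots, matrix) {
  if (!is.data.frame(plots) || !all(c("plot_id", "elevation_m") %in% names(plots)))
    abort_("plots must be a data frame with plot_id and elevation_m")
  plots$plot_id <- as.character(plots$plot_id)
  dup <- plots$plot_id[duplicated(plots$plot_id)]
  if (length(dup))
    abort_("duplicate plot id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(plots$elevation_m) || anyNA(plots$elevation_m))
    abort_("non-numeric or missing elevation for plot(s): ",
           paste(plots$plot_id[!is.finite(suppressWarnings(as.numeric(plots$elevation_m)))],
                 collapse = ", "))
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (nrow(matrix) != nrow(plots))
    abort_("matrix has ", nrow(matrix), " rows but ", nrow(plots), " plots")
  if (is.null(colnames(matrix)))
    abort_("matrix must carry species ids as column names")
  bad <- which(!(matrix %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(matrix))
    abort_("non-binary cell at plot '", plots$plot_id[rc[1]], "', species '",
           colnames(matrix)[rc[2]], "': ", matrix[bad[1]])
  }
  storage.mode(matrix) <- "integer"
  rownames(matrix) <- plots$plot_id
  structure(list(plots = plots, matrix = matrix), class = "occurrence_data")
}

#' @export
print.occurrence_data <- function(x, ...) {
  cat("occurrence_data:", nrow(x$plots), "plots x", ncol(x$matrix),
      "species;", sum(x$matrix), "presences\n")
  cat("elevations", min(x$plots$elevation_m), "-", max(x$plots$elevation_m),
      "m a.s.l.\n")
  invisible(x)
}

#' Areal-type to biogeographical-affinity lookup
#'
#' The shipped classification maps distribution-center (areal-type) labels to
#' `temperate` (eight northern-temperate categories), `tropical` (the
#' pantropic categories) or `cosmopolitan`, following Wu's areal-type system
#' as used in Himalayan flora studies. Shipped as data for auditability.
#'
#' @return Data frame with columns `areal_type` and `affinity`.
#' @export
areal_type_lookup <- function() {
  path <- system.file("extdata", "areal_types.csv", package = "elevrange")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify areal-type labels into biogeographical affinities
#'
#' Matching is case- and whitespace-insensitive. Unrecognized labels map to
#' `"unclassified"` with a warning; nothing is silently dropped.
#'
#' @param areal_type Character vector of distribution-center labels.
#' @param lookup Lookup table; defaults to [areal_type_lookup()].
#' @return Character vector in
#'   `{temperate, tropical, cosmopolitan, unclassified}`.
#' @export
classify_affinity <- function(areal_type, lookup = areal_type_lookup()) {
  key <- normalize_label(lookup$areal_type)
  idx <- match(normalize_label(areal_type), key)
  out <- lookup$affinity[idx]
  if (anyNA(idx)) {
    unknown <- unique(areal_type[is.na(idx)])
    warning("unrecognized areal type(s), classified as 'unclassified': ",
            paste(unknown, collapse = ", "), call. = FALSE)
    out[is.na(idx)] <- "unclassified"
  }
  out
}

#' Load survey CSVs into validated occurrence and trait objects
#'
#' Expects the pipeline's CSV dialect: `plot_csv` with `plot_id`,
#' `elevation_m` (optional `x`, `y`); `matrix_csv` with `plot_id` first and
#' one 0/1 column per species; `traits_csv` with `species_id`, `life_form`,
#' `areal_type`. Species present in the matrix but missing from the traits
#' table are retained with affinity `"unclassified"` (with a message).
#'
#' @param plot_csv,matrix_csv,traits_csv File paths.
#' @return List with `occ` ([occurrence_data()]) and `traits` (data frame
#'   `species_id`, `life_form`, `areal_type`, `affinity`).
#' @export
load_occurrences <- function(plot_csv, matrix_csv, traits_csv) {
  for (p in c(plot_csv, matrix_csv, traits_csv))
    if (!file.exists(p)) abort_("input file not found: ", p)
  plots <- utils::read.csv(plot_csv, stringsAsFactors = FALSE)
  if (!is.numeric(plots$elevation_m))
    abort_("non-numeric elevation_m in ", plot_csv, " (row ",
           which(is.na(suppressWarnings(as.numeric(plots$elevation_m))))[1], ")")
  mat_df <- utils::read.csv(matrix_csv, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(mat_df)[1] != "plot_id")
    abort_("first column of ", matrix_csv, " must be plot_id")
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- as.character(mat_df$plot_id)
  if (!identical(rownames(mat), as.character(plots$plot_id)))
    abort_("plot ids in matrix do not match plot table order")
  occ <- occurrence_data(plots, mat)

  traits <- utils::read.csv(traits_csv, stringsAsFactors = FALSE)
  need <- c("species_id", "life_form", "areal_type")
  if (!all(need %in% names(traits)))
    abort_(traits_csv, " must have columns ", paste(need, collapse = ", "))
  missing_sp <- setdiff(colnames(mat), traits$species_id)
  if (length(missing_sp)) {
    message(length(missing_sp),
            " species in matrix lack trait rows; kept as 'unclassified': ",
            paste(utils::head(missing_sp, 5), collapse = ", "),
            if (length(missing_sp) > 5) " ..." else "")
    traits <- rbind(traits,
                    data.frame(species_id = missing_sp,
                               life_form = NA_character_,
                               areal_type = NA_character_))
  }
  traits$affinity <- rep("unclassified", nrow(traits))
  known <- !is.na(traits$areal_type)
  traits$affinity[known] <- classify_affinity(traits$areal_type[known])
  list(occ = occ, traits = traits)
}

#' Per-species elevational ranges from occupied plots
#'
#' The elevational range of a species is the difference between the maximum
#' and minimum elevation of the plots where it was recorded; a species seen
#' in a single plot has range size 0 m. Species with no occurrences are
#' excluded with a warning listing them.
#'
#' @param occ An [occurrence_data()] object.
#' @return Data frame `species_id`, `min_elev`, `max_elev`, `size` (m), one
#'   row per recorded species (matrix column order).
#' @export
species_ranges <- function(occ) {
  stopifnot(inherits(occ, "occurrence_data"))
  elev <- occ$plots$elevation_m
  n_occ <- colSums(occ$matrix)
  absent <- colnames(occ$matrix)[n_occ == 0]
  if (length(absent))
    warning(length(absent), " species with zero occurrences excluded: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) " ..." else "", call. = FALSE)
  keep <- which(n_occ > 0)
  mins <- vapply(keep, function(j) min(elev[occ$matrix[, j] == 1L]), numeric(1))
  maxs <- vapply(keep, function(j) max(elev[occ$matrix[, j] == 1L]), numeric(1))
  data.frame(species_id = colnames(occ$matrix)[keep],
             min_elev = mins, max_elev = maxs, size = maxs - mins,
             row.names = NULL)
}

# species ids belonging to a named group
group_species <- function(traits, group, include_unclassified_overall = TRUE) {
  switch(group,
    overall = if (include_unclassified_overall) traits$species_id
              else traits$species_id[traits$affinity %in% c("temperate", "tropical")],
    woody = traits$species_id[!is.na(traits$life_form) & traits$life_form == "woody"],
    herbaceous = traits$species_id[!is.na(traits$life_form) & traits$life_form == "herbaceous"],
    temperate = traits$species_id[traits$affinity == "temperate"],
    tropical = traits$species_id[traits$affinity == "tropical"],
    abort_("unknown group filter '", group,
           "'; use overall, woody, herbaceous, temperate or tropical"))
}

#' Stevens' per-plot mean range-size profile
#'
#' For every plot, averages the elevational range sizes of exactly the
#' species of the chosen group recorded in that plot. Plots containing no
#' species of the group get `NA` (missing, not zero) and are meant to be
#' dropped from downstream regressions. Cosmopolitan (and unclassified)
#' species never enter the affinity groups; whether they enter `overall` is
#' controlled by `include_unclassified_overall` (default yes: they are
#' recorded species).
#'
#' @param occ An [occurrence_data()] object.
#' @param ranges Output of [species_ranges()].
#' @param traits Trait table with `species_id`, `life_form`, `affinity`
#'   (required for any group other than `overall`).
#' @param group One of `overall`, `woody`, `herbaceous`, `temperate`,
#'   `tropical`.
#' @param include_unclassified_overall Include cosmopolitan/unclassified
#'   species in the `overall` group.
#' @return Data frame `plot_id`, `elevation_m`, `group`, `n_species`,
#'   `mean_range_m`.
#' @export
stevens_profile <- function(occ, ranges, traits = NULL, group = "overall",
                            include_unclassified_overall = TRUE) {
  stopifnot(inherits(occ, "occurrence_data"))
  if (group != "overall" && is.null(traits))
    abort_("traits table required for group '", group, "'")
  ids <- if (is.null(traits) && group == "overall") ranges$species_id
         else group_species(traits, group, include_unclassified_overall)
  ids <- intersect(intersect(ids, ranges$species_id), colnames(occ$matrix))
  size <- ranges$size[match(ids, ranges$species_id)]
  sub <- occ$matrix[, ids, drop = FALSE]
  n_sp <- as.integer(rowSums(sub))
  total <- as.numeric(sub %*% size)
  mean_range <- ifelse(n_sp > 0, total / n_sp, NA_real_)
  data.frame(plot_id = occ$plots$plot_id,
             elevation_m = occ$plots$elevation_m,
             group = group, n_species = n_sp, mean_range_m = mean_range,
             row.names = NULL)
}

#' Counts and percentages of species per group
#'
#' Percentages are 100 x group count / total recorded species, reported to
#' two decimals. Life-form and affinity groupings are tabulated side by side
#' (their percentages need not sum to 100 because cosmopolitan and
#' unclassified species are listed too).
#'
#' @param traits Trait table with `species_id`, `life_form` and either
#'   `affinity` or `areal_type` (affinity is derived if absent).
#' @return Data frame `group`, `n`, `percentage`.
#' @export
group_percentages <- function(traits) {
  if (!nrow(traits)) abort_("empty species list")
  if (is.null(traits$affinity))
    traits$affinity <- classify_affinity(traits$areal_type)
  total <- nrow(traits)
  cnt <- function(x) sum(x, na.rm = TRUE)
  groups <- c(woody = cnt(traits$life_form == "woody"),
              herbaceous = cnt(traits$life_form == "herbaceous"),
              temperate = cnt(traits$affinity == "temperate"),
              tropical = cnt(traits$affinity == "tropical"),
              cosmopolitan = cnt(traits$affinity == "cosmopolitan"),
              unclassified = cnt(traits$affinity == "unclassified"))
  data.frame(group = names(groups), n = as.integer(groups),
             percentage = round(100 * as.integer(groups) / total, 2),
             row.names = NULL)
}
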