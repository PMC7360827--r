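#' Default gene-pool archetypes for simulation
#'
#' Loads the two synthetic pool archetypes shipped with the package
#' (`inst/extdata/pool_archetypes.yaml`): per-trait Normal parameters for
#' the quantitative traits and categorical level probabilities for the
#' qualitative traits, one set per pool. The parameters are invented
#' simulation defaults informed by published group profiles of the Andean
#' (large speckled seeds, erect/determinate, pale flowers) and
#' Mesoamerican (small speckle-free seeds, prostrate/indeterminate, plain
#' coats) gene pools; they are not estimates from real accessions. `LWS`
#' is never sampled — it is derived as `SL / SW` after the draws.
#'
#' @param catalog Catalog the archetypes must cover.
#' @param path Optional path to an alternative archetype YAML file.
#' @return A named list with elements `andean` and `mesoamerican`, each of
#'   class `pool_archetype` (fields `name`, `quantitative`, `qualitative`).
#' @examples
#' arch <- default_archetypes()
#' arch$andean$quantitative$HSW
#' @export
default_archetypes <- function(catalog = default_catalog(), path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pool_archetypes.yaml",
                        package = "beandiv", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  out <- purrr::map(raw[c("andean", "mesoamerican")], function(a) {
    structure(list(name = a$name,
                   quantitative = a$quantitative,
                   qualitative = purrr::map(a$qualitative, as.numeric)),
              class = "pool_archetype")
  })
  purrr::walk(out, check_archetype, catalog = catalog)
  out
}

#' Write archetypes back to a YAML parameter file
#'
#' @param archetypes A list as returned by [default_archetypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_archetypes <- function(archetypes, path) {
  yaml::write_yaml(purrr::map(archetypes, unclass), path)
  invisible(path)
}

check_archetype <- function(archetype, catalog) {
  stopifnot(inherits(archetype, "pool_archetype"))
  for (code in trait_codes(catalog, "quantitative")) {
    if (code == "LWS") next  # derived as SL/SW
    par <- archetype$quantitative[[code]]
    if (is.null(par)) {
      stop("archetype ", archetype$name, " missing quantitative trait ",
           code, call. = FALSE)
    }
    if (is.null(par$sd) || par$sd < 0) {
      stop("archetype ", archetype$name, ": sd for ", code,
           " must be >= 0", call. = FALSE)
    }
  }
  for (code in trait_codes(catalog, "qualitative")) {
    p <- archetype$qualitative[[code]]
    lv <- catalog_levels(catalog, code)
    if (is.null(p)) {
      stop("archetype ", archetype$name, " missing qualitative trait ",
           code, call. = FALSE)
    }
    if (length(p) != length(lv)) {
      stop("archetype ", archetype$name, ": ", code, " needs ",
           length(lv), " level probabilities", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("archetype ", archetype$name, ": ", code,
           " probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  invisible(archetype)
}

# one positive Normal draw per (trait, row); truncation at 0 by resampling
rnorm_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Draw one accession from a pool archetype
#'
#' Quantitative traits are drawn from the archetype's Normal distributions
#' (truncated at zero by resampling, so units stay valid); qualitative
#' traits are drawn categorically over the catalog's declared levels.
#' `LWS` is recomputed as `SL / SW` after the draws rather than sampled.
#' Randomness comes from R's global RNG — seed with `set.seed()` (or use
#' [simulate_collection()], which seeds for you).
#'
#' @param archetype A `pool_archetype`.
#' @param catalog A `trait_catalog`.
#' @return A one-row tibble with one column per catalog trait.
#' @export
sample_accession <- function(archetype, catalog = default_catalog()) {
  check_archetype(archetype, catalog)
  vals <- list()
  for (code in trait_codes(catalog)) {
    d <- catalog_descriptor(catalog, code)
    if (code == "LWS") next
    if (d$kind == "quantitative") {
      par <- archetype$quantitative[[code]]
      vals[[code]] <- if (par$sd == 0) par$mean else
        rnorm_positive(1, par$mean, par$sd)
    } else {
      lv <- catalog_levels(catalog, code)
      vals[[code]] <- sample(lv, 1, prob = archetype$qualitative[[code]])
    }
  }
  if (all(c("SL", "SW") %in% names(vals))) {
    vals$LWS <- vals$SL / vals$SW
  }
  tibble::as_tibble(vals)[, intersect(trait_codes(catalog), names(vals))]
}

#' Draw one introgressed accession as a trait-wise mosaic
#'
#' Each trait is drawn independently from the Andean archetype with
#' probability `lambda` and from the Mesoamerican archetype otherwise, so
#' an introgressed accession carries a mosaic of pool-typical trait
#' values rather than a parametric blend (keeping categorical traits
#' well-defined). `SL` and `SW` come from one parent choice each; `LWS`
#' is derived from the realized values.
#'
#' @param andean,mesoamerican `pool_archetype` objects.
#' @param lambda Probability in `[0, 1]` of drawing a trait from the
#'   Andean parent.
#' @param catalog A `trait_catalog`.
#' @return A one-row tibble of trait values.
#' @export
introgress <- function(andean, mesoamerican, lambda = 0.5,
                       catalog = default_catalog()) {
  if (is.na(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1]", call. = FALSE)
  }
  check_archetype(andean, catalog)
  check_archetype(mesoamerican, catalog)
  vals <- list()
  for (code in trait_codes(catalog)) {
    if (code == "LWS") next
    d <- catalog_descriptor(catalog, code)
    parent <- if (stats::runif(1) < lambda) andean else mesoamerican
    if (d$kind == "quantitative") {
      par <- parent$quantitative[[code]]
      vals[[code]] <- if (par$sd == 0) par$mean else
        rnorm_positive(1, par$mean, par$sd)
    } else {
      lv <- catalog_levels(catalog, code)
      vals[[code]] <- sample(lv, 1, prob = parent$qualitative[[code]])
    }
  }
  if (all(c("SL", "SW") %in% names(vals))) {
    vals$LWS <- vals$SL / vals$SW
  }
  tibble::as_tibble(vals)[, intersect(trait_codes(catalog), names(vals))]
}

#' Simulation configuration
#'
#' Defaults mirror the composition of a 115-accession provincial
#' collection: 52 Andean, 40 Mesoamerican, and an introgressed share of
#' 20% of the final collection (23 accessions), with region weights that
#' put the Mesoamerican pool relatively more in region I and the
#' introgressed accessions more in regions III–IV.
#'
#' @param n_andean,n_mesoamerican Pure-pool accession counts.
#' @param introgression_fraction Share of the *final* collection generated
#'   as introgressed, in `[0, 1)`; the introgressed count is
#'   `round((n_andean + n_mesoamerican) * f / (1 - f))`.
#' @param introgression_lambda Per-trait probability of the Andean parent
#'   for introgressed accessions.
#' @param region_weights Named list of per-pool probability vectors over
#'   regions I–IV (`Andean`, `Mesoamerican`, `Introgressed`).
#' @param seed Integer seed; the simulation is a pure function of
#'   (config, catalog, archetypes).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_andean = 52, n_mesoamerican = 40,
                              introgression_fraction = 0.2,
                              introgression_lambda = 0.5,
                              region_weights = NULL, seed = 1) {
  if (n_andean < 0 || n_mesoamerican < 0) {
    stop("pool counts must be >= 0", call. = FALSE)
  }
  if (introgression_fraction < 0 || introgression_fraction >= 1) {
    stop("introgression_fraction must be in [0, 1)", call. = FALSE)
  }
  if (introgression_lambda < 0 || introgression_lambda > 1) {
    stop("introgression_lambda must be in [0, 1]", call. = FALSE)
  }
  if (is.null(region_weights)) {
    region_weights <- list(
      Andean = c(I = 0.04, II = 0.42, III = 0.24, IV = 0.30),
      Mesoamerican = c(I = 0.14, II = 0.44, III = 0.20, IV = 0.22),
      Introgressed = c(I = 0.03, II = 0.32, III = 0.30, IV = 0.35))
  }
  for (w in region_weights) {
    if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-6) {
      stop("each region weight vector must be 4 non-negative values summing to 1",
           call. = FALSE)
    }
  }
  structure(list(n_andean = as.integer(n_andean),
                 n_mesoamerican = as.integer(n_mesoamerican),
                 introgression_fraction = introgression_fraction,
                 introgression_lambda = introgression_lambda,
                 region_weights = region_weights,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a labeled germplasm collection
#'
#' Generates pure Andean and Mesoamerican accessions from the archetypes
#' plus trait-wise introgressed accessions, assigns each accession a
#' natural ecological region from its pool's region weights, and records
#' the generating pool as ground truth. Deterministic given the config
#' seed.
#'
#' @param config A [simulation_config()].
#' @param catalog A `trait_catalog`.
#' @param archetypes Archetype list as from [default_archetypes()].
#' @return A list of class `labeled_collection`: `collection` (a
#'   `germplasm_collection`) and `truth` (tibble `id`, `true_pool`).
#' @examples
#' lab <- simulate_collection(simulation_config(seed = 42))
#' dplyr::count(lab$truth, true_pool)
#' @export
simulate_collection <- function(config = simulation_config(),
                                catalog = default_catalog(),
                                archetypes = default_archetypes(catalog)) {
  stopifnot(inherits(config, "simulation_config"))
  n_pure <- config$n_andean + config$n_mesoamerican
  f <- config$introgression_fraction
  n_intro <- if (f > 0) as.integer(round(n_pure * f / (1 - f))) else 0L
  n_total <- n_pure + n_intro
  if (n_total < 1) stop("empty simulation", call. = FALSE)

  set.seed(config$seed)
  pools <- c(rep("Andean", config$n_andean),
             rep("Mesoamerican", config$n_mesoamerican),
             rep("Introgressed", n_intro))
  rows <- purrr::map(pools, function(pool) {
    switch(pool,
           Andean = sample_accession(archetypes$andean, catalog),
           Mesoamerican = sample_accession(archetypes$mesoamerican, catalog),
           Introgressed = introgress(archetypes$andean,
                                     archetypes$mesoamerican,
                                     config$introgression_lambda, catalog))
  })
  regions <- purrr::map_chr(pools, function(pool) {
    w <- config$region_weights[[pool]]
    sample(names(w), 1, prob = w)
  })
  df <- dplyr::bind_rows(rows)
  df <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("ACC%03d", seq_len(n_total)),
                   region = regions, county = NA_character_), df)
  structure(list(collection = as_collection(df, catalog),
                 truth = tibble::tibble(id = df$id, true_pool = pools),
                 config = config),
            class = "labeled_collection")
}

#' Interpolate archetypes toward their common midpoint
#'
#' Scales the separation between the two archetypes: `alpha = 1` leaves
#' them unchanged, `alpha = 0` collapses both onto the midpoint (equal
#' means and averaged level probabilities), removing all pool signal.
#' Useful for studying how pipeline recovery degrades as pools overlap.
#'
#' @param archetypes List with `andean` and `mesoamerican` archetypes.
#' @param alpha Separation multiplier in `[0, 1]`.
#' @return An archetype list of the same shape.
#' @export
shrink_separation <- function(archetypes, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  a <- archetypes$andean
  m <- archetypes$mesoamerican
  for (code in union(names(a$quantitative), names(m$quantitative))) {
    mid <- (a$quantitative[[code]]$mean + m$quantitative[[code]]$mean) / 2
    a$quantitative[[code]]$mean <- mid +
      alpha * (a$quantitative[[code]]$mean - mid)
    m$quantitative[[code]]$mean <- mid +
      alpha * (m$quantitative[[code]]$mean - mid)
  }
  for (code in union(names(a$qualitative), names(m$qualitative))) {
    mid <- (a$qualitative[[code]] + m$qualitative[[code]]) / 2
    a$qualitative[[code]] <- mid + alpha * (a$qualitative[[code]] - mid)
    m$qualitative[[code]] <- mid + alpha * (m$qualitative[[code]] - mid)
  }
  list(andean = a, mesoamerican = m)
}
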