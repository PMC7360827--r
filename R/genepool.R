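#' Seed-size market class from hundred-seed weight
#'
#' Standard common-bean market classes: small below 25 g per 100 seeds,
#' medium from 25 to 40 g, large above 40 g.
#'
#' @param hsw Hundred-seed weight(s) in grams; must be positive.
#' @return Character vector in `{"small", "medium", "large"}`.
#' @examples
#' classify_seed_size(c(20, 34.87, 40.38))
#' @export
classify_seed_size <- function(hsw) {
  if (any(is.na(hsw)) || any(hsw <= 0)) {
    stop("hundred-seed weight must be positive", call. = FALSE)
  }
  dplyr::case_when(hsw < 25 ~ "small",
                   hsw <= 40 ~ "medium",
                   TRUE ~ "large")
}

# Morphological marker rules for the two domesticated gene pools.
# Andean signals: large/medium-large seed, speckled seed coat, erect growth
# habit or determinate podding, white-to-pink flowers. Mesoamerican
# signals: small seed, speckle-free coat, prostrate + indeterminate habit,
# plain black/yellow/white seed-coat colors.
ANDEAN_RULES <- c("large_or_medium_large_seed", "speckled_coat",
                  "erect_or_determinate", "white_or_pink_flower")
MESO_RULES <- c("small_seed", "speckle_free_coat",
                "prostrate_indeterminate", "plain_black_yellow_white_coat")
MESO_PLAIN_SCC <- c(2L, 3L, 4L, 6L, 8L, 9L)  # yellow/white/black family

genepool_call_one <- function(hsw, gh, pha, ssc, scc, cs) {
  if (is.na(hsw)) {
    stop("gene-pool classification requires an HSW summary", call. = FALSE)
  }
  fired_a <- c(
    large_or_medium_large_seed = hsw >= 35,
    speckled_coat = !is.na(ssc) && ssc != 0L,
    erect_or_determinate = (!is.na(gh) && gh == 1L) ||
      (!is.na(pha) && pha == 1L),
    white_or_pink_flower = !is.na(cs) && cs %in% 1:3)
  fired_m <- c(
    small_seed = hsw < 25,
    speckle_free_coat = !is.na(ssc) && ssc == 0L,
    prostrate_indeterminate = (!is.na(gh) && gh == 2L) &&
      (!is.na(pha) && pha == 2L),
    plain_black_yellow_white_coat = !is.na(scc) && scc %in% MESO_PLAIN_SCC)
  a <- sum(fired_a)
  m <- sum(fired_m)
  call <- if (a >= m + 2) "Andean" else if (m >= a + 2) "Mesoamerican"
          else "Introgressed"
  evidence <- c(names(fired_a)[fired_a], names(fired_m)[fired_m])
  if (length(evidence) == 0) evidence <- "no_marker_rule_fired"
  list(call = call, andean_score = a, mesoamerican_score = m,
       evidence = evidence)
}

#' Rule-based gene-pool assignment of accession groups
#'
#' Scores each group profile against morphological marker rules for the
#' two domesticated common-bean gene pools and calls the origin. Andean
#' rules: seed medium-large or larger (HSW >= 35 g), speckled seed coat
#' (SSC not free), erect growth habit or determinate podding habit,
#' white-to-pink flower (CS). Mesoamerican rules: small seed (HSW < 25 g),
#' speckle-free coat, prostrate and indeterminate habit, plain
#' black/yellow/white seed-coat color (SCC). A pool is called only when its
#' score exceeds the other's by at least two rules; anything closer is
#' called Introgressed — an accession group mixing signals of both pools.
#'
#' @param profiles A `group_profiles` tibble from [summarize_groups()]
#'   (quantitative means and qualitative modal levels per group). The HSW
#'   mean is required; missing qualitative modes simply fire no rule.
#' @return A tibble with one row per group: `group`, `size`, `call`,
#'   `andean_score`, `mesoamerican_score`, `seed_size` (market class of
#'   the mean HSW), and `evidence` (list-column of fired rule names).
#' @examples
#' lab <- simulate_collection(simulation_config(seed = 1))
#' dend <- upgma(euclidean_distances(standardize(lab$collection)))
#' prof <- summarize_groups(lab$collection, cut_dendrogram(dend, 2))
#' classify_gene_pool(prof)
#' @export
classify_gene_pool <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("group", "trait") %in% names(profiles)))
  pick <- function(rows, code, col) {
    v <- rows[[col]][rows$trait == code]
    if (length(v) == 0) NA else v[1]
  }
  purrr::map_dfr(split(profiles, profiles$group), function(rows) {
    res <- genepool_call_one(
      hsw = pick(rows, "HSW", "mean"),
      gh  = pick(rows, "GH",  "modal_level"),
      pha = pick(rows, "PHA", "modal_level"),
      ssc = pick(rows, "SSC", "modal_level"),
      scc = pick(rows, "SCC", "modal_level"),
      cs  = pick(rows, "CS",  "modal_level"))
    tibble::tibble(group = rows$group[1],
                   size = if ("size" %in% names(rows)) rows$size[1]
                          else NA_integer_,
                   call = res$call,
                   andean_score = res$andean_score,
                   mesoamerican_score = res$mesoamerican_score,
                   seed_size = classify_seed_size(pick(rows, "HSW", "mean")),
                   evidence = list(res$evidence))
  })
}

#' Accession-level gene-pool calls
#'
#' Applies the same marker rules as [classify_gene_pool()] to each
#' accession's own trait values instead of group summaries, for per-region
#' composition bookkeeping.
#'
#' @param collection A `germplasm_collection` with an `HSW` column.
#' @return A tibble with one row per accession: `id`, `call`,
#'   `andean_score`, `mesoamerican_score`.
#' @export
classify_accessions <- function(collection) {
  stopifnot(inherits(collection, "germplasm_collection"))
  get <- function(code, i) {
    if (code %in% names(collection)) collection[[code]][i] else NA
  }
  purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    res <- genepool_call_one(hsw = get("HSW", i), gh = get("GH", i),
                             pha = get("PHA", i), ssc = get("SSC", i),
                             scc = get("SCC", i), cs = get("CS", i))
    tibble::tibble(id = collection$id[i], call = res$call,
                   andean_score = res$andean_score,
                   mesoamerican_score = res$mesoamerican_score)
  })
}

#' Gene-pool composition overall and by ecological region
#'
#' Tallies accession-level gene-pool calls into counts and within-total
#' percentages (one decimal, half-up) per pool and per region x pool.
#'
#' @param collection A `germplasm_collection`; every accession needs a
#'   region.
#' @param calls Accession-level calls (tibble with `id` and `call`, as
#'   from [classify_accessions()]).
#' @return An object of class `pool_composition`: list with `by_pool`
#'   (tibble `call`, `n`, `pct`) and `by_region` (tibble `region`, `call`,
#'   `n`, `pct`), percentages of the full collection size.
#' @examples
#' lab <- simulate_collection(simulation_config(seed = 1))
#' comp <- regional_composition(lab$collection,
#'                              classify_accessions(lab$collection))
#' comp$by_pool
#' @export
regional_composition <- function(collection, calls) {
  stopifnot(inherits(collection, "germplasm_collection"))
  calls <- tibble::as_tibble(calls)
  stopifnot(all(c("id", "call") %in% names(calls)))
  df <- dplyr::inner_join(
    tibble::as_tibble(collection)[, c("id", "region")], calls, by = "id")
  if (nrow(df) < nrow(collection)) {
    stop("every accession needs a gene-pool call", call. = FALSE)
  }
  if (any(is.na(df$region))) {
    stop("accession(s) lacking a region: ",
         paste(utils::head(df$id[is.na(df$region)], 3), collapse = ", "),
         call. = FALSE)
  }
  total <- nrow(df)
  by_pool <- df |>
    dplyr::count(.data$call) |>
    dplyr::mutate(pct = round_half_up(.data$n / total * 100, 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  by_region <- df |>
    dplyr::count(.data$region, .data$call) |>
    dplyr::mutate(pct = round_half_up(.data$n / total * 100, 1)) |>
    dplyr::arrange(.data$region, dplyr::desc(.data$n))
  structure(list(by_pool = by_pool, by_region = by_region,
                 n_accessions = total),
            class = "pool_composition")
}

#' @export
print.pool_composition <- function(x, ...) {
  cat("Gene-pool composition of", x$n_accessions, "accessions\n\n")
  print(x$by_pool)
  invisible(x)
}

#' @rdname regional_composition
#' @param x A `pool_composition`.
#' @param ... Unused.
#' @method tidy pool_composition
#' @export
tidy.pool_composition <- function(x, ...) {
  x$by_region
}

#' @rdname regional_composition
#' @param object A `pool_composition`.
#' @method autoplot pool_composition
#' @export
autoplot.pool_composition <- function(object, ...) {
  ggplot2::ggplot(object$by_region,
                  ggplot2::aes(x = .data$region, y = .data$n,
                               fill = .data$call)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "natural ecological region", y = "accessions",
                  fill = "gene pool") +
    ggplot2::theme_minimal()
}
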