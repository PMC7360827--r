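#' Level frequencies of a qualitative trait
#'
#' Tallies observed integer level codes and their proportions of the total.
#' Only observed levels appear; proportions sum to one.
#'
#' @param values Vector of integer level codes (missing values dropped).
#' @return A tibble with columns `level`, `n`, `p`, sorted by level.
#' @examples
#' frequency_table(c(rep(1L, 75), rep(2L, 40)))
#' @export
frequency_table <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop("frequency_table() needs at least one non-missing value",
         call. = FALSE)
  }
  tab <- table(values)
  tibble::tibble(level = as.integer(names(tab)),
                 n = as.integer(tab),
                 p = as.integer(tab) / length(values))
}

#' Shannon-Weaver diversity index
#'
#' Computes \eqn{H' = -\sum_i p_i \ln p_i} over the non-empty classes of a
#' count (or proportion) vector, with the natural logarithm. `H'` is zero
#' when a single class holds everything and reaches \eqn{\ln k} for `k`
#' equally frequent classes.
#'
#' @param counts Non-negative numeric vector of class counts; proportions
#'   work identically since the vector is normalized internally.
#' @return The index, a single non-negative number (nats).
#' @examples
#' shannon_index(c(green = 75, purple = 40))
#' shannon_index(rep(10, 4))  # ln(4)
#' @export
shannon_index <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0 || any(counts < 0)) {
    stop("counts must be non-negative and non-empty", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("at least one class count must be positive", call. = FALSE)
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' the standard dimensionless dispersion measure for trait descriptors.
#'
#' @param values Numeric vector of at least two non-missing values with
#'   non-zero mean.
#' @return `sd(values) / mean(values)`.
#' @examples
#' coefficient_of_variation(c(2, 4, 6))  # 0.5
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("coefficient_of_variation() needs >= 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) {
    stop("coefficient of variation is undefined for zero mean",
         call. = FALSE)
  }
  stats::sd(values) / m
}

#' Assign quantitative observations to ten half-s.d. classes
#'
#' Partitions a quantitative trait into 10 classes centered on the trait
#' mean `X` with class width `0.5 s` (sample standard deviation): class 1
#' collects the lower tail `x < X - 2s`, class 10 the upper tail
#' `x > X + 2s`, and the interior boundaries are
#' `b_k = X - 2s + (k - 1) * 0.5 s`, `k = 1..9`. Interior class `j` covers
#' the half-open interval `[b_{j-1}, b_j)`; a value exactly equal to
#' `X + 2s` falls in class 9 (class 10 is strictly above). When `s = 0`
#' every observation sits in class 6, the class whose lower bound is `X`.
#'
#' @param values Numeric vector (>= 2 non-missing values).
#' @return An object of class `class_binning`: a list with `mean`, `sd`,
#'   `n_classes` (10), `boundaries` (length 9), `assignments` (class index
#'   1–10 per input value, `NA` preserved) and `counts` (named length-10
#'   integer vector).
#' @examples
#' b <- assign_classes(c(10, 11, 12, 13, 30))
#' b$counts
#' @export
assign_classes <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) {
    stop("assign_classes() needs >= 2 non-missing values", call. = FALSE)
  }
  m <- mean(obs)
  s <- stats::sd(obs)
  boundaries <- m - 2 * s + (seq_len(9) - 1) * 0.5 * s
  cls <- rep(NA_integer_, length(values))
  keep <- !is.na(values)
  if (s == 0) {
    cls[keep] <- 6L
  } else {
    idx <- findInterval(values[keep], boundaries) + 1L
    at_or_below_top <- values[keep] <= boundaries[9]
    idx[idx == 10L & at_or_below_top] <- 9L
    cls[keep] <- idx
  }
  counts <- tabulate(cls[keep], nbins = 10L)
  names(counts) <- as.character(1:10)
  structure(list(mean = m, sd = s, n_classes = 10L,
                 boundaries = boundaries, assignments = cls,
                 counts = counts),
            class = "class_binning")
}

#' Diversity index of one quantitative trait
#'
#' Bins the values into the ten half-s.d. classes of [assign_classes()],
#' computes the Shannon-Weaver index over the class counts, and the
#' coefficient of variation of the raw values.
#'
#' @inheritParams assign_classes
#' @return A list with `h` (Shannon-Weaver index over class counts), `cv`,
#'   `counts` (the length-10 class tally), and `binning` (the full
#'   `class_binning`).
#' @export
quantitative_trait_diversity <- function(values) {
  binning <- assign_classes(values)
  list(h = shannon_index(binning$counts),
       cv = coefficient_of_variation(values),
       counts = binning$counts,
       binning = binning)
}

#' Aggregate member-trait diversity indices to the organ level
#'
#' The organ-level index is the arithmetic mean of the member traits'
#' Shannon-Weaver indices; the collection-wide index is the same mean taken
#' over all traits.
#'
#' @param trait_h Numeric vector of per-trait `H'` values (non-empty).
#' @return The arithmetic mean.
#' @examples
#' organ_diversity(c(1.836, 1.814, 1.283, 1.055, 1.012))  # seed qualitative
#' @export
organ_diversity <- function(trait_h) {
  trait_h <- trait_h[!is.na(trait_h)]
  if (length(trait_h) == 0) {
    stop("organ_diversity() needs at least one trait index", call. = FALSE)
  }
  mean(trait_h)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (0.0005 -> 0.001),
#' matching how trait tables are conventionally printed; `base::round()`
#' rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Full diversity report for a collection
#'
#' Computes, for every trait column of the collection, the Shannon-Weaver
#' diversity index (qualitative traits over raw level frequencies;
#' quantitative traits over the ten half-s.d. classes) and, for
#' quantitative traits, the coefficient of variation; aggregates trait
#' indices into organ-by-kind means, an overall collection mean, and
#' per-region overall means on each region's accession subset.
#'
#' Missing values are dropped per trait (the number dropped is recorded in
#' the per-trait table). A trait with fewer than two non-missing
#' observations is an error naming the trait; in per-region subsets such
#' traits are skipped instead, so a small region still gets a mean over the
#' traits it can support.
#'
#' @param collection A `germplasm_collection`.
#' @return An object of class `diversity_report`: a list with
#'   `per_trait` (tibble: `trait`, `name`, `organ`, `kind`, `n`,
#'   `n_dropped`, `n_classes`, `h`, `cv`), `per_organ` (tibble: `organ`,
#'   `kind`, `n_traits`, `h`), `overall_mean`, and `per_region` (tibble:
#'   `region`, `n_accessions`, `h`).
#' @examples
#' lab <- simulate_collection(simulation_config(seed = 1))
#' rep <- diversity_report(lab$collection)
#' glance(rep)
#' @export
diversity_report <- function(collection) {
  stopifnot(inherits(collection, "germplasm_collection"))
  catalog <- collection_catalog(collection)
  traits <- trait_columns(collection)
  if (length(traits) == 0) {
    stop("collection has no trait columns", call. = FALSE)
  }

  per_trait <- purrr::map_dfr(traits, function(code) {
    d <- catalog_descriptor(catalog, code)
    x <- collection[[code]]
    n_dropped <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) < 2) {
      stop("trait ", code, " has fewer than 2 observations", call. = FALSE)
    }
    if (d$kind == "qualitative") {
      ft <- frequency_table(x)
      h <- shannon_index(ft$n)
      n_classes <- nrow(ft)
      cv <- NA_real_
    } else {
      qtd <- quantitative_trait_diversity(x)
      h <- qtd$h
      n_classes <- sum(qtd$counts > 0)
      cv <- qtd$cv
    }
    tibble::tibble(trait = code, name = d$name, organ = d$organ,
                   kind = d$kind, n = length(x), n_dropped = n_dropped,
                   n_classes = n_classes, h = h, cv = cv)
  })

  per_organ <- per_trait |>
    dplyr::group_by(.data$organ, .data$kind) |>
    dplyr::summarise(n_traits = dplyr::n(),
                     h = organ_diversity(.data$h), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$h))

  with_region <- tibble::as_tibble(collection) |>
    dplyr::filter(!is.na(.data$region))
  per_region <- purrr::map_dfr(
    split(with_region, with_region$region), function(rows) {
      hs <- purrr::map_dbl(traits, function(code) {
        x <- rows[[code]]
        x <- x[!is.na(x)]
        if (length(x) < 2) return(NA_real_)
        kind <- catalog$kind[match(code, catalog$code)]
        if (kind == "qualitative") {
          shannon_index(frequency_table(x)$n)
        } else {
          quantitative_trait_diversity(x)$h
        }
      })
      hs <- hs[!is.na(hs)]
      tibble::tibble(region = rows$region[1], n_accessions = nrow(rows),
                     h = if (length(hs) > 0) organ_diversity(hs)
                         else NA_real_)
    })
  if (nrow(per_region) == 0) {
    per_region <- tibble::tibble(region = character(),
                                 n_accessions = integer(), h = double())
  }

  structure(list(per_trait = per_trait,
                 per_organ = per_organ,
                 overall_mean = organ_diversity(per_trait$h),
                 per_region = per_region),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Diversity report:", nrow(x$per_trait), "traits, overall mean H' =",
      format(round_half_up(x$overall_mean, 3)), "\n\n")
  print(x$per_organ)
  invisible(x)
}

#' @rdname diversity_report
#' @param x A `diversity_report`.
#' @param ... Unused.
#' @method tidy diversity_report
#' @export
tidy.diversity_report <- function(x, ...) {
  x$per_trait
}

#' @rdname diversity_report
#' @method glance diversity_report
#' @export
glance.diversity_report <- function(x, ...) {
  tibble::tibble(
    n_traits = nrow(x$per_trait),
    n_qualitative = sum(x$per_trait$kind == "qualitative"),
    n_quantitative = sum(x$per_trait$kind == "quantitative"),
    overall_mean_h = x$overall_mean,
    max_h = max(x$per_trait$h),
    min_h = min(x$per_trait$h))
}

#' @rdname diversity_report
#' @param object A `diversity_report`.
#' @method autoplot diversity_report
#' @export
autoplot.diversity_report <- function(object, ...) {
  df <- object$per_trait |>
    dplyr::mutate(trait = stats::reorder(.data$trait, .data$h))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$h,
                                   fill = .data$organ)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$kind), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = "Shannon-Weaver index H' (nats)",
                  fill = "organ") +
    ggplot2::theme_minimal()
}

#' Export a diversity report
#'
#' `diversity_csv()` writes the per-trait table (one row per trait);
#' `diversity_json()` writes the full nested report.
#'
#' @param report A `diversity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
diversity_csv <- function(report, path) {
  readr::write_csv(report$per_trait, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname diversity_csv
#' @export
diversity_json <- function(report, path) {
  js <- jsonlite::toJSON(list(per_trait = report$per_trait,
                              per_organ = report$per_organ,
                              overall_mean = report$overall_mean,
                              per_region = report$per_region),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}
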