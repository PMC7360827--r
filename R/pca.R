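#' Correlation-matrix principal component analysis of a trait matrix
#'
#' Eigendecomposition of the trait correlation matrix (sample, n - 1
#' normalization). Eigenvalues sum to the number of traits `p`; each
#' component's contribution rate is `eigenvalue / p * 100` and the
#' cumulative rate is its running sum. Scores are the z-scored data
#' projected on the eigenvectors, so the sample variance of the j-th score
#' column equals the j-th eigenvalue. Eigenvector signs are arbitrary; for
#' determinism each loading column is flipped so its largest-magnitude
#' entry is positive.
#'
#' @param x A `standardized_traits` tibble from [standardize()] (or a
#'   numeric matrix of accessions x traits, standardized or not — the
#'   correlation matrix is scale-free).
#' @return An object of class `trait_pca`: a list with `eigenvalues`
#'   (descending), `loadings` (traits x components, unit-norm columns),
#'   `contribution` and `cumulative` (percent), `scores` (accessions x
#'   components), `trait_codes`, and `accession_ids`.
#' @examples
#' lab <- simulate_collection(simulation_config(seed = 1))
#' pca <- correlation_pca(standardize(lab$collection))
#' head(tidy(pca))
#' @export
correlation_pca <- function(x) {
  m <- st_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("correlation_pca() needs >= 2 accessions and >= 2 traits",
         call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  constant <- colnames(m)[sds == 0]
  if (length(constant) > 0) {
    stop("correlation undefined for constant trait(s): ",
         paste(constant, collapse = ", "), call. = FALSE)
  }
  p <- ncol(m)
  R <- stats::cor(m)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  V <- eig$vectors
  # sign convention: largest-|entry| positive per column
  for (j in seq_len(p)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(m), paste0("PC", seq_len(p)))
  Z <- scale(m)  # z-scores with n-1 sd, matching the correlation estimator
  scores <- Z %*% V
  rates <- contribution_rates(lambda, p)
  structure(list(eigenvalues = lambda,
                 loadings = V,
                 contribution = rates$contribution,
                 cumulative = rates$cumulative,
                 scores = scores,
                 trait_codes = colnames(m),
                 accession_ids = rownames(m)),
            class = "trait_pca")
}

#' Contribution and cumulative contribution rates
#'
#' For a correlation-matrix PCA on `p` traits the total variance is `p`,
#' so component j explains `lambda_j / p * 100` percent.
#'
#' @param eigenvalues Non-negative eigenvalues (need not be all `p` of
#'   them).
#' @param p Number of traits (total variance).
#' @return A list with numeric vectors `contribution` and `cumulative`
#'   (percent).
#' @examples
#' contribution_rates(c(4.3895, 2.6272, 2.5903, 2.0796), p = 29)
#' @export
contribution_rates <- function(eigenvalues, p) {
  if (p <= 0) stop("p must be positive", call. = FALSE)
  if (length(eigenvalues) > p) {
    stop("more eigenvalues than traits", call. = FALSE)
  }
  if (any(eigenvalues < 0)) {
    stop("eigenvalues must be non-negative", call. = FALSE)
  }
  contribution <- eigenvalues / p * 100
  list(contribution = contribution, cumulative = cumsum(contribution))
}

#' Per-accession score pairs for a 2-D ordination plot
#'
#' @param result A `trait_pca`.
#' @param components Integer pair of component indices (default PC1/PC2).
#' @param groups Optional tibble with columns `id` and `group` to carry a
#'   group label per accession.
#' @return A tibble with columns `id`, `x`, `y` (scores on the requested
#'   components) and optionally `group`.
#' @export
score_scatter <- function(result, components = c(1, 2), groups = NULL) {
  stopifnot(inherits(result, "trait_pca"))
  k <- ncol(result$scores)
  if (length(components) != 2 || any(components < 1) ||
      any(components > k)) {
    stop("components must be two indices between 1 and ", k, call. = FALSE)
  }
  out <- tibble::tibble(id = result$accession_ids,
                        x = unname(result$scores[, components[1]]),
                        y = unname(result$scores[, components[2]]))
  if (!is.null(groups)) {
    out <- dplyr::left_join(out, tibble::as_tibble(groups), by = "id")
  }
  out
}

#' @export
print.trait_pca <- function(x, ...) {
  k <- min(4L, length(x$eigenvalues))
  cat("Correlation PCA:", length(x$trait_codes), "traits,",
      length(x$accession_ids), "accessions\n")
  tb <- rbind(eigenvalue = x$eigenvalues[1:k],
              `contribution (%)` = x$contribution[1:k],
              `cumulative (%)` = x$cumulative[1:k])
  colnames(tb) <- paste0("PC", 1:k)
  print(round(tb, 4))
  invisible(x)
}

#' @rdname correlation_pca
#' @param x A `trait_pca`.
#' @param ... Unused.
#' @method tidy trait_pca
#' @export
tidy.trait_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 contribution = x$contribution,
                 cumulative = x$cumulative)
}

#' @rdname correlation_pca
#' @method glance trait_pca
#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(n_traits = length(x$trait_codes),
                 n_accessions = length(x$accession_ids),
                 pc1_contribution = x$contribution[1],
                 cumulative_4 = x$cumulative[min(4, length(x$cumulative))])
}

#' @rdname correlation_pca
#' @param object A `trait_pca`.
#' @param components,groups Passed to [score_scatter()].
#' @method autoplot trait_pca
#' @export
autoplot.trait_pca <- function(object, components = c(1, 2), groups = NULL,
                               ...) {
  df <- score_scatter(object, components, groups)
  lab <- function(j) sprintf("PC%d (%.1f%%)", j, object$contribution[j])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if ("group" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group,
                                              shape = .data$group))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = lab(components[1]), y = lab(components[2])) +
    ggplot2::theme_minimal()
}

#' Export PCA results as CSV
#'
#' `pca_report_csv()` writes the eigen-report (one column per component:
#' eigenvalue, contribution, cumulative rows followed by the per-trait
#' loadings); `pca_scores_csv()` writes accession scores.
#'
#' @param result A `trait_pca`.
#' @param path Output path.
#' @param components Number of leading components to export.
#' @return `path`, invisibly.
#' @export
pca_report_csv <- function(result, path, components = 4) {
  k <- min(components, length(result$eigenvalues))
  rows <- rbind(result$eigenvalues[1:k], result$contribution[1:k],
                result$cumulative[1:k], result$loadings[, 1:k, drop = FALSE])
  tb <- tibble::as_tibble(rows, .name_repair = ~paste0("PC", 1:k))
  tb <- dplyr::bind_cols(
    tibble::tibble(row = c("eigenvalue", "contribution_pct",
                           "cumulative_pct", result$trait_codes)), tb)
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}

#' @rdname pca_report_csv
#' @export
pca_scores_csv <- function(result, path, components = 4) {
  k <- min(components, ncol(result$scores))
  tb <- tibble::as_tibble(result$scores[, 1:k, drop = FALSE],
                          .name_repair = ~paste0("PC", 1:k))
  tb <- dplyr::bind_cols(tibble::tibble(id = result$accession_ids), tb)
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}
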