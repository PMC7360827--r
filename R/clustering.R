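#' Standardize the trait matrix of a collection
#'
#' Converts the selected trait columns (all traits by default, with
#' qualitative level codes treated as numeric — the convention under which
#' coded morphological matrices are clustered) to column-wise z-scores:
#' each column gets mean 0 and sample standard deviation 1. Constant
#' columns cannot be scaled and become all zeros, with a warning. Rows with
#' any missing value among the included traits are dropped, with a message
#' listing how many.
#'
#' @param collection A `germplasm_collection`.
#' @param traits Character vector of trait codes to include (default: every
#'   trait column present).
#' @return A `standardized_traits` tibble: `id` column plus one z-scored
#'   numeric column per trait; attributes `dropped_ids` (rows removed for
#'   missingness) and `constant_traits`.
#' @export
standardize <- function(collection, traits = NULL) {
  stopifnot(inherits(collection, "germplasm_collection"))
  if (is.null(traits)) traits <- trait_columns(collection)
  missing_traits <- setdiff(traits, names(collection))
  if (length(missing_traits) > 0) {
    stop("trait(s) not in collection: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(collection)[, c("id", traits)]
  complete <- stats::complete.cases(df[traits])
  dropped <- df$id[!complete]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " accession(s) with missing trait values")
    df <- df[complete, ]
  }
  if (nrow(df) < 2) {
    stop("standardize() needs >= 2 complete accessions", call. = FALSE)
  }
  constant <- character()
  for (code in traits) {
    x <- as.double(df[[code]])
    s <- stats::sd(x)
    if (s == 0) {
      constant <- c(constant, code)
      df[[code]] <- rep(0, length(x))
    } else {
      df[[code]] <- (x - mean(x)) / s
    }
  }
  if (length(constant) > 0) {
    warning("constant trait column(s) set to zero: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  structure(df, dropped_ids = dropped, constant_traits = constant,
            class = c("standardized_traits", class(tibble::tibble())))
}

#' @keywords internal
st_matrix <- function(x) {
  if (inherits(x, "standardized_traits")) {
    m <- as.matrix(tibble::as_tibble(x)[, -1, drop = FALSE])
    rownames(m) <- x$id
    return(m)
  }
  as.matrix(x)
}

#' Euclidean distances between accessions
#'
#' @param x A `standardized_traits` tibble (or any numeric matrix with one
#'   row per accession).
#' @return A [stats::dist] object with accession ids as labels.
#' @export
euclidean_distances <- function(x) {
  m <- st_matrix(x)
  if (nrow(m) < 2) {
    stop("need >= 2 accessions for a distance matrix", call. = FALSE)
  }
  stats::dist(m, method = "euclidean")
}

#' UPGMA dendrogram of a distance matrix
#'
#' Agglomerative clustering with unweighted pair-group average linkage: at
#' each step the two clusters with the smallest mean inter-point distance
#' merge, the merge height is that mean distance (not halved), and distances
#' to the merged cluster are the size-weighted averages of the members'
#' distances. Heights are therefore non-decreasing across merges.
#'
#' @param dist A [stats::dist] object or a symmetric square matrix with
#'   zero diagonal.
#' @param leaf_ids Optional leaf labels (defaults to the labels carried by
#'   `dist`, else `1..n`).
#' @return An object of class `c("upgma", "hclust")`; the usual `hclust`
#'   fields (`merge`, `height`, `order`, `labels`) apply.
#' @examples
#' d <- euclidean_distances(matrix(c(0, 0, 3, 4, 10, 0), ncol = 2,
#'                                 byrow = TRUE))
#' upgma(d)$height
#' @export
upgma <- function(dist, leaf_ids = NULL) {
  if (!inherits(dist, "dist")) {
    m <- as.matrix(dist)
    if (nrow(m) != ncol(m)) {
      stop("distance matrix must be square", call. = FALSE)
    }
    if (max(abs(m - t(m))) > 1e-8) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    dist <- stats::as.dist(m)
  }
  hc <- stats::hclust(dist, method = "average")
  if (!is.null(leaf_ids)) {
    stopifnot(length(leaf_ids) == attr(dist, "Size"))
    hc$labels <- as.character(leaf_ids)
  } else if (is.null(hc$labels)) {
    hc$labels <- as.character(seq_len(attr(dist, "Size")))
  }
  class(hc) <- c("upgma", "hclust")
  hc
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` highest merges and labels the resulting groups
#' `G1`, `G2`, ... in decreasing order of size (ties broken by first
#' appearance in leaf order).
#'
#' @param dendrogram An `upgma`/`hclust` object.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return A tibble with columns `id` and `group`.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  if (k < 1 || k > n) {
    stop("k must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  raw <- stats::cutree(dendrogram, k = k)
  sizes <- table(raw)
  first_seen <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(sizes), as.integer(first_seen))
  relabel <- stats::setNames(paste0("G", seq_len(k)), names(sizes)[ord])
  tibble::tibble(id = names(raw), group = unname(relabel[as.character(raw)]))
}

#' Export a dendrogram as a Newick string
#'
#' Converts the merge tree to a phylo object (merge heights become node
#' depths, so leaf-to-root path lengths are half the merge heights, the
#' standard ultrametric convention) and writes Newick.
#'
#' @param dendrogram An `upgma`/`hclust` object.
#' @param path Optional file path; when `NULL`, the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
as_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("as_newick() requires the 'ape' package", call. = FALSE)
  }
  phy <- ape::as.phylo(dendrogram)
  if (is.null(path)) {
    return(ape::write.tree(phy))
  }
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Export the merge table of a dendrogram as CSV
#'
#' @param dendrogram An `upgma`/`hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
merge_table_csv <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "hclust"))
  tb <- tibble::tibble(step = seq_along(dendrogram$height),
                       a = dendrogram$merge[, 1],
                       b = dendrogram$merge[, 2],
                       height = dendrogram$height)
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}

#' Summarize trait profiles of accession groups
#'
#' For each group: size, per-quantitative-trait mean and standard
#' deviation, and per-qualitative-trait modal level with its within-group
#' frequency (ties broken toward the smallest level code).
#'
#' @param collection A `germplasm_collection`.
#' @param labels A tibble with columns `id` and `group` (as returned by
#'   [cut_dendrogram()]), covering only ids present in the collection.
#' @return A `group_profiles` tibble, one row per group x trait, with
#'   columns `group`, `size`, `trait`, `kind`, `mean`, `sd` (quantitative)
#'   and `modal_level`, `modal_freq` (qualitative).
#' @export
summarize_groups <- function(collection, labels) {
  stopifnot(inherits(collection, "germplasm_collection"))
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("id", "group") %in% names(labels)))
  unknown <- setdiff(labels$id, collection$id)
  if (length(unknown) > 0) {
    stop("label(s) for unknown accession(s): ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  catalog <- collection_catalog(collection)
  joined <- dplyr::inner_join(labels, tibble::as_tibble(collection),
                              by = "id")
  traits <- trait_columns(collection)
  out <- purrr::map_dfr(split(joined, joined$group), function(rows) {
    purrr::map_dfr(traits, function(code) {
      kind <- catalog$kind[match(code, catalog$code)]
      x <- rows[[code]]
      x <- x[!is.na(x)]
      base <- tibble::tibble(group = rows$group[1], size = nrow(rows),
                             trait = code, kind = kind,
                             mean = NA_real_, sd = NA_real_,
                             modal_level = NA_integer_,
                             modal_freq = NA_real_)
      if (length(x) == 0) return(base)
      if (kind == "quantitative") {
        base$mean <- mean(x)
        base$sd <- if (length(x) > 1) stats::sd(x) else 0
      } else {
        tab <- table(x)
        top <- which.max(tab)  # ties: first = smallest level code
        base$modal_level <- as.integer(names(tab)[top])
        base$modal_freq <- as.integer(tab[top]) / length(x)
      }
      base
    })
  })
  class(out) <- c("group_profiles", class(tibble::tibble()))
  out
}

#' @rdname upgma
#' @param object An `upgma` dendrogram.
#' @param ... Unused.
#' @method autoplot upgma
#' @export
autoplot.upgma <- function(object, ...) {
  hc <- object
  n <- length(hc$order)
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  node_x <- numeric(length(hc$height))
  segs <- vector("list", length(hc$height))
  pos <- function(j) {
    if (j < 0) c(x = unname(leaf_x[as.character(-j)]), y = 0)
    else c(x = node_x[j], y = hc$height[j])
  }
  for (m in seq_along(hc$height)) {
    a <- pos(hc$merge[m, 1]); b <- pos(hc$merge[m, 2])
    node_x[m] <- (a["x"] + b["x"]) / 2
    h <- hc$height[m]
    segs[[m]] <- tibble::tibble(
      x = c(a["x"], b["x"], a["x"]), xend = c(a["x"], b["x"], b["x"]),
      y = c(a["y"], b["y"], h), yend = c(h, h, h))
  }
  seg_df <- dplyr::bind_rows(segs)
  lab_df <- tibble::tibble(x = seq_len(n),
                           label = hc$labels[hc$order])
  ggplot2::ggplot(seg_df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = lab_df$x, labels = lab_df$label) +
    ggplot2::labs(x = NULL, y = "merge height (Euclidean distance)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}
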