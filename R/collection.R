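#' Germplasm collections as tibbles
#'
#' A germplasm collection is a tibble with one row per accession: metadata
#' columns `id` (unique), `region` (natural ecological region `"I"`–`"IV"`,
#' or `NA` when unknown) and `county`, followed by one column per trait code
#' present. Qualitative traits hold the integer level codes declared in the
#' catalog; quantitative traits hold values in catalog units. Empty cells are
#' missing values (`NA`), never zero. The catalog travels with the tibble as
#' an attribute so downstream stages always validate against the same
#' descriptor set.
#'
#' @name germplasm_collection
NULL

METADATA_COLS <- c("id", "region", "county")
REGIONS <- c("I", "II", "III", "IV")

#' Build a collection from an in-memory data frame
#'
#' @param data A data frame with an `id` column, optional `region`/`county`,
#'   and trait columns named by catalog codes.
#' @param catalog A [trait_catalog][default_catalog]; defaults to the
#'   standard 29-trait catalog.
#' @return A `germplasm_collection` tibble.
#' @details Structural problems (unknown trait columns, duplicate accession
#'   ids, qualitative codes outside the declared level set) are errors.
#'   Value-level problems that do not break the data model (non-positive
#'   HSW, unknown region, ...) are left to [validate_collection()], which
#'   reports them as data.
#' @examples
#' df <- tibble::tibble(id = c("a1", "a2"), HSW = c(42, 21), GH = c(1L, 2L))
#' col <- as_collection(df)
#' trait_columns(col)
#' @export
as_collection <- function(data, catalog = default_catalog()) {
  data <- tibble::as_tibble(data)
  if (!"id" %in% names(data)) {
    stop("collection data must have an 'id' column", call. = FALSE)
  }
  data$id <- as.character(data$id)
  if (!"region" %in% names(data)) data$region <- NA_character_
  if (!"county" %in% names(data)) data$county <- NA_character_
  data$region <- as.character(data$region)
  data$county <- as.character(data$county)

  unknown <- setdiff(names(data), c(METADATA_COLS, catalog$code))
  if (length(unknown) > 0) {
    stop("unknown trait column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- data$id[duplicated(data$id)]
  if (length(dup) > 0) {
    stop("duplicated accession id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  traits <- intersect(catalog$code, names(data))
  for (code in traits) {
    kind <- catalog$kind[match(code, catalog$code)]
    if (kind == "qualitative") {
      v <- data[[code]]
      if (!is.numeric(v)) {
        stop("qualitative trait ", code, " must hold integer level codes",
             call. = FALSE)
      }
      iv <- suppressWarnings(as.integer(v))
      if (any(!is.na(v) & (is.na(iv) | iv != v))) {
        stop("qualitative trait ", code, " has non-integer values",
             call. = FALSE)
      }
      ok_levels <- catalog_levels(catalog, code)
      bad <- which(!is.na(iv) & !(iv %in% ok_levels))
      if (length(bad) > 0) {
        stop(sprintf(
          "accession %s: value %s is not a declared level of trait %s",
          data$id[bad[1]], iv[bad[1]], code), call. = FALSE)
      }
      data[[code]] <- iv
    } else {
      data[[code]] <- as.double(data[[code]])
    }
  }
  data <- data[, c(METADATA_COLS, traits)]
  attr(data, "catalog") <- catalog
  class(data) <- c("germplasm_collection", class(tibble::tibble()))
  data
}

#' Read a germplasm collection from a CSV trait matrix
#'
#' The file dialect is plain UTF-8 CSV with a header row naming `id`,
#' optionally `region` and `county`, and a subset of catalog trait codes;
#' one row per accession; an empty cell is a missing value.
#'
#' @param path Path to the CSV file.
#' @inheritParams as_collection
#' @return A `germplasm_collection` tibble.
#' @seealso [write_collection()] for the inverse; the pair round-trips
#'   exactly.
#' @export
load_collection <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE)
  for (code in intersect(names(raw), catalog$code)) {
    suppressWarnings(num <- as.numeric(raw[[code]]))
    bad <- !is.na(raw[[code]]) & is.na(num)
    if (any(bad)) {
      stop("non-numeric value '", raw[[code]][which(bad)[1]],
           "' in trait column ", code, call. = FALSE)
    }
    raw[[code]] <- num
  }
  as_collection(raw, catalog)
}

#' Write a germplasm collection to CSV
#'
#' Writes the collection's metadata and trait columns as plain CSV with
#' missing values as empty cells, such that
#' `load_collection(write_collection(x, p))` reproduces `x` exactly.
#'
#' @param collection A `germplasm_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_collection <- function(collection, path) {
  stopifnot(inherits(collection, "germplasm_collection"))
  readr::write_csv(tibble::as_tibble(unclass_collection(collection)),
                   path, na = "", progress = FALSE)
  invisible(path)
}

unclass_collection <- function(collection) {
  out <- collection
  attr(out, "catalog") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @keywords internal
collection_catalog <- function(collection) {
  cat <- attr(collection, "catalog")
  if (is.null(cat)) cat <- default_catalog()
  cat
}

#' Trait columns present in a collection
#' @param collection A `germplasm_collection`.
#' @param kind `"any"`, `"qualitative"` or `"quantitative"`.
#' @return Character vector of trait codes, in catalog order.
#' @export
trait_columns <- function(collection, kind = c("any", "qualitative",
                                               "quantitative")) {
  kind <- match.arg(kind)
  intersect(trait_codes(collection_catalog(collection), kind),
            names(collection))
}

#' Validate a collection against its catalog's value rules
#'
#' Violations are data, not exceptions: each row of the report names the
#' accession, the trait (or `"region"`), the rule, and a message. An empty
#' report means every accession invariant holds: qualitative values are
#' declared levels, quantitative values are finite, `HSW` and `PH` are
#' strictly positive where present, count traits (`NS`, `NB`, `NP`, `NSP`)
#' are non-negative, and the region is one of I–IV or missing.
#'
#' @param collection A `germplasm_collection`.
#' @return A tibble with columns `accession`, `trait`, `rule`, `message`
#'   (zero rows when clean).
#' @examples
#' col <- as_collection(tibble::tibble(id = "a1", HSW = -1, region = "V"))
#' validate_collection(col)
#' @export
validate_collection <- function(collection) {
  stopifnot(inherits(collection, "germplasm_collection"))
  catalog <- collection_catalog(collection)
  v <- list()
  add <- function(accession, trait, rule, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      accession = accession, trait = trait, rule = rule, message = message)
  }

  bad_region <- !is.na(collection$region) &
    !(collection$region %in% REGIONS)
  for (i in which(bad_region)) {
    add(collection$id[i], "region", "region_in_I_IV",
        sprintf("region '%s' is not one of I, II, III, IV",
                collection$region[i]))
  }

  for (code in trait_columns(collection)) {
    kind <- catalog$kind[match(code, catalog$code)]
    x <- collection[[code]]
    if (kind == "quantitative") {
      for (i in which(!is.na(x) & !is.finite(x))) {
        add(collection$id[i], code, "finite",
            sprintf("%s is not finite", code))
      }
      if (code %in% c("HSW", "PH")) {
        for (i in which(is.finite(x) & x <= 0)) {
          add(collection$id[i], code, "positive",
              sprintf("%s = %g must be > 0", code, x[i]))
        }
      }
      if (code %in% c("NS", "NB", "NP", "NSP")) {
        for (i in which(is.finite(x) & x < 0)) {
          add(collection$id[i], code, "non_negative",
              sprintf("%s = %g must be >= 0", code, x[i]))
        }
      }
    } else {
      ok <- catalog_levels(catalog, code)
      for (i in which(!is.na(x) & !(x %in% ok))) {
        add(collection$id[i], code, "declared_level",
            sprintf("%s = %s is not a declared level", code, x[i]))
      }
    }
  }

  if (length(v) == 0) {
    return(tibble::tibble(accession = character(), trait = character(),
                          rule = character(), message = character()))
  }
  dplyr::bind_rows(v)
}

#' Serialize a validation report to JSON
#' @param report A validation report from [validate_collection()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
validation_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(list(n_violations = nrow(report),
                              violations = report),
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
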