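#' The 29-trait descriptor catalog for common bean characterization
#'
#' Builds the standard catalog of 29 morpho-agronomic trait descriptors used
#' to characterize common bean (*Phaseolus vulgaris* L.) germplasm: 13
#' quantitative traits (with measurement units) and 16 qualitative traits
#' (with integer level codes and labels), organized by plant organ
#' (phenology, plant, leaf, flower, pod, seed).
#'
#' Qualitative traits are scored as small integer codes (e.g. growth habit
#' `GH`: 1 = erect, 2 = prostrate; speckle of seed coat `SSC`: 0 = free,
#' 1 = punctiform, 2 = stripe, 3 = reticulate). Quantitative traits carry a
#' unit (e.g. hundred-seed weight `HSW` in g). The catalog is the single
#' source of truth downstream: collections are validated against it, and the
#' diversity report uses its organ/kind grouping.
#'
#' @return A tibble of class `trait_catalog` with one row per descriptor and
#'   columns `code`, `name`, `organ`, `kind`, `unit` (quantitative only,
#'   otherwise `NA`), and `levels` (list-column of tibbles with `level` and
#'   `label`; `NULL` for quantitative traits).
#' @examples
#' cat29 <- default_catalog()
#' dplyr::count(cat29, organ, kind)
#' @export
default_catalog <- function() {
  qt <- function(code, name, organ, unit) {
    tibble::tibble(code = code, name = name, organ = organ,
                   kind = "quantitative", unit = unit,
                   levels = list(NULL))
  }
  ql <- function(code, name, organ, levels, labels) {
    tibble::tibble(code = code, name = name, organ = organ,
                   kind = "qualitative", unit = NA_character_,
                   levels = list(tibble::tibble(level = as.integer(levels),
                                                label = labels)))
  }
  flower_colors <- c("white", "pinkish-white", "pinkish-red", "purple",
                     "light purple")
  out <- dplyr::bind_rows(
    qt("DF",  "days to flowering",             "phenology", "d"),
    qt("DM",  "days to physiological maturity", "phenology", "d"),
    qt("PH",  "plant height",                  "plant", "cm"),
    qt("NS",  "node number of the main stem",  "plant", "count"),
    qt("NB",  "number of primary branches",    "plant", "count"),
    qt("NP",  "number of pods per plant",      "pod",   "count"),
    qt("PL",  "pod length",                    "pod",   "cm"),
    qt("PW",  "pod width",                     "pod",   "cm"),
    qt("NSP", "number of seeds per pod",       "pod",   "count"),
    qt("SL",  "seed length",                   "seed",  "cm"),
    qt("SW",  "seed width",                    "seed",  "cm"),
    qt("LWS", "length/width of seed",          "seed",  "ratio"),
    qt("HSW", "hundred-seed weight",           "seed",  "g"),
    ql("HP",  "hypocotyl pigmentation", "plant", 1:2, c("green", "purple")),
    ql("GH",  "growth habit",           "plant", 1:2, c("erect", "prostrate")),
    ql("PHA", "podding habit",          "plant", 1:2,
       c("determinate", "indeterminate")),
    ql("ST",  "stem type",              "plant", 1:2,
       c("normal stem", "clasp stem")),
    ql("LS",  "leaf shape",             "leaf",  1:2,
       c("ovate", "rhombic ovate")),
    ql("CS",  "color of standard",      "flower", 1:5, flower_colors),
    ql("CW",  "color of wings",         "flower", 1:5, flower_colors),
    ql("PC",  "pod color",              "pod",   1:4,
       c("stripe", "light brown", "yellowish white", "brown")),
    ql("SP",  "shape of pod",           "pod",   1:8,
       c("round curved", "short flat strip", "long flat strip",
         "sickle-shaped", "sword-shaped", "round curved stick-shaped",
         "short round stick-shaped", "long round stick-shaped")),
    ql("SPA", "shape of pod apex",      "pod",   1:2,
       c("acute apex", "obtuse apex")),
    ql("PS",  "pod surface",            "pod",   1:3,
       c("tiny protruding", "protruding", "flat")),
    ql("SS",  "seed shape",             "seed",  1:8,
       c("long elliptic", "ovate", "flat round", "square", "short cylinder",
         "elliptic", "kidney-shaped", "round")),
    ql("SCC", "seed coat color",        "seed",  1:10,
       c("stripe", "yellow", "white", "black", "brown", "yellowish-white",
         "pinkish-red", "milk white", "deep yellow", "red")),
    ql("SSC", "speckle of seed coat",   "seed",  0:3,
       c("free", "punctiform", "stripe", "reticulate")),
    ql("CSSC", "color speckle of seed coat", "seed", 0:5,
       c("free", "brown", "pink", "black", "light brown", "red")),
    ql("HC",  "hilum color",            "seed",  1:3,
       c("yellowish-white", "white", "light brown"))
  )
  new_trait_catalog(out)
}

new_trait_catalog <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("code", "name", "organ", "kind", "unit", "levels") %in%
                  names(x)))
  if (anyDuplicated(x$code) > 0) {
    stop("trait codes must be unique in a catalog", call. = FALSE)
  }
  bad_kind <- setdiff(unique(x$kind), c("qualitative", "quantitative"))
  if (length(bad_kind) > 0) {
    stop("unknown trait kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    lv <- x$levels[[i]]
    if (x$kind[i] == "qualitative") {
      if (is.null(lv) || nrow(lv) < 2) {
        stop("qualitative trait ", x$code[i], " must declare >= 2 levels",
             call. = FALSE)
      }
      if (anyDuplicated(lv$level) > 0) {
        stop("duplicate level codes for trait ", x$code[i], call. = FALSE)
      }
    } else if (!is.null(lv)) {
      stop("quantitative trait ", x$code[i], " must not declare levels",
           call. = FALSE)
    }
  }
  class(x) <- c("trait_catalog", class(tibble::tibble()))
  x
}

#' Look up a single trait descriptor
#'
#' @param catalog A `trait_catalog`.
#' @param code Trait code, e.g. `"HSW"`.
#' @return A one-row tibble for the descriptor.
#' @keywords internal
catalog_descriptor <- function(catalog, code) {
  i <- match(code, catalog$code)
  if (is.na(i)) {
    stop("unknown trait code: ", code, call. = FALSE)
  }
  catalog[i, ]
}

#' Declared level codes of a qualitative trait
#' @inheritParams catalog_descriptor
#' @return Integer vector of level codes.
#' @keywords internal
catalog_levels <- function(catalog, code) {
  d <- catalog_descriptor(catalog, code)
  if (d$kind != "qualitative") {
    stop("trait ", code, " is quantitative and has no levels", call. = FALSE)
  }
  d$levels[[1]]$level
}

#' @keywords internal
trait_codes <- function(catalog, kind = c("any", "qualitative", "quantitative")) {
  kind <- match.arg(kind)
  if (kind == "any") catalog$code else catalog$code[catalog$kind == kind]
}
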