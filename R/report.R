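#' Run the full characterization pipeline and write a report bundle
#'
#' Chains every analysis stage on one input — diversity report, UPGMA
#' clustering with a k-group cut and group profiles, correlation PCA,
#' gene-pool classification and regional composition — and writes all
#' outputs plus a run log to a directory.
#'
#' Files written: `diversity.csv`, `diversity.json`, `dendrogram.nwk`,
#' `groups.csv`, `pca_report.csv`, `pca_scores.csv`, `genepool_calls.csv`,
#' `regional_composition.csv` (omitted, with a log line, when no
#' accession has a region), and `run_log.txt`. Any stage failure is
#' re-thrown with the stage name.
#'
#' @param input A `germplasm_collection`, a path to a collection CSV, or a
#'   [simulation_config()] (the collection is then simulated).
#' @param out_dir Output directory (created if needed).
#' @param traits Trait codes to cluster/ordinate on (default: all).
#' @param k Number of dendrogram groups.
#' @param components Number of PCA components to export.
#' @param catalog Trait catalog used to read/validate the input.
#' @return Invisibly, a list with the in-memory stage results
#'   (`collection`, `diversity`, `dendrogram`, `groups`, `profiles`,
#'   `pca`, `calls`, `composition`, `files`).
#' @examples
#' out <- run_full_report(simulation_config(seed = 7),
#'                        out_dir = tempfile("report"))
#' out$composition$by_pool
#' @export
run_full_report <- function(input, out_dir, traits = NULL, k = 4,
                            components = 4, catalog = default_catalog()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  collection <- stage("input", {
    if (inherits(input, "germplasm_collection")) {
      input
    } else if (inherits(input, "simulation_config")) {
      note("simulating collection with seed %d", input$seed)
      simulate_collection(input, catalog)$collection
    } else if (is.character(input) && length(input) == 1) {
      load_collection(input, catalog)
    } else {
      stop("input must be a collection, a CSV path, or a simulation_config",
           call. = FALSE)
    }
  })
  note("collection: %d accessions, %d trait columns",
       nrow(collection), length(trait_columns(collection)))

  problems <- stage("validate", validate_collection(collection))
  if (nrow(problems) > 0) {
    stop("stage validate: collection has ", nrow(problems),
         " invariant violation(s); see validate_collection()",
         call. = FALSE)
  }

  files <- character()
  emit <- function(name) {
    path <- file.path(out_dir, name)
    files <<- c(files, path)
    path
  }

  div <- stage("diversity", diversity_report(collection))
  diversity_csv(div, emit("diversity.csv"))
  diversity_json(div, emit("diversity.json"))
  note("diversity: overall mean H' = %.3f", div$overall_mean)

  z <- stage("standardize", standardize(collection, traits))
  if (length(attr(z, "dropped_ids")) > 0) {
    note("clustering: dropped %d accession(s) with missing values: %s",
         length(attr(z, "dropped_ids")),
         paste(attr(z, "dropped_ids"), collapse = ", "))
  }
  dend <- stage("cluster", upgma(euclidean_distances(z)))
  as_newick(dend, emit("dendrogram.nwk"))
  groups <- stage("cut", cut_dendrogram(dend, k))
  readr::write_csv(groups, emit("groups.csv"), progress = FALSE)
  profiles <- stage("profiles", summarize_groups(collection, groups))
  note("cluster: k = %d groups of sizes %s", k,
       paste(sort(table(groups$group), decreasing = TRUE), collapse = "/"))

  pca <- stage("pca", correlation_pca(z))
  pca_report_csv(pca, emit("pca_report.csv"), components)
  pca_scores_csv(pca, emit("pca_scores.csv"), components)
  note("pca: first %d components explain %.2f%%", components,
       pca$cumulative[min(components, length(pca$cumulative))])

  calls <- stage("classify", {
    group_calls <- classify_gene_pool(profiles)
    acc_calls <- classify_accessions(collection)
    readr::write_csv(dplyr::select(group_calls, -"evidence"),
                     emit("genepool_calls.csv"), progress = FALSE)
    list(groups = group_calls, accessions = acc_calls)
  })
  composition <- NULL
  if (all(is.na(collection$region))) {
    note("composition: skipped, no accession has a region")
  } else {
    composition <- stage("composition",
                         regional_composition(collection,
                                              calls$accessions))
    readr::write_csv(composition$by_region,
                     emit("regional_composition.csv"), progress = FALSE)
  }

  note("package beandiv %s",
       as.character(utils::packageVersion("beandiv")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(collection = collection, diversity = div,
                 dendrogram = dend, groups = groups, profiles = profiles,
                 pca = pca, calls = calls, composition = composition,
                 files = files))
}
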