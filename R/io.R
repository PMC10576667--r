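# Delimited-text readers and writers for the registry tables, with schema
# validation, row-level diagnostics and a machine-readable run manifest.
# All tables are plain CSV; dates are ISO 8601; centroids may alternatively
# come from a GeoJSON file of Point features.

.table_schemas <- list(
  municipalities = c("municipality_id", "name", "x", "y"),
  census = c("municipality_id", "year", "sex", "age_class", "count"),
  patients = c("patient_id", "sex", "birth_date", "onset_date",
               "diagnosis_date", "genetic_status", "relatedness_group"),
  residences = c("patient_id", "dwelling_id", "municipality_id",
                 "start_date", "end_date"),
  dwellings = c("dwelling_id", "capacity"))

.parse_dates <- function(df, cols, table) {
  for (col in cols) {
    v <- as.character(df[[col]])
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", v)
    d <- as.Date(v, format = "%Y-%m-%d")
    bad <- which(!ok | is.na(d))
    if (length(bad)) {
      stop("malformed date in ", table, "$", col, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), ": '",
           v[bad[1]], "'")
    }
    df[[col]] <- d
  }
  df
}

#' Read and validate the pipeline's input tables
#'
#' Reads the five CSV tables, checks headers against the documented schemas,
#' parses ISO 8601 dates, and enforces referential integrity (residences
#' refer to known patients and municipalities; patient and dwelling ids are
#' unique). Errors name the offending table, column and rows.
#'
#' @param paths named list or vector with elements `municipalities`,
#'   `census`, `patients`, `residences` and optionally `dwellings`.
#' @return list of validated data.frames (same names), with `census` split
#'   into the rows carrying strata and the totals-only rows, plus
#'   `population`: the assembled [stratified_population()].
#' @export
read_inputs <- function(paths) {
  out <- list()
  for (nm in names(.table_schemas)) {
    if (is.null(paths[[nm]])) {
      if (nm == "dwellings") next
      stop("missing path for required table '", nm, "'")
    }
    if (!file.exists(paths[[nm]])) stop("file not found: ", paths[[nm]])
    df <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
    missing_cols <- setdiff(.table_schemas[[nm]], names(df))
    if (length(missing_cols)) {
      stop("table '", nm, "' is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    out[[nm]] <- df
  }
  out$patients <- .parse_dates(out$patients,
                               c("birth_date", "onset_date",
                                 "diagnosis_date"), "patients")
  out$residences <- .parse_dates(out$residences,
                                 c("start_date", "end_date"), "residences")

  if (any(dup <- duplicated(out$patients$patient_id))) {
    stop("duplicate patient_id at row(s) ",
         paste(which(dup), collapse = ", "))
  }
  if (!is.null(out$dwellings) &&
      any(dup <- duplicated(out$dwellings$dwelling_id))) {
    stop("duplicate dwelling_id at row(s) ",
         paste(which(dup), collapse = ", "))
  }
  bad <- which(!(out$residences$municipality_id %in%
                   out$municipalities$municipality_id))
  if (length(bad)) {
    stop("residences row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " reference unknown municipality '",
         out$residences$municipality_id[bad[1]], "'")
  }
  bad <- which(!(out$residences$patient_id %in% out$patients$patient_id))
  if (length(bad)) {
    stop("residences row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " reference unknown patient '",
         out$residences$patient_id[bad[1]], "'")
  }

  cen <- out$census
  has_strata <- !is.na(cen$sex) & !is.na(cen$age_class)
  totals <- cen[!has_strata, c("municipality_id", "year", "count")]
  strata <- if (any(has_strata)) cen[has_strata, ] else NULL
  out$population <- stratified_population(totals, strata)
  out
}

#' Read municipality centroids from GeoJSON
#'
#' Accepts a FeatureCollection of Point features; the municipality id is
#' taken from the `municipality_id` (or `id`) property.
#'
#' @param path GeoJSON file.
#' @return data.frame `municipality_id`, `x`, `y`.
#' @export
read_centroids_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      stop("only Point features are supported")
    }
    id <- f$properties$municipality_id %||% f$properties$id %||% f$id
    if (is.null(id)) stop("feature without a municipality id property")
    data.frame(municipality_id = as.character(id),
               x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]))
  })
  do.call(rbind, rows)
}

#' Write scan and dwelling-analysis reports
#'
#' Writes one CSV row per (offset, direction, cluster rank) for the scan, a
#' dwelling-analysis CSV when supplied, and a JSON run manifest (the
#' configuration, seeds and package version needed for a bit-identical
#' re-run).
#'
#' @param scan a `timeshift_scan` result (or `NULL`).
#' @param dwelling a list of restriction reports from
#'   [restrict_and_rerun()] and/or [cooccurrence_probability()] summaries
#'   (or `NULL`).
#' @param dir output directory (created if needed).
#' @param config list recorded verbatim in the manifest.
#' @return invisibly, the paths written.
#' @export
write_reports <- function(scan = NULL, dwelling = NULL, dir,
                          config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(scan)) {
    p <- file.path(dir, "scan_clusters.csv")
    utils::write.csv(scan$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(dwelling)) {
    rows <- lapply(seq_along(dwelling), function(i) {
      d <- dwelling[[i]]
      data.frame(analysis = names(dwelling)[i] %||% as.character(i),
                 ceiling = d$ceiling %||% NA,
                 n_dwellings = d$n_dwellings_kept %||% NA,
                 observed_pairs = d$observed_pairs,
                 observed_trios = d$observed_trios,
                 P_pairs = d$P_pairs, P_trios = d$P_trios)
    })
    p <- file.path(dir, "dwelling_analysis.csv")
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "presymscan",
    version = as.character(utils::packageVersion("presymscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    scan_seed = if (!is.null(scan)) scan$seed else NULL,
    scan_replicates = if (!is.null(scan)) scan$R else NULL)
  mp <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}

#' Write a synthetic cohort and region to CSV
#'
#' Writes the five input tables in the exact schemas [read_inputs()]
#' expects, so generated fixtures round-trip through the readers.
#'
#' @param region a [generate_region()] fixture.
#' @param cohort a [generate_cohort()] result.
#' @param registry optional dwelling registry.
#' @param dir output directory.
#' @return invisibly, the named vector of paths written.
#' @export
write_fixture <- function(region, cohort, registry = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(municipalities = file.path(dir, "municipalities.csv"),
             census = file.path(dir, "census.csv"),
             patients = file.path(dir, "patients.csv"),
             residences = file.path(dir, "residences.csv"))
  utils::write.csv(region$municipalities, paths["municipalities"],
                   row.names = FALSE)
  pop <- region$population
  tm <- pop$totals
  tot_years <- setdiff(pop$years, pop$adjusted_years)
  totals <- data.frame(
    municipality_id = rep(rownames(tm), times = length(tot_years)),
    year = rep(tot_years, each = nrow(tm)),
    sex = NA_character_, age_class = NA_character_,
    count = as.vector(tm[, as.character(tot_years)]))
  strat <- do.call(rbind, lapply(pop$adjusted_years, function(yr) {
    sl <- pop$strata[, , as.character(yr)]
    lab <- strsplit(colnames(sl), ".", fixed = TRUE)
    data.frame(municipality_id = rep(rownames(sl), times = ncol(sl)),
               year = yr,
               sex = rep(vapply(lab, `[`, "", 1), each = nrow(sl)),
               age_class = rep(vapply(lab, `[`, "", 2), each = nrow(sl)),
               count = as.vector(sl))
  }))
  utils::write.csv(rbind(totals, strat), paths["census"], row.names = FALSE)
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(cohort$residences, paths["residences"],
                   row.names = FALSE)
  if (!is.null(registry)) {
    paths <- c(paths, dwellings = file.path(dir, "dwellings.csv"))
    utils::write.csv(as.data.frame(registry), paths["dwellings"],
                     row.names = FALSE)
  }
  invisible(paths)
}
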