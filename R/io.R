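# Crash-table schema: canonical column names, indicator groups and units.
# Indicator groups are mutually exclusive with an all-zeros reference row
# (reference categories: passenger car, before dawn, single-vehicle crash).
crash_schema <- function() {
  list(outcome = "fatal",
       section = "section_id",
       groups = list(
         vehicle = c("coach", "truck", "other_vehicle"),
         time_of_day = c("morning", "afternoon", "evening"),
         crash_type = c("rear_end_crash", "angle_crash")),
       binary = c("weekend", "non_local_vehicle", "bridge", "ramp"),
       positive = c("ems_time"),
       continuous = c("ems_time", "curvature", "grade", "wind_speed",
                      "precipitation", "temperature", "humidity",
                      "visibility"))
}

#' Validate a crash-level table
#'
#' Checks the schema contract used throughout the package: binary 0/1
#' outcome, strictly positive EMS response time (minutes), 0/1 indicators, at
#' most one active indicator per mutually exclusive group (vehicle type,
#' time of day, crash type), and -- when a network is supplied -- that every
#' crash's section id exists in it. Violations are reported with the
#' offending row and column.
#'
#' @param data Crash-level data frame.
#' @param network Optional [build_adjacency()] `section_network` against which
#'   section ids are checked.
#' @param outcome,section Column names of the binary outcome and the section
#'   identifier.
#' @return `data`, invisibly, with the section column coerced to character.
#' @export
validate_crash_data <- function(data, network = NULL, outcome = "fatal",
                                section = "section_id") {
  sch <- crash_schema()
  if (!outcome %in% names(data))
    stop("missing outcome column '", outcome, "'")
  bad <- which(!data[[outcome]] %in% c(0, 1))
  if (length(bad))
    stop("non-binary outcome value ", data[[outcome]][bad[1L]],
         " in column '", outcome, "', row ", bad[1L])
  for (col in intersect(sch$positive, names(data))) {
    bad <- which(!is.finite(data[[col]]) | data[[col]] <= 0)
    if (length(bad))
      stop("non-positive value in column '", col, "', row ", bad[1L])
  }
  inds <- c(unlist(sch$groups, use.names = FALSE), sch$binary)
  for (col in intersect(inds, names(data))) {
    bad <- which(!data[[col]] %in% c(0, 1))
    if (length(bad))
      stop("indicator column '", col, "' has non-0/1 value in row ", bad[1L])
  }
  for (g in names(sch$groups)) {
    cols <- intersect(sch$groups[[g]], names(data))
    if (length(cols) > 1L) {
      tot <- rowSums(data[cols])
      bad <- which(tot > 1)
      if (length(bad))
        stop("more than one active indicator in group '", g,
             "' (columns ", paste(cols, collapse = ", "), "), row ", bad[1L])
    }
  }
  if (section %in% names(data)) {
    data[[section]] <- as.character(data[[section]])
    if (!is.null(network)) {
      bad <- which(!data[[section]] %in% network$section_ids)
      if (length(bad))
        stop("unknown section id '", data[[section]][bad[1L]],
             "' in row ", bad[1L])
    }
  } else if (!is.null(network)) {
    stop("missing section column '", section, "'")
  }
  invisible(data)
}

#' Read a crash-level CSV
#'
#' Reads one row per crash and validates it with [validate_crash_data()].
#'
#' @inheritParams validate_crash_data
#' @param path Path to the CSV file.
#' @param required Character vector of column names that must be present
#'   (in addition to the outcome).
#' @return A validated data frame.
#' @export
read_crash_csv <- function(path, network = NULL, outcome = "fatal",
                           section = "section_id", required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c(outcome, required), names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  validate_crash_data(data, network = network, outcome = outcome,
                      section = section)
  if (section %in% names(data)) data[[section]] <- as.character(data[[section]])
  data
}

#' Write a crash-level CSV
#'
#' @param data Crash-level data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crash_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the full output bundle of a fitted model
#'
#' Writes, under `dir`: `draws.csv` (one column per monitored parameter plus
#' the deviance), `report.csv` and `report.txt` (the posterior summary table),
#' and `manifest.json` (seed, sampler configuration and its hash, acceptance
#' rates, convergence flags, and package version) -- enough to reproduce and
#' audit the run.
#'
#' @param object A fitted [spatlogit()] model.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit_outputs <- function(object, dir) {
  stopifnot(inherits(object, "spatlogit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- cbind(as.data.frame(object$draws), deviance = object$deviance)
  write.csv(draws, file.path(dir, "draws.csv"), row.names = FALSE)
  s <- summary(object)
  write.csv(s$coefficients, file.path(dir, "report.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(s)), file.path(dir, "report.txt"))
  cfg <- list(family = object$family,
              formula = deparse(object$formula),
              random = object$random,
              priors = object$priors,
              control = object$control[c("n_iter", "n_burnin", "thin",
                                         "adapt_interval", "target_accept")],
              seed = object$seed)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  conv <- convergence_check(object)
  manifest <- list(package = "spatlogit",
                   version = as.character(packageVersion("spatlogit")),
                   config = cfg,
                   config_md5 = unname(tools::md5sum(tf)),
                   n_obs = object$n_obs,
                   acceptance = object$acceptance,
                   dic = object$dic[c("dbar", "pd", "dic")],
                   converged = list(all = all(conv$pass, na.rm = TRUE),
                                    ratio = stats::setNames(conv$ratio,
                                                            conv$parameter)))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
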