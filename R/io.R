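#' Dataset readers and writers
#'
#' All dialects are plain comma-separated UTF-8 files with headers.
#' Edge list: \code{from,to,travel_time} (minutes).  Vertex roles:
#' \code{id,role}.  Origin covariates: \code{id,pop,CA}.  Destination
#' covariates: \code{id,A,camp,fac,mar,lpop}.  Shifts:
#' \code{shift,station,start,end} (decimal hours).  Counts:
#' \code{shift,origin,destination,count} (zeros implicit; shifts with no
#' surveyed agents appear only in the shift table).  Compliance:
#' \code{shift,stopped,bypassed,highrisk_stopped,highrisk_complete}
#' (\code{bypassed} may be empty).  Survey times:
#' \code{obs,shift,time}.
#'
#' @param path file path
#' @param edges_file,roles_file paths of the edge list and vertex-role
#'   tables
#' @name io
NULL

.read_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df
}

#' @rdname io
#' @export
read_road_network <- function(edges_file, roles_file = NULL) {
  edges <- .read_csv(edges_file, c("from", "to", "travel_time"))
  roles <- if (!is.null(roles_file)) .read_csv(roles_file, c("id", "role"))
  road_network(edges, roles)
}

#' @rdname io
#' @export
read_origin_covariates <- function(path)
  .read_csv(path, c("id", "pop", "CA"))

#' @rdname io
#' @export
read_destination_covariates <- function(path)
  .read_csv(path, c("id", "A", "camp", "fac", "mar", "lpop"))

#' @rdname io
#' @export
read_compliance_data <- function(path) {
  df <- .read_csv(path, c("shift", "stopped", "bypassed",
                          "highrisk_stopped", "highrisk_complete"))
  if (any(df$highrisk_complete > df$highrisk_stopped, na.rm = TRUE))
    stop(path, ": highrisk_complete exceeds highrisk_stopped")
  df
}

#' @rdname io
#' @export
read_survey_times <- function(path)
  .read_csv(path, c("obs", "shift", "time"))

#' Read and cross-validate the survey count dataset
#'
#' @param shifts_file,counts_file CSV paths (see \link{io})
#' @param origins,destinations the origin/destination id universe
#' @return a \code{\link{count_data}}
#' @export
read_counts <- function(shifts_file, counts_file, origins, destinations) {
  shifts <- .read_csv(shifts_file, c("shift", "station", "start", "end"))
  counts <- .read_csv(counts_file, c("shift", "origin", "destination",
                                     "count"))
  count_data(shifts, counts, origins, destinations)
}

#' Read all five datasets of a run configuration
#'
#' Performs cross-referential validation: count records must reference
#' known shifts, origins, destinations; stations must be network vertices;
#' every observation time must lie inside its shift window.  Violations
#' fail hard with the offending record named.
#'
#' @param config a list (typically from \code{\link{read_run_config}})
#'   with components \code{edges}, \code{roles}, \code{origins},
#'   \code{destinations}, \code{shifts}, \code{counts}, \code{compliance},
#'   \code{survey_times}: file paths
#' @return list of validated datasets
#' @export
read_datasets <- function(config) {
  net <- read_road_network(config$edges, config$roles)
  origins <- read_origin_covariates(config$origins)
  destinations <- read_destination_covariates(config$destinations)
  for (nm in c("origin", "destination", "station")) {
    ids <- switch(nm, origin = origins$id, destination = destinations$id,
                  station = network_vertices(net, "station"))
    miss <- setdiff(as.character(ids), network_vertices(net))
    if (length(miss))
      stop("unknown ", nm, " vertices: ", paste(miss, collapse = ", "))
  }
  cdata <- read_counts(config$shifts, config$counts,
                       origins$id, destinations$id)
  st <- setdiff(unique(cdata$shifts$station), network_vertices(net, "station"))
  if (length(st))
    stop("shift stations not marked as stations in the network: ",
         paste(st, collapse = ", "))
  compliance <- read_compliance_data(config$compliance)
  times <- read_survey_times(config$survey_times)
  si <- match(times$shift, cdata$shifts$shift)
  if (anyNA(si))
    stop("survey times reference unknown shifts: ",
         paste(unique(times$shift[is.na(si)]), collapse = ", "))
  ws <- cdata$shifts$start[si]; we <- cdata$shifts$end[si]
  inside <- ifelse(we > ws, times$time >= ws & times$time <= we,
                   times$time >= ws | times$time <= we %% 24)
  if (any(!inside))
    stop("observation times outside their shift window: ",
         paste(utils::head(times$obs[!inside], 5), collapse = ", "))
  list(network = net, origins = origins, destinations = destinations,
       counts = cdata, compliance = compliance, survey_times = times)
}

#' Write the synthetic datasets of a scenario to CSV files
#'
#' Emits the exact dialects the readers consume, so the simulator doubles
#' as a format fixture generator.
#'
#' @param scenario a \code{\link{generate_scenario}} result
#' @param surveys a \code{\link{simulate_surveys}} result
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of file paths
#' @export
write_datasets <- function(scenario, surveys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- scenario$network
  el <- igraph::as_edgelist(net$graph)
  paths <- c(edges = "edges.csv", roles = "roles.csv",
             origins = "origins.csv", destinations = "destinations.csv",
             shifts = "shifts.csv", counts = "counts.csv",
             compliance = "compliance.csv", survey_times = "survey_times.csv")
  paths[] <- file.path(dir, paths)
  utils::write.csv(data.frame(from = el[, 1], to = el[, 2],
                              travel_time = igraph::E(net$graph)$weight),
                   paths["edges"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(id = names(net$roles), role = net$roles),
                   paths["roles"], row.names = FALSE, quote = FALSE)
  utils::write.csv(scenario$origins, paths["origins"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(scenario$destinations, paths["destinations"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(surveys$counts$shifts[, c("shift", "station", "start",
                                             "end")],
                   paths["shifts"], row.names = FALSE, quote = FALSE)
  utils::write.csv(surveys$counts$counts, paths["counts"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(surveys$compliance, paths["compliance"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(surveys$survey_times, paths["survey_times"],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; top-level keys name the dataset files
#'   (\code{edges}, \code{roles}, \code{origins}, \code{destinations},
#'   \code{shifts}, \code{counts}, \code{compliance},
#'   \code{survey_times}), model settings (\code{gamma}, \code{delta},
#'   \code{free}, \code{start}), optimizer settings and \code{seed};
#'   relative paths resolve against the config file's directory
#' @return named list, class \code{run_config}
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in c("edges", "roles", "origins", "destinations", "shifts",
               "counts", "compliance", "survey_times")) {
    if (!is.null(cfg[[nm]]) && !grepl("^(/|[A-Za-z]:)", cfg[[nm]]))
      cfg[[nm]] <- file.path(base, cfg[[nm]])
  }
  cfg$path <- path
  structure(cfg, class = "run_config")
}
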