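#' Read a YAML or JSON configuration file
#'
#' @param path File path; `.json` is parsed with jsonlite, anything else
#'   with yaml (YAML is a superset of JSON, so either extension works).
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N:` key as the boolean FALSE; the only key in the
  # config schema that can trigger this is the population size, so map it back
  if (is.list(cfg) && !is.null(names(cfg)))
    names(cfg)[names(cfg) %in% c("FALSE", "TRUE")] <- "N"
  cfg
}

#' Export a trajectory as CSV
#'
#' Writes an RFC-4180 CSV with header `t,S,I,R,sigma,Rn`. The logarithmic
#' growth rate and effective reproduction number are computed on the grid;
#' undefined values (active count below the floor) are written as empty
#' fields. Numbers are written with 10 significant digits, so re-parsing
#' reproduces the written values exactly at that precision.
#'
#' @param traj A [wave_trajectory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "wave_trajectory"))
  sigma <- growth_rate(traj)
  Rn <- 1 + sigma / traj_params(traj)$rho
  fmt <- function(x) ifelse(is.na(x), "",
                            trimws(formatC(x, digits = 10, format = "g")))
  df <- data.frame(t = fmt(traj$t), S = fmt(traj$S), I = fmt(traj$I),
                   R = fmt(traj$R), sigma = fmt(sigma), Rn = fmt(Rn),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-import a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return A data frame with numeric columns `t`, `S`, `I`, `R`, `sigma`,
#'   `Rn` (`NA` where fields were empty).
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Export a trajectory as JSON
#'
#' JSON mirror of the CSV export with metadata: generating parameters,
#' source label, and the integration/evaluation tolerances in force.
#'
#' @param traj A [wave_trajectory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  stopifnot(inherits(traj, "wave_trajectory"))
  params <- traj_params(traj)
  sigma <- growth_rate(traj)
  payload <- list(
    metadata = list(
      source = traj_source(traj),
      params = params[c("N", "tau", "rho", "S0", "I0", "R0")],
      tolerances = list(rtol = 1e-9, atol_frac_N = 1e-9,
                        sigma_floor_frac_N = 1e-12)
    ),
    t = traj$t, S = traj$S, I = traj$I, R = traj$R,
    sigma = sigma, Rn = 1 + sigma / params$rho
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
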