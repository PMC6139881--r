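#' Read a concentration-series dataset from CSV
#'
#' Expected header: `c_nM, l_um, l_se, tau_s, tau_se, V_um_s, V_se,
#' lam_um_s, lam_se`; empty cells mark missing observations. Values are
#' validated (positive concentrations, positive standard errors wherever a
#' value is present) and returned with the package-internal short names.
#'
#' @param path CSV file path.
#' @return A tibble with columns `c`, `l`, `l_se`, `tau`, `tau_se`, `V`,
#'   `V_se`, `lam`, `lam_se`.
#' @export
read_dataset_csv <- function(path) {
  schema <- c(c_nM = "c", l_um = "l", l_se = "l_se", tau_s = "tau",
              tau_se = "tau_se", V_um_s = "V", V_se = "V_se",
              lam_um_s = "lam", lam_se = "lam_se")
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "d"))
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols)) {
    abort(paste("malformed header; missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  d <- setNames(raw[names(schema)], schema)
  if (any(!is.finite(d$c) | d$c <= 0)) {
    abort("concentrations must be present and positive")
  }
  for (obs in c("l", "tau", "V", "lam")) {
    se <- d[[paste0(obs, "_se")]]
    bad <- which(is.finite(d[[obs]]) & (!is.finite(se) | se <= 0))
    if (length(bad)) {
      abort(sprintf("row %d, column %s_se: standard error must be positive where a value is present",
                    bad[1], obs))
    }
  }
  tibble::as_tibble(d)
}

#' Write a concentration-series dataset to CSV
#'
#' Inverse of [read_dataset_csv()]; finite values round-trip exactly.
#'
#' @param data Dataset tibble (internal column names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  schema <- c(c = "c_nM", l = "l_um", l_se = "l_se", tau = "tau_s",
              tau_se = "tau_se", V = "V_um_s", V_se = "V_se",
              lam = "lam_um_s", lam_se = "lam_se")
  out <- setNames(data[names(schema)], schema)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a trajectory table to CSV
#'
#' Positions are in lattice sites; the site length `a` (nm per site) is
#' recorded in a comment header for unit conversion.
#'
#' @param traj Trajectory tibble (`motor_id`, `t`, `position`, and
#'   optionally `site`, `active`).
#' @param path Output path.
#' @param a Site length (um).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, a = 0.0084) {
  con <- file(path, "w")
  writeLines(sprintf("# position unit: lattice site; a_nm_per_site=%g",
                     a * 1000), con)
  close(con)
  readr::write_csv(traj, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory_csv()]
#'
#' @param path CSV path (external tables with columns `motor_id`, `t`,
#'   `position` are accepted too).
#' @return A trajectory tibble.
#' @export
read_trajectory_csv <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("motor_id", "t", "position")
  if (!all(need %in% names(d))) {
    abort("trajectory CSV needs columns motor_id, t, position")
  }
  tibble::as_tibble(d)
}

#' Wrap a result payload with provenance
#'
#' Every artifact written by the command-line interface embeds the exact
#' configuration, seed and package version that produced it.
#'
#' @param command Subcommand name.
#' @param payload Named list or one-row data frame of results.
#' @param config Configuration snapshot (named list).
#' @param seed Integer seed used.
#' @return A list of class `"result_envelope"`.
#' @export
result_envelope <- function(command, payload, config = list(), seed = NA) {
  structure(
    list(command = command, package = "kintraffic",
         version = as.character(utils::packageVersion("kintraffic")),
         seed = seed, config = config,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         payload = payload),
    class = "result_envelope"
  )
}

#' Write a result envelope as JSON
#'
#' @param env A [result_envelope()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope_json <- function(env, path) {
  jsonlite::write_json(unclass(env), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
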