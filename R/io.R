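# CSV / JSON plumbing: plate tables, trace tables and their metadata
# sidecars.  Time columns are always decimal hours ("time_h").

#' Write or read a plate table as CSV
#'
#' The plate CSV has column 1 \code{time_h} followed by one column per well.
#' When metadata or a manifest is supplied, a JSON sidecar
#' (\code{<path>.json}) is written next to the CSV.
#'
#' @param plate plate data.frame (\code{time_h} + well columns), or the list
#'   returned by \code{\link{generate_plate}} (its manifest becomes the
#'   sidecar).
#' @param path CSV path.
#' @param manifest optional list stored as the JSON sidecar.
#' @return \code{path}, invisibly.
#' @export
write_plate <- function(plate, path, manifest = NULL) {
  if (is.list(plate) && !is.data.frame(plate) && !is.null(plate$plate)) {
    manifest <- manifest %||% plate$manifest
    plate <- plate$plate
  }
  stopifnot(is.data.frame(plate), names(plate)[1] == "time_h")
  write.csv(plate, path, row.names = FALSE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_plate
#' @return \code{read_plate} returns a list with \code{plate} and (if the
#'   sidecar exists) \code{manifest}.
#' @export
read_plate <- function(path) {
  plate <- read.csv(path, check.names = FALSE)
  if (names(plate)[1] != "time_h")
    stop("malformed plate CSV (first column must be 'time_h'): ", path)
  side <- paste0(path, ".json")
  manifest <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  list(plate = plate, manifest = manifest)
}

#' Serialize a fitted model to JSON
#'
#' Stores the best parameter set, the final optimizer population with costs,
#' stage diagnostics and the fit's seed so a fit can be archived or passed
#' to the command-line tools.
#'
#' @param fit a \code{\link{clock_fit}}.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "clock_fit"))
  jsonlite::write_json(
    list(params = unclass(fit$params), e_f = fit$e_f, cost = fit$cost,
         d_data = fit$d_data,
         population = fit$population$members,
         population_costs = fit$population$costs,
         seed = fit$control$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read fitted parameters from a fit JSON
#'
#' @param path JSON written by \code{\link{write_fit}}.
#' @return a \code{\link{clock_parameters}} object.
#' @export
read_fit_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$params
  clock_parameters(A = p$A, d_M = p$d_M, d_P = p$d_P, d_R = p$d_R,
                   i = p$i, sigma = p$sigma, K = p$K)
}
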