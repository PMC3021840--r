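#' Create or extend a provenance record
#'
#' Every data object in the package carries a nested provenance tree: the
#' name and parameters of the step that produced it, plus the provenance of
#' each input object.  The full processing history of any object is therefore
#' recoverable by recursive descent, without retaining the data payloads
#' themselves (only parameters are stored).
#'
#' @param previous list of `meeg_prov` objects (the inputs' provenance);
#'   empty list for a root node.
#' @param step_name character scalar naming the operation.
#' @param parameters named list of parameter values (must be representable
#'   as a key-value tree; data payloads do not belong here).
#' @return An object of class `meeg_prov`.
#' @export
append_provenance <- function(previous = list(), step_name, parameters = list()) {
  stopifnot(is.character(step_name), length(step_name) == 1L)
  if (inherits(previous, "meeg_prov")) previous <- list(previous)
  stopifnot(is.list(previous))
  for (p in previous) {
    if (!inherits(p, "meeg_prov")) stop("'previous' must contain meeg_prov objects")
  }
  structure(
    list(
      step_name = step_name,
      parameters = parameters,
      previous = previous,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      version = as.character(utils::packageVersion("meegflow"))
    ),
    class = "meeg_prov"
  )
}

#' Depth of a provenance chain
#'
#' The number of steps along the longest path from this node back to a root.
#'
#' @param prov a `meeg_prov` object (or NULL, depth 0).
#' @return integer depth; a single root step has depth 1.
#' @export
provenance_depth <- function(prov) {
  if (is.null(prov)) return(0L)
  stopifnot(inherits(prov, "meeg_prov"))
  if (length(prov$previous) == 0L) return(1L)
  1L + max(vapply(prov$previous, provenance_depth, integer(1)))
}

#' Flatten a provenance chain to a vector of step names (root first)
#'
#' For linear (single-input) histories; merge nodes follow their first input.
#' @param prov a `meeg_prov` object.
#' @return character vector of step names.
#' @export
provenance_steps <- function(prov) {
  if (is.null(prov)) return(character(0))
  below <- if (length(prov$previous)) provenance_steps(prov$previous[[1]]) else character(0)
  c(below, prov$step_name)
}

#' Export provenance as JSON
#'
#' @param prov a `meeg_prov` object.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
provenance_to_json <- function(prov, path = NULL) {
  stopifnot(inherits(prov, "meeg_prov"))
  js <- jsonlite::toJSON(prov_to_list(prov), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

prov_to_list <- function(prov) {
  list(
    step_name = prov$step_name,
    parameters = prov$parameters,
    timestamp = prov$timestamp,
    version = prov$version,
    previous = lapply(prov$previous, prov_to_list)
  )
}

#' Rebuild a provenance object from its JSON export
#' @param path file path or JSON string.
#' @return a `meeg_prov` object.
#' @export
provenance_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  list_to_prov(x)
}

list_to_prov <- function(x) {
  structure(
    list(
      step_name = x$step_name,
      parameters = x$parameters,
      previous = lapply(x$previous, list_to_prov),
      timestamp = x$timestamp,
      version = x$version
    ),
    class = "meeg_prov"
  )
}

#' @export
print.meeg_prov <- function(x, ...) {
  cat("Provenance:", paste(provenance_steps(x), collapse = " -> "), "\n")
  invisible(x)
}
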