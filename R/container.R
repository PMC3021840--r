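# On-disk container: one file per data object (RDS serialization of the
# structured list, groups mirroring fields), with the provenance tree
# additionally exportable as JSON (see provenance_to_json).

#' Save a data object to the package container format
#'
#' @param obj any package data object (`meeg_raw`, `meeg_freq`, ...).
#' @param path output file path (conventionally `.rds`).
#' @param provenance_json optional path for a JSON export of the object's
#'   provenance alongside the container.
#' @return invisible path.
#' @export
save_meeg <- function(obj, path, provenance_json = NULL) {
  saveRDS(obj, path)
  if (!is.null(provenance_json) && !is.null(obj$provenance))
    provenance_to_json(obj$provenance, provenance_json)
  invisible(path)
}

#' Load a data object from the package container format
#'
#' @param path file path written by [save_meeg()].
#' @return the stored object.
#' @export
load_meeg <- function(path) readRDS(path)
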