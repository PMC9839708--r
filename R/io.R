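# Shared persistence: manifest CSVs, segment array containers, versioned
# artifacts (models, classifiers, embeddings) and metrics JSON.

MANIFEST_COLS <- c("segment_id", "patient_id", "institution", "label",
                   "sampling_rate_hz", "array_key")
ARTIFACT_MAGIC <- "ieegsift-artifact"
ARTIFACT_VERSION <- 1L

#' Build a manifest data frame from segment records
#' @param segments list of `segment_record`s.
#' @return data.frame with the manifest columns; unlabeled segments carry NA.
#' @export
segments_to_manifest <- function(segments) {
  data.frame(
    segment_id = segment_ids(segments),
    patient_id = vapply(segments, function(s) s$patient_id, character(1)),
    institution = vapply(segments, function(s) s$institution, character(1)),
    label = vapply(segments, function(s)
      if (is.null(s$label)) NA_integer_ else as.integer(s$label), integer(1)),
    sampling_rate_hz = vapply(segments, function(s) s$sampling_rate_hz, numeric(1)),
    array_key = segment_ids(segments)
  )
}

#' Write a manifest CSV
#' @param manifest data.frame with the manifest columns.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, MANIFEST_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a manifest CSV
#'
#' @param path CSV path with the declared header.
#' @param allowed_labels label code set (default 0-3); empty string / NA means
#'   unlabeled.
#' @return the manifest data.frame.
#' @export
read_manifest <- function(path, allowed_labels = 0:3) {
  m <- utils::read.csv(path, colClasses = c(
    segment_id = "character", patient_id = "character",
    institution = "character", label = "integer",
    sampling_rate_hz = "numeric", array_key = "character"))
  if (!identical(sort(names(m)), sort(MANIFEST_COLS))) {
    ieeg_error("manifest is missing required columns", "ieegsift_bad_manifest")
  }
  dup <- duplicated(m$segment_id)
  if (any(dup)) {
    ieeg_error(sprintf("duplicate segment_id '%s' at row %d",
                       m$segment_id[dup][1], which(dup)[1]),
               "ieegsift_bad_manifest")
  }
  bad <- !is.na(m$label) & !m$label %in% allowed_labels
  if (any(bad)) {
    ieeg_error(sprintf("unknown label %d at row %d (segment '%s')",
                       m$label[bad][1], which(bad)[1], m$segment_id[bad][1]),
               "ieegsift_bad_manifest")
  }
  m
}

#' Write segment sample vectors to an array container
#'
#' One single-file container of named sample vectors keyed by segment id,
#' alongside which [write_manifest()] describes provenance and labels.
#'
#' @param segments list of `segment_record`s.
#' @param path output path (`.rds`).
#' @export
write_segment_array <- function(segments, path) {
  arrays <- stats::setNames(lapply(segments, function(s) s$samples),
                            segment_ids(segments))
  saveRDS(arrays, path)
  invisible(path)
}

#' Read a segment array container back, joined with its manifest
#' @param array_path container written by [write_segment_array()].
#' @param manifest a manifest data.frame (or path to one).
#' @return list of `segment_record`s.
#' @export
read_segment_array <- function(array_path, manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  arrays <- readRDS(array_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    samples <- arrays[[row$array_key]]
    if (is.null(samples)) {
      ieeg_error(sprintf("array key '%s' missing from container", row$array_key),
                 "ieegsift_bad_manifest")
    }
    structure(list(segment_id = row$segment_id, samples = samples,
                   sampling_rate_hz = row$sampling_rate_hz,
                   label = if (is.na(row$label)) NA_integer_ else as.integer(row$label),
                   patient_id = row$patient_id, institution = row$institution),
              class = "segment_record")
  })
}

#' Save a versioned artifact (model, classifier, embeddings, metrics)
#'
#' The artifact header records the format version, creation time, the package
#' version string and any caller-supplied config; `load_artifact` verifies
#' the header before returning the payload.
#'
#' @param object payload to store.
#' @param path output path.
#' @param config optional configuration to record in the header.
#' @export
save_artifact <- function(object, path, config = NULL) {
  saveRDS(list(magic = ARTIFACT_MAGIC, version = ARTIFACT_VERSION,
               created = format(Sys.time(), tz = "UTC"),
               package_version = as.character(utils::packageVersion("ieegsift")),
               config = config, payload = object),
          path)
  invisible(path)
}

#' Load an artifact written by [save_artifact()]
#' @param path artifact path.
#' @return the stored payload, with the header attached as attribute
#'   `"artifact_header"`.
#' @export
load_artifact <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) e)
  if (inherits(obj, "error")) {
    ieeg_error(sprintf("artifact '%s' is corrupt or truncated: %s",
                       path, conditionMessage(obj)), "ieegsift_corrupt_artifact")
  }
  if (!is.list(obj) || !identical(obj$magic, ARTIFACT_MAGIC)) {
    ieeg_error(sprintf("'%s' is not an ieegsift artifact", path),
               "ieegsift_corrupt_artifact")
  }
  if (!identical(obj$version, ARTIFACT_VERSION)) {
    ieeg_error(sprintf("artifact version %s does not match supported version %s",
                       obj$version, ARTIFACT_VERSION), "ieegsift_corrupt_artifact")
  }
  payload <- obj$payload
  attr(payload, "artifact_header") <- obj[c("version", "created",
                                            "package_version", "config")]
  payload
}

#' Write a metrics report as JSON
#' @param report a `metrics_report` or any list of metric values.
#' @param path output JSON path.
#' @export
write_metrics_json <- function(report, path) {
  x <- report
  if (inherits(x, "metrics_report")) {
    x <- list(per_fold = x$per_fold, mean = as.list(x$mean), sd = as.list(x$sd),
              recall = as.data.frame(x$recall),
              confusion = as.data.frame.matrix(x$confusion))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
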