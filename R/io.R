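#' Read and write the package's CSV dialects
#'
#' Plain-text interchange formats: telemetry
#' (`time_s,heading_deg,altitude_ft,speed_kt`), RR series (`time_s,rr_ms`),
#' turn segments
#' (`start_s,end_s,pre_heading,post_heading,heading_delta,altitude_change,class_id,class_name`)
#' and the per-window feature matrix
#' (`subject,start_s,end_s,class_id,` + 30 feature columns).
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name turnload_io
NULL

#' @rdname turnload_io
#' @export
write_telemetry_csv <- function(x, path) {
  utils::write.csv(x[, c("time_s", "heading_deg", "altitude_ft", "speed_kt")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname turnload_io
#' @export
read_telemetry_csv <- function(path) as_tibble(utils::read.csv(path))

#' @rdname turnload_io
#' @export
write_rr_csv <- function(x, path) {
  utils::write.csv(x[, c("time_s", "rr_ms")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname turnload_io
#' @export
read_rr_csv <- function(path) as_tibble(utils::read.csv(path))

#' @rdname turnload_io
#' @export
write_segments_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname turnload_io
#' @export
read_segments_csv <- function(path) as_tibble(utils::read.csv(path))

#' @rdname turnload_io
#' @export
write_features_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname turnload_io
#' @export
read_features_csv <- function(path) as_tibble(utils::read.csv(path))
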