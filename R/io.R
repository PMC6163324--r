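#' Read a cane recording from delimited text
#'
#' Recordings are stored as CSV with a header row
#' `time_s,strain,gyro_ap[,switch]`. Time is stored explicitly even though
#' it is uniform; the sample rate is derived from the time column and
#' cross-checked, which catches corrupt exports. A `schema` mapping lets
#' files with different column names be read without rewriting them.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the canonical names
#'   `time`, `strain`, `gyro_ap`, `switch` to the file's column names.
#'   Alternatively `schema` may carry a numeric `sample_rate_hz` entry (as a
#'   list) for files without a time column.
#' @return A [cane_recording()].
#' @export
read_recording <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- list(time = "time_s", strain = "strain", gyro_ap = "gyro_ap",
             switch = "switch")
  if (!is.null(schema)) sc[names(schema)] <- as.list(schema)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("failed to parse ", path, ": ",
                               conditionMessage(w), call. = FALSE))
  for (nm in c("strain", "gyro_ap")) {
    if (!sc[[nm]] %in% names(df))
      stop("missing required column '", sc[[nm]], "' (", nm, ") in ", path)
  }
  has_time <- is.character(sc$time) && sc$time %in% names(df)
  if (has_time) {
    t <- as.numeric(df[[sc$time]])
    dts <- diff(t)
    if (length(dts) < 1 || any(dts <= 0))
      stop("time column in ", path, " is not strictly increasing")
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > 1e-6 * dt))
      stop("time column in ", path, " is not uniformly sampled")
    fs <- 1 / dt
  } else if (!is.null(sc$sample_rate_hz)) {
    fs <- as.numeric(sc$sample_rate_hz)
    t <- NULL
  } else {
    stop("no time column '", sc$time, "' in ", path,
         " and no sample_rate_hz supplied in schema")
  }
  sw <- if (is.character(sc$switch) && sc$switch %in% names(df))
    df[[sc$switch]] else NULL
  cane_recording(strain = df[[sc$strain]], gyro_ap = df[[sc$gyro_ap]],
                 sample_rate_hz = fs, switch = sw, t = t)
}

#' Write a cane recording to delimited text
#'
#' Channels are written with enough digits that a read/write round trip is
#' lossless to at least 1e-9 relative precision.
#'
#' @param rec A [cane_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "cane_recording"))
  df <- data.frame(time_s = rec$t, strain = rec$strain,
                   gyro_ap = rec$gyro_ap)
  if (!is.null(rec$switch)) df$switch <- rec$switch
  # format() at 15 significant digits keeps the round trip below 1e-9
  for (nm in c("time_s", "strain", "gyro_ap"))
    df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read/write annotation sets (reference gait cycles) as JSON
#'
#' The on-disk format is a JSON object
#' `{"provenance": ..., "cycles": [{"ic_s", "tc_s", "ps_s", "ec_s",
#' "valid", "similarity", "terrain"}, ...]}`. Event times survive a round
#' trip to better than 1e-6 s. Files whose cycles are out of IC order, or
#' whose valid cycles violate event ordering, are rejected.
#'
#' @param path JSON file path.
#' @param sample_rate_hz Sample rate used to derive event sample indices.
#' @return [read_annotations()] returns an [annotation_set()];
#'   [write_annotations()] returns `path` invisibly.
#' @export
read_annotations <- function(path, sample_rate_hz = 231) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cyc <- obj$cycles
  if (is.null(cyc) || length(cyc) == 0 ||
      (is.data.frame(cyc) && nrow(cyc) == 0))
    return(annotation_set(list(), provenance = obj$provenance %||% "simulator"))
  if (!is.data.frame(cyc)) stop("malformed annotation file: ", path)
  ics <- cyc$ic_s
  if (is.unsorted(ics[!is.na(ics)]))
    stop("annotation cycles are not ordered by IC time in ", path)
  cycles <- lapply(seq_len(nrow(cyc)), function(i) {
    gait_cycle(ic = cyc$ic_s[i], tc = cyc$tc_s[i], ps = cyc$ps_s[i],
               ec = cyc$ec_s[i], valid = cyc$valid[i],
               similarity = if ("similarity" %in% names(cyc))
                 cyc$similarity[i] else NA_real_,
               terrain = if ("terrain" %in% names(cyc))
                 cyc$terrain[i] else NA_character_,
               sample_rate_hz = sample_rate_hz)
  })
  annotation_set(cycles, provenance = obj$provenance %||% "simulator")
}

#' @rdname read_annotations
#' @param set An [annotation_set()] (or plain list of [gait_cycle()]).
#' @export
write_annotations <- function(set, path) {
  if (!inherits(set, "annotation_set"))
    set <- annotation_set(set)
  obj <- list(provenance = set$provenance, cycles = cycles_df(set))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Read/write stride templates as JSON
#'
#' Format: `{"sample_rate_hz": ..., "values": [...], "source": ...}`.
#'
#' @param path JSON file path.
#' @return [read_template()] returns a [stride_template()].
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  stride_template(values = obj$values,
                  sample_rate_hz = obj$sample_rate_hz,
                  source = obj$source %||% "unspecified")
}

#' @rdname read_template
#' @param template A [stride_template()].
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "stride_template"))
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
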