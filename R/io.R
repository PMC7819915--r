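# Schema-validated readers and writers for the package's CSV dialects and
# JSON result files. All tables are comma-separated with a header row,
# UTF-8, "." decimal; units are fixed: temperatures in degrees C, energy
# in W, mass in g, flow in ml min^-1 STP, water loss in mg min^-1.

.SCHEMAS <- list(
  steady_state = c(bird_id = "character", group = "character",
                   acclimation = "character", ta_c = "numeric",
                   mb_g = "numeric", vo2_mlmin = "numeric",
                   vco2_mlmin = "numeric", ewl_mgmin = "numeric",
                   mr_w = "numeric", ehl_w = "numeric", tb_c = "numeric"),
  raw_trace = c(time_s = "numeric", channel = "character",
                feo2 = "numeric", feco2 = "numeric",
                ph2o_kpa = "numeric", flow_mlmin = "numeric",
                ta_c = "numeric"),
  mask_session = c(bird_id = "character", ta_set_c = "numeric",
                   line = "character", feo2 = "numeric",
                   feco2 = "numeric", ph2o_kpa = "numeric",
                   flow_mlmin = "numeric", bp_kpa = "numeric"))

.read_table <- function(path, schema_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  schema <- .SCHEMAS[[schema_name]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no data rows in ", path)
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop(schema_name, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      if (!is.numeric(df[[col]])) {
        suppressWarnings(v <- as.numeric(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]]) & df[[col]] != ""))
          stop("column '", col, "' in ", path, " is not numeric")
        df[[col]] <- v
      }
    } else df[[col]] <- as.character(df[[col]])
  }
  df
}

#' Read a steady-state physiological table
#'
#' Columns: `bird_id`, `group`, `acclimation`, `ta_c`, `mb_g`,
#' `vo2_mlmin`, `vco2_mlmin`, `ewl_mgmin`, `mr_w`, `ehl_w`, `tb_c`.
#' Missing values are empty fields. Any missing or mistyped column is an
#' error naming the column.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_steady_state <- function(path) .read_table(path, "steady_state")

#' Read a raw multiplexed trace
#'
#' Columns: `time_s`, `channel` (`"REF"` marks reference air), `feo2`,
#' `feco2`, `ph2o_kpa`, `flow_mlmin`, `ta_c`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_raw_trace <- function(path) {
  df <- .read_table(path, "raw_trace")
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing in ", path)
  df
}

#' Read a two-line mask-session table
#'
#' Columns: `bird_id`, `ta_set_c`, `line` (`"mask"` or `"chamber"`),
#' `feo2`, `feco2`, `ph2o_kpa`, `flow_mlmin`, `bp_kpa`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_mask_session <- function(path) {
  df <- .read_table(path, "mask_session")
  bad <- setdiff(unique(df$line), c("mask", "chamber"))
  if (length(bad))
    stop("unknown line label(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  df
}

#' Write a steady-state table
#' @param df a steady-state data frame.
#' @param path output CSV path.
#' @param force overwrite an existing file.
#' @export
write_steady_state <- function(df, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  utils::write.csv(df[, names(.SCHEMAS$steady_state)], path,
                   row.names = FALSE)
  invisible(path)
}

# strip non-serializable parts of fitted objects into plain lists
.as_plain <- function(x) {
  if (inherits(x, "segmented_fit"))
    x <- x[c("breakpoints", "breakpoint_se", "slopes", "intercepts",
             "constraints", "n_breakpoints", "sse", "r2", "residual_sd",
             "n_obs", "x_range")]
  if (inherits(x, "thermoreg_profile")) x <- unclass(x)
  if (inherits(x, "repeatability")) x <- unclass(x)
  x
}

#' Write an analysis result to JSON
#'
#' Serializes a fitted object (segmented fit, thermoregulatory profile,
#' repeatability result, summary table, or plain list) with a package
#' version stamp. Non-finite values (e.g. an SE with the bootstrap
#' disabled) become JSON `null`.
#'
#' @param x object to serialize.
#' @param path output path; refuses to overwrite unless `force`.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  payload <- list(
    tnz_version = as.character(utils::packageVersion("tnz")),
    result = .as_plain(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON result written by [write_results_json()]
#'
#' @param path JSON file path.
#' @return The `result` payload as a list (version stamp in attribute
#'   `tnz_version`). `null` fields come back as `NULL`/`NA`.
#' @export
read_results_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- payload$result
  attr(out, "tnz_version") <- payload$tnz_version
  out
}
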