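#' Per-frame, per-subunit scalar series
#'
#' @param times Frame times, ns.
#' @param subunit_ids Character vector of subunit labels.
#' @param values Numeric matrix, frames x subunits. `NA` marks flagged
#'   missing values (degenerate geometry); all other entries must be finite.
#' @param unit Unit string (`"deg"`, `"A"`, `"A^2"`, ...).
#' @param metric Name of the descriptor the series holds.
#' @return Object of class `"scalar_series"`.
#' @export
scalar_series <- function(times, subunit_ids, values, unit = "",
                          metric = "") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(times),
            ncol(values) == length(subunit_ids))
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-finite values must be flagged NA")
  colnames(values) <- subunit_ids
  structure(list(times = as.numeric(times),
                 subunit_ids = as.character(subunit_ids),
                 values = values, unit = unit, metric = metric),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %s [%s]: %d frames x %d subunits, mean %.3f\n",
              x$metric, x$unit, nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Write a series or profile to CSV or JSON
#'
#' CSV headers carry units (e.g. `A.deg` for subunit A of an angle series);
#' JSON keeps the object's arrays verbatim. Both round-trip through
#' [read_table].
#'
#' @param x A [scalar_series], `"axial_profile"`, `"pore_profile"`,
#'   [hydropathy_profile] or plain data frame.
#' @param path Output file.
#' @param format `"csv"` or `"json"` (default: by file extension).
#' @export
write_table <- function(x, path, format = NULL) UseMethod("write_table")

#' @export
write_table.scalar_series <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  if (format == "csv") {
    df <- data.frame(time_ns = x$times, x$values, check.names = FALSE)
    names(df)[-1] <- paste0(x$subunit_ids, ".", x$unit)
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(metric = x$metric, unit = x$unit, times_ns = x$times,
           subunit_ids = x$subunit_ids,
           values = unclass(as.data.frame(x$values))),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @export
write_table.axial_profile <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  if (format == "csv") {
    mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
    df <- data.frame(z_mid.A = mid, mean.waters = x$mean,
                     sd_of_mean.waters = x$sd_of_mean, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(bin_edges_A = x$bin_edges, mean = x$mean,
           sd_of_mean = x$sd_of_mean,
           per_replica_counts = apply(x$per_replica_counts, 1, identity,
                                      simplify = FALSE),
           cylinder_radius_A = x$cylinder_radius),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @export
write_table.pore_profile <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  if (format == "csv") {
    df <- data.frame(z.A = x$z, radius.A = x$radius, check.names = FALSE)
    if (!is.null(x$sd_of_mean)) df$sd_of_mean.A <- x$sd_of_mean
    write.csv(df, path, row.names = FALSE)
  } else {
    out <- list(z_A = x$z, radius_A = x$radius)
    if (!is.null(x$sd_of_mean)) out$sd_of_mean_A <- x$sd_of_mean
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @export
write_table.hydropathy_profile <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  if (format == "csv") {
    write.csv(data.frame(position = x$positions, score = x$score),
              path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(positions = x$positions, score = x$score,
                              window = x$window, scale = x$scale_name),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @export
write_table.data.frame <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  if (format == "csv") write.csv(x, path, row.names = FALSE)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            na = "null")
  invisible(path)
}

resolved_format <- function(path, format) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  match.arg(format, c("csv", "json"))
}

#' Read back a table written by [write_table]
#'
#' @param path File written by [write_table].
#' @param format `"csv"` or `"json"` (default: by extension).
#' @return A data frame (CSV) or list (JSON).
#' @export
read_table <- function(path, format = NULL) {
  format <- resolved_format(path, format)
  if (format == "csv") read.csv(path, check.names = FALSE)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
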