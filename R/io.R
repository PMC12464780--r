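# Text I/O for the three data families. All formats are plain text:
# CSV isotherms with '#'-prefixed metadata, xvg-dialect stress profiles
# (the comment/column text files written by common MD post-processing),
# and coordinate tables with a box header line.

#' Read / write isotherm CSV files
#'
#' The file format is a CSV with header `area_A2,pressure_mN_m` preceded by
#' optional metadata comment lines `# key: value` (keys `temperature_K`,
#' `x_cer`, `label`).
#'
#' @param path file path.
#' @return `read_isotherm_csv`: an [isotherm()].
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read isotherm file: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("area_A2", "pressure_mN_m") %in% names(df))) {
    stop("isotherm CSV must have columns area_A2, pressure_mN_m: ", path)
  }
  comp <- if (!is.null(meta$x_cer)) mixture_spec(as.numeric(meta$x_cer)) else NULL
  isotherm(df$area_A2, df$pressure_mN_m,
           temperature = as.numeric(meta$temperature_K %||% 298.15),
           composition = comp, label = meta$label %||% "")
}

#' @rdname read_isotherm_csv
#' @param iso an [isotherm()] to write.
#' @export
write_isotherm_csv <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K: %.6g", attr(iso, "temperature")), con)
  comp <- attr(iso, "composition")
  if (!is.null(comp)) {
    writeLines(sprintf("# x_cer: %.12g", comp$fraction_CER), con)
  }
  if (nzchar(attr(iso, "label"))) {
    writeLines(sprintf("# label: %s", attr(iso, "label")), con)
  }
  utils::write.csv(data.frame(area_A2 = iso$area, pressure_mN_m = iso$pressure),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write stress profiles in xvg-dialect text
#'
#' Whitespace-separated columns z (nm), Pxx, Pyy, Pzz (bar); lines starting
#' with `#` or `@` are comments, as in the text files written by common MD
#' post-processing tools. Column positions are configurable.
#'
#' @param path file path.
#' @param columns 1-based column indices of z, Pxx, Pyy, Pzz.
#' @return `read_stress_xvg`: a [stress_profile()].
#' @export
read_stress_xvg <- function(path, columns = 1:4) {
  if (!file.exists(path)) stop("cannot read stress file: ", path)
  lines <- readLines(path)
  data_lines <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = data_lines)
  if (ncol(df) < max(columns)) {
    stop("stress file has ", ncol(df), " columns; need index ", max(columns))
  }
  stress_profile(df[[columns[1]]], df[[columns[2]]],
                 df[[columns[3]]], df[[columns[4]]])
}

#' @rdname read_stress_xvg
#' @param stress a [stress_profile()] to write.
#' @export
write_stress_xvg <- function(stress, path) {
  stopifnot(inherits(stress, "stress_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# stress-tensor profile along the membrane normal",
               "@ xaxis label \"z (nm)\"",
               "@ yaxis label \"P (bar)\"",
               "# columns: z_nm Pxx_bar Pyy_bar Pzz_bar"), con)
  writeLines(sprintf("%.17g %.17g %.17g %.17g",
                     stress$z, stress$Pxx, stress$Pyy, stress$Pzz), con)
  invisible(path)
}

#' Read / write lipid coordinate frames as CSV
#'
#' Columns `x_nm,y_nm,z_nm,leaflet` with a leading box header comment line
#' `# box_nm: Lx Ly` (and optionally `# time_ps: t`).
#'
#' @param path file path.
#' @return `read_frame_csv`: a [lipid_frame()].
#' @export
read_frame_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read frame file: ", path)
  lines <- readLines(path)
  box_line <- grep("^#\\s*box_nm\\s*:", lines, value = TRUE)
  if (length(box_line) != 1L) stop("frame CSV needs one '# box_nm: Lx Ly' header line")
  box <- as.numeric(strsplit(trimws(sub("^#\\s*box_nm\\s*:", "", box_line)),
                             "\\s+")[[1]])
  time_line <- grep("^#\\s*time_ps\\s*:", lines, value = TRUE)
  tm <- if (length(time_line) == 1L) {
    as.numeric(trimws(sub("^#\\s*time_ps\\s*:", "", time_line)))
  } else NA_real_
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("x_nm", "y_nm", "z_nm", "leaflet") %in% names(df))) {
    stop("frame CSV must have columns x_nm, y_nm, z_nm, leaflet")
  }
  lipid_frame(cbind(df$x_nm, df$y_nm, df$z_nm), df$leaflet, box, time = tm)
}

#' @rdname read_frame_csv
#' @param frame a [lipid_frame()] to write.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "lipid_frame"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box_nm: %.10g %.10g", frame$box[1], frame$box[2]), con)
  if (!is.na(frame$time)) writeLines(sprintf("# time_ps: %.10g", frame$time), con)
  utils::write.csv(data.frame(x_nm = frame$positions[, 1],
                              y_nm = frame$positions[, 2],
                              z_nm = frame$positions[, 3],
                              leaflet = frame$leaflet),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
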