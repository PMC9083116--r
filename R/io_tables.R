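## Plain-text persistence: order-parameter series as commented CSV,
## free-energy grids with a commented header, DCCMs as labelled CSV.
## Values are written with 17 significant digits so a read-back reproduces
## them exactly.

#' Write an order-parameter series as CSV
#'
#' Columns `time_ps`, `value`; name, units and temperature are recorded in
#' `#`-comment header lines.
#'
#' @param series an [op_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "op_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name: %s", series$name),
               sprintf("# units: %s", series$units),
               sprintf("# temperature_K: %s", .fmt_num(series$temperature)),
               "time_ps,value"), con)
  writeLines(paste(.fmt_num(series$times), .fmt_num(series$values),
                   sep = ","), con)
  invisible(path)
}

#' Read an order-parameter series written by [write_series_csv()]
#' @param path CSV file.
#' @return an [op_series()].
#' @export
read_series_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NA_character_
  }
  body <- read.csv(text = lines[!grepl("^#", lines)])
  op_series(field("name") %||% "series", field("units") %||% "",
            body$value, body$time_ps,
            temperature = suppressWarnings(as.numeric(field("temperature_K"))))
}

#' Write a free-energy grid as plain text
#'
#' `#`-comment header lines carry axis names, bin edges, RT, temperature
#' and frame count; the body is the row-major F matrix (one line per x
#' bin), masked bins written as `NA`.
#'
#' @param grid a [fel_2d()] grid.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "fel_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# x_name: %s", grid$x_name),
    sprintf("# y_name: %s", grid$y_name),
    sprintf("# x_edges: %s", paste(.fmt_num(grid$x_edges), collapse = " ")),
    sprintf("# y_edges: %s", paste(.fmt_num(grid$y_edges), collapse = " ")),
    sprintf("# rt_kcal_mol: %s", .fmt_num(grid$rt)),
    sprintf("# temperature_K: %s", .fmt_num(grid$temperature)),
    sprintf("# n_frames: %d", grid$n_frames),
    "# F matrix, kcal/mol: one line per x bin, columns are y bins, NA = unvisited"
  ), con)
  for (i in seq_len(nrow(grid$F))) {
    writeLines(paste(.fmt_num(grid$F[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a free-energy grid written by [write_fel_grid()]
#' @param path grid file.
#' @return a `fel_grid` object.
#' @export
read_fel_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) sub(paste0("^# ", key, ": "), "",
                             grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1])
  x_edges <- as.numeric(strsplit(field("x_edges"), " ")[[1]])
  y_edges <- as.numeric(strsplit(field("y_edges"), " ")[[1]])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  F <- do.call(rbind, lapply(body, function(l) {
    tok <- strsplit(l, " ")[[1]]
    v <- rep(NA_real_, length(tok))
    ok <- tok != "NA"
    v[ok] <- as.numeric(tok[ok])
    v
  }))
  structure(list(x_name = field("x_name"), y_name = field("y_name"),
                 x_edges = x_edges, y_edges = y_edges, F = F,
                 mask = is.na(F),
                 rt = as.numeric(field("rt_kcal_mol")),
                 temperature = as.numeric(field("temperature_K")),
                 n_frames = as.integer(field("n_frames"))),
            class = "fel_grid")
}

#' Write a cross-correlation matrix as labelled CSV
#'
#' @param dccm a [dccm_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dccm_csv <- function(dccm, path) {
  stopifnot(inherits(dccm, "dccm_matrix"))
  lab <- paste0("res", dccm$res_index)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# window: %d %d", dccm$window[1], dccm$window[2]),
               paste(c("residue", lab), collapse = ",")), con)
  for (i in seq_len(nrow(dccm$values))) {
    writeLines(paste(c(lab[i], .fmt_num(dccm$values[i, ])), collapse = ","),
               con)
  }
  invisible(path)
}

#' Read a cross-correlation matrix written by [write_dccm_csv()]
#' @param path CSV file.
#' @return a `dccm_matrix` object.
#' @export
read_dccm_csv <- function(path) {
  lines <- readLines(path)
  w <- as.integer(strsplit(sub("^# window: ", "",
                               grep("^# window:", lines, value = TRUE)[1]),
                           " ")[[1]])
  body <- read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  vals <- as.matrix(body[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  structure(list(values = vals, window = w,
                 res_index = as.integer(sub("^res", "", body$residue)),
                 aligned = NA),
            class = "dccm_matrix")
}

#' Write a secondary-structure timeline as CSV
#'
#' One row per frame, one single-character column per residue.
#'
#' @param timeline an [ss_timeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ss_timeline_csv <- function(timeline, path) {
  stopifnot(inherits(timeline, "ss_timeline"))
  codes <- unclass(timeline)
  df <- data.frame(time_ps = attr(timeline, "times"), codes,
                   check.names = FALSE)
  names(df) <- c("time_ps", paste0("res", seq_len(ncol(codes))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
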