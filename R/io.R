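#' Write a velocity burst to CSV
#'
#' Columns `t,u,v,w` (SI units: seconds and m s^-1), header row, no row
#' names. Metadata lines (elevation, location, seed) are written as `#`
#' comments above the header.
#'
#' @param burst A `velocity_burst`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_burst_csv <- function(burst, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# canopyflow velocity burst: sample_rate_hz=%g elevation_cmab=%s location=%s profile_id=%s",
                     burst$sample_rate, format(burst$elevation),
                     format(burst$location), format(burst$profile_id)), con)
  writeLines("t,u,v,w", con)
  writeLines(sprintf("%.10g,%.10g,%.10g,%.10g",
                     burst$t, burst$u, burst$v, burst$w), con)
  invisible(path)
}

#' Read a velocity burst from CSV
#'
#' Expects columns `t,u,v,w` (header row; `#` comment lines allowed). The
#' sample rate is inferred from `t` and validated: timestamps must be uniform
#' to within `tol` of the step.
#'
#' @param path CSV path.
#' @param elevation,location,profile_id Optional metadata overrides.
#' @param tol Relative tolerance on timestamp uniformity.
#' @return A `velocity_burst`.
#' @export
read_burst_csv <- function(path, elevation = NA, location = NA,
                           profile_id = NA, tol = 1e-6) {
  d <- read.csv(path, comment.char = "#")
  miss <- setdiff(c("t", "u", "v", "w"), names(d))
  if (length(miss)) stop("burst CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  dt <- diff(d$t)
  if (length(dt) < 1 || any(dt <= 0)) stop("t must be strictly increasing")
  step <- median(dt)
  if (any(abs(dt - step) > tol * step))
    stop("non-uniform timestamps: gap or jitter in t beyond tolerance")
  structure(list(t = d$t, u = d$u, v = d$v, w = d$w,
                 sample_rate = 1 / step, elevation = elevation,
                 location = location, profile_id = profile_id, truth = NULL),
            class = "velocity_burst")
}

normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("–|—", "-", x)          # en/em dash -> hyphen
  gsub("[ ]*-[ ]*", "-", gsub("\\s+", " ", x))
}

#' Read a per-minute count table from delimited text
#'
#' Mapping-driven reader for deposited-data-style layouts: `column_map` names
#' the file's columns for each required field. Position and tide labels are
#' normalised case-insensitively (en-dashes folded to hyphens) and validated
#' against the allowed sets; rows violating `watercolumn_count <= abundance`
#' are rejected with their row numbers.
#'
#' @param path Delimited text path.
#' @param column_map Named character vector mapping canonical fields
#'   (`asu_id`, `camera_position`, `tide`, `minute_index`, `abundance`,
#'   `watercolumn_count`, optionally `velocity`, `visibility_ok`) to file
#'   column names. `NULL` assumes canonical names.
#' @param sep Field separator (default `","`).
#' @return A validated `count_table`.
#' @export
read_count_table <- function(path, column_map = NULL, sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  comment.char = "#")
  need <- c("asu_id", "camera_position", "tide", "minute_index",
            "abundance", "watercolumn_count")
  opt <- c("velocity", "visibility_ok")
  if (is.null(column_map)) column_map <- setNames(need, need)
  miss <- setdiff(need, names(column_map))
  if (length(miss)) stop("column_map missing field(s): ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent)) stop("file lacks mapped column(s): ",
                           paste(absent, collapse = ", "))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    lapply(column_map[intersect(c(need, opt),
                                                names(column_map))],
                           function(cn) raw[[cn]]))
  names(out) <- intersect(c(need, opt), names(column_map))
  pos <- normalize_label(out$camera_position)
  bad_pos <- setdiff(unique(pos), camera_positions)
  if (length(bad_pos))
    stop("unknown camera_position label(s): ",
         paste(bad_pos, collapse = ", "), "; allowed: ",
         paste(camera_positions, collapse = ", "))
  out$camera_position <- factor(pos, levels = camera_positions)
  tide <- normalize_label(out$tide)
  bad_tide <- setdiff(unique(tide), c("flood", "ebb"))
  if (length(bad_tide))
    stop("unknown tide label(s): ", paste(bad_tide, collapse = ", "),
         "; allowed: flood, ebb")
  out$tide <- factor(tide, levels = c("ebb", "flood"))
  if (is.null(out$visibility_ok)) out$visibility_ok <- TRUE
  class(out) <- c("count_table", "data.frame")
  validate_count_table(out)
  out
}
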