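# Two-column delimited text reader shared by trace and distribution files:
# whitespace- or comma-delimited, '#' comments.
read_two_column <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(lines, "[,[:space:]]+")
  m <- vapply(parts, function(p) {
    p <- p[nzchar(p)]
    if (length(p) < 2L) stop("malformed row in ", path, call. = FALSE)
    as.numeric(p[1:2])
  }, numeric(2))
  if (any(!is.finite(m))) stop("non-numeric data in ", path, call. = FALSE)
  list(x = m[1, ], y = m[2, ])
}

#' Read a DEER trace from delimited text
#'
#' Two columns (time in us, normalized intensity), whitespace- or
#' comma-delimited, `#` comments. A JSON sidecar `<path>.json` (or
#' `<stem>.json`), when present, supplies the metadata (`pair`, `pH`,
#' `environment`, `noise_sigma`).
#'
#' @param path Trace file path.
#' @param sidecar Optional explicit sidecar path.
#' @return A [dipolar_trace()].
#' @export
read_trace <- function(path, sidecar = NULL) {
  xy <- read_two_column(path)
  meta <- list()
  cands <- c(sidecar, paste0(path, ".json"),
             paste0(tools::file_path_sans_ext(path), ".json"))
  for (s in cands) {
    if (!is.null(s) && file.exists(s)) {
      meta <- jsonlite::read_json(s, simplifyVector = TRUE)
      break
    }
  }
  dipolar_trace(xy$x, xy$y, meta = as.list(meta))
}

#' Write a DEER trace (and metadata sidecar) to text
#'
#' @param trace A [dipolar_trace()].
#' @param path Output path; metadata is written to `<path>.json` when
#'   present.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is_dipolar_trace(trace))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# t_us V", con)
  writeLines(sprintf("%.10g %.10g", trace$t, trace$V), con)
  if (length(trace$meta))
    jsonlite::write_json(trace$meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a distance distribution from two-column text (r_nm, P)
#'
#' @param path File path.
#' @return A [distance_distribution()] on the file's own grid.
#' @export
read_distribution <- function(path) {
  xy <- read_two_column(path)
  r <- xy$x
  step <- stats::median(diff(r))
  grid <- structure(list(r_min = min(r), r_max = max(r), step = step,
                         values = r), class = "distance_grid")
  distance_distribution(grid, density = xy$y)
}

#' Write a distance distribution as two-column text
#'
#' @param P A [distance_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(P, path) {
  stopifnot(is_distance_distribution(P))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# r_nm P", con)
  writeLines(sprintf("%.10g %.10g", P$grid$values, P$density), con)
  invisible(path)
}

#' Read a titration table (pH, f, [sigma2, direction])
#'
#' @param path Delimited text path; 2-4 columns, `#` comments.
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("pH", "f", "sigma2", "direction")[1:
                             max(utils::count.fields(path, comment.char = "#"),
                                 na.rm = TRUE)],
                           fill = TRUE)
  direction <- if ("direction" %in% names(tab))
    unique(stats::na.omit(tab$direction))[1] else "auto"
  titration_series(tab$pH, tab$f,
                   sigma2 = if ("sigma2" %in% names(tab)) tab$sigma2 else NULL,
                   direction = direction)
}

#' Write a titration table
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pH f sigma2 direction", con)
  writeLines(sprintf("%.6g %.8g %.8g %s", series$pH, series$f, series$sigma2,
                     attr(series, "direction")), con)
  invisible(path)
}

#' Write a structure as a (multi-model) PDB file
#'
#' @param structure A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(is_structure_model(structure))
  at <- structure$atoms
  bio3d::write.pdb(file = path, xyz = structure$xyz,
                   resno = at$resno, resid = at$resid,
                   elety = trimws(at$elety), chain = at$chain)
  invisible(path)
}

#' Serialize a global fit report to JSON
#'
#' Writes all fitted parameters, the per-trace table, the model-selection
#' criterion table (when present) and optional confidence bands.
#'
#' @param fit A `deer_global_fit`.
#' @param path Output JSON path.
#' @param bands Optional result of [confidence_band()].
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, bands = NULL) {
  stopifnot(inherits(fit, "deer_global_fit"))
  rep <- list(
    n_components = fit$n_components,
    components = fit$components,
    populations = as.data.frame(fit$populations),
    populations_2sigma = as.data.frame(fit$populations_2sigma),
    per_trace = fit$per_trace,
    objective = fit$objective,
    criterion = fit$criterion %||% NA,
    criterion_table = fit$criterion_table %||% NULL,
    converged = fit$converged)
  if (!is.null(bands)) rep$bands <- bands
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
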