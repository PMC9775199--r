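# Plain-text readers/writers for the shared table formats, and structured
# configuration loading. Numeric tables use full-precision scientific
# notation with mandatory, versioned column headers so that write-then-read
# round trips reproduce values exactly.

TRAJ_HEADER <- "# uscphmd trajectory v1"
PROFILE_HEADER <- "# uscphmd profile v1"
WINDOWS_HEADER <- "# uscphmd windows v1"

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_numeric_table <- function(df, path, header, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  lines <- header
  if (length(meta)) lines <- c(lines, paste0("# ", meta))
  writeLines(c(lines, paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    body <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) fmt_num(col)
      else as.character(col)
    }, character(nrow(df)))
    body <- matrix(body, nrow = nrow(df))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

read_numeric_table <- function(path, expect_header = NULL) {
  lines <- readLines(path)
  if (!is.null(expect_header) &&
      (!length(lines) || lines[1] != expect_header))
    stop(sprintf("%s: not a '%s' file", path, expect_header), call. = FALSE)
  is_meta <- startsWith(lines, "#")
  body_idx <- which(!is_meta)
  if (!length(body_idx)) stop(sprintf("%s: no data", path), call. = FALSE)
  header_line <- body_idx[1]
  cols <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1]]
  data_idx <- body_idx[-1]
  if (length(data_idx)) {
    nfield <- vapply(strsplit(lines[data_idx], "\t", fixed = TRUE),
                     length, 0L)
    bad <- which(nfield != length(cols))
    if (length(bad))
      stop(sprintf("%s: line %d has %d columns, expected %d",
                   path, data_idx[bad[1]], nfield[bad[1]], length(cols)),
           call. = FALSE)
  }
  df <- read.table(text = lines[data_idx], sep = "\t",
                   col.names = cols, stringsAsFactors = FALSE)
  attr(df, "meta") <- sub("^# ?", "", lines[is_meta][-1])
  df
}

#' Write or read a constant-pH trajectory table
#'
#' Whitespace-delimited plain text with a versioned header: time (ps),
#' z (nm), one integer state column per site, total charge (e) and
#' instantaneous bias energy (kJ/mol). The pH and equilibration fraction
#' are stored as metadata lines and restored on read.
#'
#' @param traj A `cphmd_traj` from [run_cphmd()].
#' @param path File path.
#' @return `read_trajectory()` returns a `cphmd_traj`-compatible data
#'   frame.
#' @export
write_trajectory <- function(traj, path) {
  meta <- c(sprintf("pH=%s", fmt_num(attr(traj, "pH") %||% NA_real_)),
            sprintf("equilibration_fraction=%s",
                    fmt_num(attr(traj, "equilibration_fraction") %||% 0)))
  write_numeric_table(as.data.frame(traj), path, TRAJ_HEADER, meta)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read_numeric_table(path, TRAJ_HEADER)
  meta <- attr(df, "meta")
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  scol <- grep("^s_", names(df), value = TRUE)
  for (col in setdiff(names(df), scol)) df[[col]] <- as.numeric(df[[col]])
  for (col in scol) df[[col]] <- as.integer(df[[col]])
  attr(df, "pH") <- as.numeric(vals["pH"])
  attr(df, "equilibration_fraction") <-
    as.numeric(vals["equilibration_fraction"])
  attr(df, "site_ids") <- sub("^s_", "", scol)
  class(df) <- c("cphmd_traj", "data.frame")
  df
}

#' Write or read umbrella-window metadata
#'
#' Plain-text window table (center, force constant, segment, sample-file
#' path) in the style of common WHAM input conventions. Writing also
#' writes each window's trajectory next to the metadata file; reading
#' restores the sampled window list.
#'
#' @param windows List of [umbrella_window()] objects with samples.
#' @param path Metadata file path; sample tables go to
#'   `<path-dir>/window_<i>.traj`.
#' @return `read_window_metadata()` returns the window list.
#' @export
write_window_metadata <- function(windows, path) {
  dir <- dirname(path)
  files <- sprintf("window_%03d.traj", seq_along(windows))
  for (i in seq_along(windows)) {
    if (is.null(windows[[i]]$samples))
      stop("all windows must carry samples", call. = FALSE)
    write_trajectory(windows[[i]]$samples, file.path(dir, files[i]))
  }
  df <- windows_table(windows)
  df$file <- files
  df$n_samples <- NULL
  write_numeric_table(df, path, WINDOWS_HEADER)
}

#' @rdname write_window_metadata
#' @export
read_window_metadata <- function(path) {
  df <- read_numeric_table(path, WINDOWS_HEADER)
  dir <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    f <- file.path(dir, df$file[i])
    if (!file.exists(f))
      stop(sprintf("sample file '%s' not found", f), call. = FALSE)
    umbrella_window(df$center[i], df$k[i], df$segment[i],
                    samples = read_trajectory(f))
  })
}

#' Write or read a profile table
#'
#' Generic (z, value, error, ...) tables used for PMFs and re-weighted
#' observable profiles.
#'
#' @param profile A data frame (e.g. from [wham()] or
#'   [reweight_observable()]).
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  write_numeric_table(as.data.frame(profile), path, PROFILE_HEADER)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) read_numeric_table(path, PROFILE_HEADER)

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration describing one of the packaged experiment
#' types (`bulk_titration`, `channel_scan`, `two_segment_scan`) and
#' validates the schema, naming the offending field on failure.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @seealso [write_fixture_configs()], [run_pipeline()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

required_field <- function(cfg, field, type = "numeric") {
  if (is.null(cfg[[field]]))
    stop(sprintf("config field '%s' is missing", field), call. = FALSE)
  ok <- switch(type,
               numeric = is.numeric(cfg[[field]]),
               character = is.character(cfg[[field]]),
               list = is.list(cfg[[field]]))
  if (!ok)
    stop(sprintf("config field '%s' must be %s", field, type),
         call. = FALSE)
  invisible(cfg[[field]])
}

validate_config <- function(cfg) {
  kinds <- c("bulk_titration", "channel_scan", "two_segment_scan")
  experiment <- required_field(cfg, "experiment", "character")
  if (!experiment %in% kinds)
    stop(sprintf("config field 'experiment' must be one of: %s",
                 paste(kinds, collapse = ", ")), call. = FALSE)
  switch(experiment,
    bulk_titration = {
      required_field(cfg, "pk_int")
      required_field(cfg, "pH_values")
      if (length(cfg$pH_values) < 3)
        stop("config field 'pH_values' needs at least 3 values",
             call. = FALSE)
    },
    channel_scan = {
      required_field(cfg, "field", "list")
      required_field(cfg, "substrate_pk")
      required_field(cfg, "pH")
    },
    two_segment_scan = {
      required_field(cfg, "fieldA", "list")
      required_field(cfg, "fieldB", "list")
      required_field(cfg, "transition_z")
      required_field(cfg, "substrate_pk")
      required_field(cfg, "pH")
    })
  invisible(cfg)
}

field_from_config <- function(lst) do.call(channel_field, lst)

schedule_from_config <- function(cfg) {
  args <- cfg$schedule %||% list()
  do.call(cphmd_schedule, args)
}

windows_from_config <- function(cfg) {
  args <- cfg$windows %||% list()
  if (!is.null(args$range)) args$range <- as.numeric(args$range)
  if (!is.null(args$interior)) args$interior <- as.numeric(args$interior)
  do.call(window_schedule, args)
}

#' Emit complete fixture configurations
#'
#' Writes ready-to-run YAML configurations for the three packaged
#' experiment types into a directory.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fixture_configs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfgs <- list(
    bulk_titration = list(
      experiment = "bulk_titration",
      pk_int = 6.5,
      neighbor_charges = list(q = list(), distance = list()),
      pH_values = c(4, 5, 6, 7, 8, 9),
      replicates = 3L,
      schedule = list(total_steps = 2e4)),
    channel_scan = list(
      experiment = "channel_scan",
      substrate_pk = 6.5, pH = 7,
      field = list(cation_depth = 2, cation_center = -1, cation_width = 0.6,
                   desolv_height = 2, desolv_center = 1, desolv_width = 0.6),
      windows = list(range = c(-4, 4), interior = c(-2, 2),
                     interior_spacing = 0.1, exterior_spacing = 0.2,
                     interior_k = 1000, exterior_k = 500),
      steps_per_window = 4e4, bin_width = 0.05),
    two_segment_scan = list(
      experiment = "two_segment_scan",
      substrate_pk = 6.5, pH = 7, transition_z = 0.2,
      fieldA = list(cation_depth = 2, cation_center = -1,
                    cation_width = 0.6),
      fieldB = list(cation_depth = 3, cation_center = 1,
                    cation_width = 0.6),
      windows = list(range = c(-4, 4), interior = c(-2, 2),
                     interior_spacing = 0.1, exterior_spacing = 0.2,
                     interior_k = 1000, exterior_k = 500),
      steps_per_window = 4e4, bin_width = 0.05))
  paths <- file.path(dir, paste0(names(cfgs), ".yaml"))
  for (i in seq_along(cfgs)) yaml::write_yaml(cfgs[[i]], paths[i])
  invisible(paths)
}
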