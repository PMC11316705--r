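#' Write / read multi-frame XYZ trajectories
#'
#' Standard XYZ: per frame, a bead-count line, a comment line (carrying
#' `step=<index>` plus any provenance tokens), then one `C x y z` row per
#' bead. Coordinates are written with 17 significant digits, so a
#' write-then-read round trip reproduces float64 values exactly.
#'
#' @param traj A `"trajectory"`, or an N x 3 matrix, or an N x 3 x F array.
#' @param path Output file path.
#' @param comment Extra provenance text appended to each comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, comment = "") {
  frames <- .as_frame_stack(traj)
  steps <- if (inherits(traj, "trajectory")) traj$step_index
           else seq_len(dim(frames)[3])
  n <- dim(frames)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(frames)[3])) {
    writeLines(as.character(n), con)
    writeLines(trimws(sprintf("step=%d %s", steps[f], comment)), con)
    writeLines(sprintf("C %.17g %.17g %.17g",
                       frames[, 1, f], frames[, 2, f], frames[, 3, f]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return For `read_xyz`: a list with `frames` (N x 3 x F array),
#'   `step_index` and `comments`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  i <- 1L
  frames <- list(); steps <- integer(); comments <- character()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("malformed XYZ count at line %d", i),
                       call. = FALSE)
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated XYZ frame starting at line %d", i),
           call. = FALSE)
    comments <- c(comments, lines[i + 1L])
    st <- regmatches(lines[i + 1L],
                     regexpr("step=[0-9]+", lines[i + 1L]))
    steps <- c(steps, if (length(st)) as.integer(sub("step=", "", st))
                      else length(frames) + 1L)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad))
      stop(sprintf("malformed XYZ record at line %d", i + 1L + bad[1]),
           call. = FALSE)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("non-numeric coordinate in frame starting at line %d", i),
           call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in XYZ file", call. = FALSE)
  arr <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  list(frames = arr, step_index = steps, comments = comments)
}

#' Read a Chimera CMM marker file
#'
#' Extracts the `x`, `y`, `z` attributes of `<marker>` elements in file
#' order; the format used by Hi-C structure-modelling tools for per-bead
#' genome models.
#'
#' @param path Path to a `.cmm` (XML) file.
#' @return An M x 3 numeric matrix.
#' @export
read_cmm <- function(path) {
  doc <- xml2::read_xml(path)
  mk <- xml2::xml_find_all(doc, ".//marker")
  if (!length(mk)) stop("no <marker> elements found", call. = FALSE)
  getattr <- function(a) {
    v <- as.numeric(xml2::xml_attr(mk, a))
    if (anyNA(v))
      stop(sprintf("marker %d is missing coordinate attribute '%s'",
                   which(is.na(v))[1], a), call. = FALSE)
    v
  }
  cbind(x = getattr("x"), y = getattr("y"), z = getattr("z"))
}

#' Write / read profile CSV files
#'
#' Tidy CSV with a `#`-prefixed provenance header (tool version, seed, extra
#' key-value pairs); numeric columns round-trip at float64 precision.
#'
#' @param profile Data frame (e.g. a contact or distance profile).
#' @param path Output path.
#' @param meta Named character/numeric vector written into the header.
#' @return `path` (write) or the data frame with a `meta` attribute (read).
#' @export
write_profile_csv <- function(profile, path, meta = c()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ctpoly %s",
                     as.character(utils::packageVersion("ctpoly"))), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, format(meta[[nm]], digits = 17)), con)
  df <- as.data.frame(profile)
  for (j in seq_along(df))   # full float64 precision in the text output
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- regmatches(h, regexec("^# *([^=]+)=(.*)$", h))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  out <- utils::read.csv(text = paste(body, collapse = "\n"))
  attr(out, "meta") <- meta
  out
}

#' Read and validate a simulation config file
#'
#' YAML (or JSON) file with keys matching the [sim_config] arguments, plus
#' optional grid keys `beta` and `rho_sigma3` given as vectors (expanded to
#' a run per combination by [cli_simulate]). Unknown keys are rejected.
#'
#' @param path Path to the YAML/JSON config.
#' @return A named list of validated parameter values.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a mapping of parameter names to values",
         call. = FALSE)
  allowed <- c("n_beads", "rho_sigma3", "beta", "dt", "gamma", "kT",
               "n_steps_equil", "n_steps_prod", "sample_every", "seed",
               "wall_mode", "n_seeds", "k_fene", "R0", "eps_wca", "sigma",
               "wall_eps", "wall_spacing")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg
}
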