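#' Subject bundle objects
#'
#' A `subject_bundle` holds one subject's fiber bundle: an ordered list of
#' streamlines, each an ordered data frame of points with columns
#' `x`, `y`, `z` (mm) and `value` (the per-point microstructure scalar, e.g.
#' FA, unitless, or MD in mm^2/s). Point order within a streamline is the
#' traversal order; every streamline has at least 2 points and all values are
#' finite. Values outside [0, 1] trigger a warning only (MD and other scalars
#' are legitimate), via `warn_range`.
#'
#' @param subject_id subject identifier (scalar character).
#' @param streamlines list of data frames with columns x, y, z, value.
#' @param warn_range if TRUE, warn when values fall outside [0, 1].
#' @return An object of class `subject_bundle`.
#' @export
new_subject_bundle <- function(subject_id, streamlines, warn_range = FALSE) {
  if (length(subject_id) != 1L || is.na(subject_id))
    stopf("`subject_id` must be a single non-missing identifier")
  subject_id <- as.character(subject_id)
  if (!length(streamlines))
    stopf("subject %s: bundle is empty", subject_id)
  for (j in seq_along(streamlines)) {
    s <- streamlines[[j]]
    if (!all(c("x", "y", "z", "value") %in% names(s)))
      stopf("subject %s, streamline %d: need columns x, y, z, value",
            subject_id, j)
    if (nrow(s) < 2L)
      stopf("subject %s, streamline %d: fewer than 2 points", subject_id, j)
    if (!all(is.finite(as.matrix(s[c("x", "y", "z", "value")]))))
      stopf("subject %s, streamline %d: non-finite coordinate or value",
            subject_id, j)
  }
  if (warn_range) {
    v <- unlist(lapply(streamlines, `[[`, "value"), use.names = FALSE)
    if (any(v < 0 | v > 1))
      warnf("subject %s: values outside [0, 1]; fine for MD-like scalars",
            subject_id)
  }
  structure(list(subject_id = subject_id,
                 streamlines = lapply(streamlines, function(s)
                   data.frame(s[c("x", "y", "z", "value")],
                              row.names = NULL))),
            class = "subject_bundle")
}

#' @export
print.subject_bundle <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("subject_bundle %s: %d streamlines, %d points (%d-%d per streamline)\n",
              x$subject_id, length(np), sum(np), min(np), max(np)))
  invisible(x)
}

#' Number of points in a bundle
#' @param bundle a [new_subject_bundle()] object.
#' @return Total number of streamline points.
#' @export
n_points <- function(bundle) {
  sum(vapply(bundle$streamlines, nrow, integer(1)))
}

bundle_values <- function(bundle) {
  unlist(lapply(bundle$streamlines, `[[`, "value"), use.names = FALSE)
}

# ---------------------------------------------------------------------------
# Long-table CSV: the canonical interchange format
# columns: subject_id, streamline_id, point_index, x, y, z, value
# ---------------------------------------------------------------------------

bundle_to_long <- function(bundle) {
  rows <- lapply(seq_along(bundle$streamlines), function(j) {
    s <- bundle$streamlines[[j]]
    data.frame(subject_id = bundle$subject_id, streamline_id = j,
               point_index = seq_len(nrow(s)),
               x = s$x, y = s$y, z = s$z, value = s$value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

long_to_bundles <- function(tab, warn_range = FALSE) {
  need <- c("subject_id", "streamline_id", "point_index", "x", "y", "z", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("long table is missing column(s): %s", paste(miss, collapse = ", "))
  split_subj <- split(tab, tab$subject_id)
  bundles <- lapply(split_subj, function(st) {
    sls <- split(st, st$streamline_id)
    sls <- lapply(sls, function(sl) {
      sl <- sl[order(sl$point_index), , drop = FALSE]
      sl[c("x", "y", "z", "value")]
    })
    new_subject_bundle(st$subject_id[1], unname(sls), warn_range = warn_range)
  })
  bundles[order(names(bundles))]
}

#' Read a streamline bundle with per-point scalar values
#'
#' Reads one subject's bundle from disk. The canonical format is the long
#' table (CSV with columns `subject_id`, `streamline_id`, `point_index`,
#' `x`, `y`, `z`, `value`); TRK and TCK are supported as adapters. For TCK,
#' the geometry file carries no scalars, so an aligned per-point scalar
#' sidecar (plain text, one value per point in file order) is required.
#' Coordinates are passed through unchanged: no registration or resampling
#' happens at I/O time.
#'
#' @param path file path.
#' @param format `"long_table"`, `"trk"`, or `"tck"`.
#' @param scalar_path sidecar scalar file (required for `"tck"`).
#' @param subject_id subject identifier for trk/tck files (which store none);
#'   defaults to the file stem.
#' @param warn_range warn when values fall outside the FA range [0, 1].
#' @return A `subject_bundle` (long tables holding several subjects are read
#'   with [read_bundles()]).
#' @export
read_bundle <- function(path, format = c("long_table", "trk", "tck"),
                        scalar_path = NULL, subject_id = NULL,
                        warn_range = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
    long_table = {
      bundles <- long_to_bundles(utils::read.csv(path, stringsAsFactors = FALSE),
                                 warn_range = warn_range)
      if (length(bundles) != 1L)
        stopf("%s holds %d subjects; use read_bundles()", path, length(bundles))
      bundles[[1]]
    },
    trk = read_trk(path, subject_id, warn_range = warn_range),
    tck = {
      if (is.null(scalar_path))
        stopf("tck format needs `scalar_path` (per-point scalar sidecar)")
      read_tck(path, scalar_path, subject_id, warn_range = warn_range)
    })
}

#' Read a multi-subject long table into a list of bundles
#'
#' @param path long-table CSV holding one or more subjects.
#' @param warn_range warn when values fall outside [0, 1].
#' @return Named list of `subject_bundle` objects, sorted by subject id.
#' @export
read_bundles <- function(path, warn_range = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  long_to_bundles(utils::read.csv(path, stringsAsFactors = FALSE),
                  warn_range = warn_range)
}

#' Write a streamline bundle
#'
#' Inverse of [read_bundle()]. TRK files are written as version-2 with one
#' scalar channel named `value`; TCK files get a plain-text scalar sidecar at
#' `scalar_path`.
#'
#' @param bundle a `subject_bundle` or a list of them (long table only).
#' @param path output path.
#' @param format `"long_table"`, `"trk"`, or `"tck"`.
#' @param scalar_path sidecar path (tck only; defaults to `path` with a
#'   `.value.txt` suffix).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, format = c("long_table", "trk", "tck"),
                         scalar_path = NULL) {
  format <- match.arg(format)
  if (format == "long_table") {
    bl <- if (inherits(bundle, "subject_bundle")) list(bundle) else bundle
    tab <- do.call(rbind, lapply(bl, bundle_to_long))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(bundle, "subject_bundle"))
  if (format == "trk") write_trk(bundle, path)
  else {
    if (is.null(scalar_path)) scalar_path <- paste0(path, ".value.txt")
    write_tck(bundle, path, scalar_path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# TRK (TrackVis) version 2, little-endian, one scalar channel.
# 1000-byte header; per streamline: int32 m, then m rows of
# (x, y, z, value) float32. Coordinates are passed through unchanged and the
# affine is written as identity; this adapter does no spatial interpretation.
# ---------------------------------------------------------------------------

write_trk <- function(bundle, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(nbytes) writeBin(raw(nbytes), con)
  writeChar("TRACK", con, nchars = 5, eos = NULL); pad(1)       # id_string[6]
  writeBin(as.integer(c(1, 1, 1)), con, size = 2)               # dim[3]
  writeBin(c(1, 1, 1), con, size = 4)                           # voxel_size[3]
  writeBin(c(0, 0, 0), con, size = 4)                           # origin[3]
  writeBin(1L, con, size = 2)                                   # n_scalars
  writeChar("value", con, nchars = 5, eos = NULL); pad(200 - 5) # scalar_name[10][20]
  writeBin(0L, con, size = 2)                                   # n_properties
  pad(200)                                                      # property_name
  m4 <- diag(4); writeBin(as.numeric(t(m4)), con, size = 4)     # vox_to_ras
  pad(444)                                                      # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); pad(1)         # voxel_order[4]
  pad(4)                                                        # pad2[4]
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)                  # img orient [6]
  pad(2)                                                        # pad1[2]
  pad(6)                                                        # invert/swap flags
  writeBin(as.integer(length(bundle$streamlines)), con, size = 4) # n_count
  writeBin(2L, con, size = 4)                                   # version
  writeBin(1000L, con, size = 4)                                # hdr_size
  for (s in bundle$streamlines) {
    writeBin(as.integer(nrow(s)), con, size = 4)
    writeBin(as.numeric(t(as.matrix(s[c("x", "y", "z", "value")]))),
             con, size = 4)
  }
  invisible(path)
}

read_trk <- function(path, subject_id, warn_range = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readChar(con, 5, useBytes = TRUE)
  if (!identical(id, "TRACK")) stopf("%s: not a TRK file", path)
  seek(con, 36)                                # skip to n_scalars
  n_scalars <- readBin(con, integer(), size = 2)
  if (n_scalars != 1L)
    stopf("%s: expected exactly 1 scalar channel, found %d", path, n_scalars)
  seek(con, 238)
  n_properties <- readBin(con, integer(), size = 2)
  seek(con, 988)
  n_count <- readBin(con, integer(), size = 4)
  version <- readBin(con, integer(), size = 4)
  hdr_size <- readBin(con, integer(), size = 4)
  if (hdr_size != 1000L) stopf("%s: unsupported TRK header size %d", path, hdr_size)
  seek(con, 1000)
  streamlines <- list(); j <- 0L
  repeat {
    m <- readBin(con, integer(), size = 4)
    if (length(m) == 0L) break
    j <- j + 1L
    dat <- readBin(con, numeric(), n = m * 4L, size = 4)
    if (length(dat) != m * 4L)
      stopf("subject %s, streamline %d: truncated TRK record", subject_id, j)
    mat <- matrix(dat, ncol = 4L, byrow = TRUE)
    if (n_properties > 0) readBin(con, numeric(), n = n_properties, size = 4)
    streamlines[[j]] <- data.frame(x = mat[, 1], y = mat[, 2], z = mat[, 3],
                                   value = mat[, 4])
  }
  if (n_count > 0 && j != n_count)
    warnf("%s: header advertises %d streamlines, read %d", path, n_count, j)
  new_subject_bundle(subject_id, streamlines, warn_range = warn_range)
}

# ---------------------------------------------------------------------------
# TCK (MRtrix): text header terminated by END, then float32 LE triples;
# streamlines separated by a NaN triple, stream terminated by an Inf triple.
# Scalars travel in a plain-text sidecar, one value per point in file order.
# ---------------------------------------------------------------------------

write_tck <- function(bundle, path, scalar_path) {
  n_str <- length(bundle$streamlines)
  header_for <- function(offset) paste0(
    "mrtrix tracks\ndatatype: Float32LE\ncount: ", n_str,
    "\nfile: . ", offset, "\nEND\n")
  offset <- nchar(header_for(0), type = "bytes")
  # offset digits may change the header length; iterate to a fixed point
  while (nchar(header_for(offset), type = "bytes") != offset)
    offset <- nchar(header_for(offset), type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_for(offset), con, eos = NULL)
  for (k in seq_len(n_str)) {
    s <- bundle$streamlines[[k]]
    writeBin(as.numeric(t(as.matrix(s[c("x", "y", "z")]))), con, size = 4)
    if (k < n_str) writeBin(rep(NaN, 3), con, size = 4)
  }
  writeBin(rep(Inf, 3), con, size = 4)
  writeLines(format(unlist(lapply(bundle$streamlines, `[[`, "value"),
                           use.names = FALSE), digits = 17),
             scalar_path)
  invisible(path)
}

read_tck <- function(path, scalar_path, subject_id, warn_range = FALSE) {
  raw_all <- readBin(path, raw(), n = file.info(path)$size)
  end_pat <- as.raw(c(0x45, 0x4e, 0x44, 0x0a))  # "END\n"
  hdr_end <- NA_integer_
  for (i in seq_len(min(length(raw_all) - 3L, 4096L))) {
    if (identical(raw_all[i:(i + 3L)], end_pat)) { hdr_end <- i + 3L; break }
  }
  if (is.na(hdr_end)) stopf("%s: no END marker in TCK header", path)
  header <- rawToChar(raw_all[seq_len(hdr_end)])
  if (!grepl("^mrtrix tracks", header)) stopf("%s: not a TCK file", path)
  if (!grepl("Float32LE", header)) stopf("%s: only Float32LE TCK supported", path)
  off <- as.integer(sub(".*file: \\. ([0-9]+).*", "\\1", header))
  floats <- readBin(raw_all[(off + 1L):length(raw_all)], numeric(),
                    n = (length(raw_all) - off) %/% 4L, size = 4)
  tri <- matrix(floats, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(tri[, 1]); is_end <- is.infinite(tri[, 1])
  stream_id <- cumsum(c(1L, utils::head(is_sep, -1))) # grows after each NaN row
  keep <- !is_sep & !is_end
  values <- scan(scalar_path, what = numeric(), quiet = TRUE)
  if (length(values) != sum(keep))
    stopf("subject %s: scalar sidecar has %d values for %d points",
          subject_id, length(values), sum(keep))
  pts <- data.frame(sl = stream_id[keep], x = tri[keep, 1], y = tri[keep, 2],
                    z = tri[keep, 3], value = values)
  sls <- lapply(split(pts, pts$sl), function(d) d[c("x", "y", "z", "value")])
  new_subject_bundle(subject_id, unname(sls), warn_range = warn_range)
}

# ---------------------------------------------------------------------------
# Covariates
# ---------------------------------------------------------------------------

#' Read a per-subject covariate table
#'
#' Expects a CSV with header `subject_id,sex,age,<scalar...>`: one row per
#' subject, `sex` coded female/male (any capitalization, or f/m), `age` in
#' years, plus one numeric column per scalar factor (e.g., a cognitive
#' assessment score).
#'
#' @param path CSV path.
#' @return Validated data frame with `sex` normalized to `"female"`/`"male"`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("covariate table is missing column(s): %s", paste(miss, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stopf("duplicate subject_id: %s",
          paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  sex <- tolower(trimws(tab$sex))
  sex[sex == "f"] <- "female"; sex[sex == "m"] <- "male"
  bad <- !sex %in% c("female", "male")
  if (any(bad))
    stopf("unknown sex label(s): %s", paste(unique(tab$sex[bad]), collapse = ", "))
  tab$sex <- sex
  tab$age <- as.numeric(tab$age)
  if (anyNA(tab$age)) stopf("non-numeric or missing age values")
  tab
}

#' Write a per-subject covariate table
#' @param covariates data frame with `subject_id`, `sex`, `age`, scalars.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Per-point annotations for external 3-D rendering
# ---------------------------------------------------------------------------

#' Export per-point region annotations
#'
#' Writes a long table (`subject_id`, `streamline_id`, `point_index`,
#' `value`, `region_index`, `z_score_of_region`) aligned with the pooled
#' points, suitable for coloring streamlines in an external 3-D viewer.
#'
#' @param pool a [pool_bundles()] result.
#' @param labels integer region label per pooled point (from
#'   [assign_regions()]).
#' @param region_stats optional data frame with columns `region` and `z`
#'   giving a per-region statistic (e.g., the scalar-factor Z-score); points
#'   in regions absent from it get `z_score_of_region = NA`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_annotations <- function(pool, labels, region_stats = NULL, path) {
  stopifnot(inherits(pool, "population_pool"))
  if (length(labels) != nrow(pool$records))
    stopf("labels length %d does not match pool size %d",
          length(labels), nrow(pool$records))
  z <- rep(NA_real_, length(labels))
  if (!is.null(region_stats)) {
    stopifnot(all(c("region", "z") %in% names(region_stats)))
    z <- region_stats$z[match(labels, region_stats$region)]
  }
  out <- data.frame(pool$records[c("subject_id", "streamline_id", "point_index",
                                   "value")],
                    region_index = labels, z_score_of_region = z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
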