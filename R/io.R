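# Text I/O: orientation fields, velocity fields, tracks and defect tables as
# CSV (with commented calibration headers), images as plain-text PGM (P2).
# No binary formats are used anywhere in the package.

#' Write / read an orientation field as CSV
#'
#' Long format, one row per grid point: `x_px`, `y_px`, `theta_deg`,
#' `coherency`, `mask`; lattice calibration is stored in commented header
#' lines so the round trip is lossless.
#'
#' @param field an [orientation_field].
#' @param path file path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   returns an [orientation_field].
#' @export
write_field_csv <- function(field, path) {
  co <- field_coords(field)
  df <- data.frame(
    x_px = rep(co$x, each = nrow(field$theta)),
    y_px = rep(co$y, times = ncol(field$theta)),
    theta_deg = as.vector(field$theta),
    coherency = as.vector(field$coherency),
    mask = as.integer(as.vector(field$mask)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# nrow=%d ncol=%d", nrow(field$theta), ncol(field$theta)),
    sprintf("# grid_size=%.10g pixel_size=%.10g origin_x=%.10g origin_y=%.10g",
            field$grid_size, field$pixel_size, field$origin[1],
            field$origin[2])), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  num <- function(line, key) {
    as.numeric(sub(sprintf(".*%s=([-0-9.eE+]+).*", key), "\\1", line))
  }
  nr <- num(hdr[1], "nrow"); nc <- num(hdr[1], "ncol")
  df <- utils::read.csv(path, comment.char = "#")
  theta <- matrix(df$theta_deg, nr, nc)
  orientation_field(theta,
                    coherency = matrix(df$coherency, nr, nc),
                    mask = matrix(df$mask == 1L, nr, nc),
                    grid_size = num(hdr[2], "grid_size"),
                    pixel_size = num(hdr[2], "pixel_size"),
                    origin = c(num(hdr[2], "origin_x"), num(hdr[2], "origin_y")))
}

#' Write a velocity field as CSV
#'
#' One row per lattice vector: `x_px`, `y_px`, `u_umh`, `v_umh`, `valid`.
#'
#' @param vf a calibrated [velocity_field].
#' @param path file path.
#' @export
write_velocity_csv <- function(vf, path) {
  if (is.null(vf$u_umh)) stop("velocity field is not calibrated")
  df <- data.frame(x_px = rep(vf$x, each = length(vf$y)),
                   y_px = rep(vf$y, times = length(vf$x)),
                   u_umh = as.vector(vf$u_umh), v_umh = as.vector(vf$v_umh),
                   valid = as.integer(as.vector(vf$valid)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a track table as CSV
#'
#' Canonical schema `track_id, frame, t_h, x_um, y_um`. `read_tracks_csv`
#' also accepts TrackMate-style spot exports (`TRACK_ID`, `FRAME`,
#' `POSITION_X`, `POSITION_Y`, optionally `POSITION_T`), mapped onto the
#' canonical schema.
#'
#' @param ts a [track_set].
#' @param path file path.
#' @param frame_interval,field_area_mm2 calibration used when reading.
#' @export
write_tracks_csv <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval=%.10g field_area_mm2=%.10g",
                     attr(ts, "frame_interval"), attr(ts, "field_area_mm2")),
             con)
  utils::write.csv(as.data.frame(ts), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, frame_interval = NULL,
                            field_area_mm2 = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    num <- function(key) as.numeric(
      sub(sprintf(".*%s=([-0-9.eE+]+).*", key), "\\1", first))
    if (is.null(frame_interval)) frame_interval <- num("frame_interval")
    if (is.null(field_area_mm2)) field_area_mm2 <- num("field_area_mm2")
  }
  df <- utils::read.csv(path, comment.char = "#")
  if ("TRACK_ID" %in% names(df)) {
    if (is.null(frame_interval)) frame_interval <- 1
    tcol <- if ("POSITION_T" %in% names(df)) df$POSITION_T
    else df$FRAME * frame_interval
    df <- data.frame(track_id = df$TRACK_ID + 1L, frame = df$FRAME + 1L,
                     t_h = tcol, x_um = df$POSITION_X, y_um = df$POSITION_Y)
  }
  if (is.null(frame_interval))
    frame_interval <- stats::median(diff(sort(unique(df$t_h))))
  if (is.null(field_area_mm2)) field_area_mm2 <- 1
  track_set(df, frame_interval = frame_interval,
            field_area_mm2 = field_area_mm2)
}

#' Write / read an 8-bit grayscale image as plain-text PGM (P2)
#'
#' Numeric matrices in `[0, 1]` are scaled to 0-255. A portable text format
#' every image tool reads; used in place of TIFF throughout.
#'
#' @param img numeric matrix in `[0, 1]` (or integers 0-255).
#' @param path file path.
#' @export
write_pgm <- function(img, path) {
  v <- if (is.integer(img)) pmin(pmax(img, 0L), 255L)
  else as.integer(round(pmin(pmax(img, 0), 1) * 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  m <- matrix(v, nrow(img), ncol(img))
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stop("only plain-text (P2) PGM is supported")
  vals <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
  nc <- vals[1]; nr <- vals[2]; maxv <- vals[3]
  matrix(vals[-(1:3)], nr, nc, byrow = TRUE) / maxv
}
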