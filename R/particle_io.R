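## Micrograph and particle-coordinate I/O: MRC mode-2, PNG/TIFF, STAR files,
## and coordinate-frame conversions.
##
## Coordinate convention used throughout the package: origin at the top-left
## pixel, x = column index, y = row index, both 0-based, in pixel units of the
## frame's space. Downstream cryo-EM tools differ on this; the convention is
## stated here once and applied everywhere.

#' Construct a micrograph object
#'
#' @param data numeric matrix of intensities; rows are image rows (y), columns
#'   are image columns (x).
#' @param pixel_size physical pixel size in Angstrom per pixel, or `NA` when
#'   unknown.
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(data, pixel_size = NA_real_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, pixel size %s A/px\n",
              nrow(x$data), ncol(x$data),
              ifelse(is.na(x$pixel_size), "?", format(x$pixel_size))))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$data)

as_image_matrix <- function(x) {
  if (inherits(x, "micrograph")) x$data else as.matrix(x)
}

#' Describe a coordinate frame
#'
#' A frame is a pixel space: either `native` (the original micrograph pixels)
#' or `model` (the resized grid the segmentation model operates on). Origin is
#' the top-left pixel, x = column, y = row, 0-based.
#'
#' @param space `"native"` or `"model"`.
#' @param width,height extent of the space in pixels.
#' @return an object of class `coord_frame`.
#' @export
coord_frame <- function(space = c("native", "model"), width, height = width) {
  space <- match.arg(space)
  if (width <= 0 || height <= 0) stopf("coord_frame: zero-sized space")
  structure(list(space = space, width = as.numeric(width),
                 height = as.numeric(height)),
            class = "coord_frame")
}

#' Construct a particle set
#'
#' A data frame of particle centers with a shared diameter and an optional
#' coordinate frame attached as attributes.
#'
#' @param x,y numeric vectors of particle centers (0-based pixels, x = column,
#'   y = row from the top-left corner).
#' @param diameter particle diameter in the same pixel units.
#' @param frame optional [coord_frame()] the coordinates live in.
#' @return a `particle_set` (a data frame with columns `x`, `y`).
#' @export
particle_set <- function(x = numeric(0), y = numeric(0), diameter = NA_real_,
                         frame = NULL) {
  if (length(x) != length(y)) stopf("particle_set: x and y lengths differ")
  ps <- data.frame(x = as.numeric(x), y = as.numeric(y))
  attr(ps, "diameter") <- as.numeric(diameter)
  attr(ps, "frame") <- frame
  class(ps) <- c("particle_set", "data.frame")
  ps
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, diameter %s px (%s frame)\n",
              nrow(x), format(attr(x, "diameter")),
              if (is.null(attr(x, "frame"))) "unspecified"
              else attr(x, "frame")$space))
  if (nrow(x) > 0) print(head(as.data.frame(x), 6))
  invisible(x)
}

#' Convert particle coordinates between frames
#'
#' Linear scaling of x, y (and the diameter) by the ratio of the frame
#' extents. Anisotropic scale factors are allowed for coordinates; the
#' diameter is scaled by the geometric mean of the two factors.
#'
#' @param particles a [particle_set()].
#' @param from source [coord_frame()]; defaults to the frame attached to
#'   `particles`.
#' @param to target [coord_frame()].
#' @return the converted `particle_set` with `to` attached.
#' @export
convert_frame <- function(particles, from = NULL, to) {
  from <- from %||% attr(particles, "frame")
  if (is.null(from)) stopf("convert_frame: source frame not specified")
  if (!inherits(to, "coord_frame") || !inherits(from, "coord_frame")) {
    stopf("convert_frame: frames must be coord_frame objects")
  }
  sx <- to$width / from$width
  sy <- to$height / from$height
  out <- particle_set(particles$x * sx, particles$y * sy,
                      diameter = attr(particles, "diameter") * sqrt(sx * sy),
                      frame = to)
  out
}

## ---- MRC ----

## MRC2014 mode-2 (float32) single-section maps. Header is 1024 bytes; we
## read/write the fields needed for coordinates and pixel size and leave the
## rest zero. Data axis order: x fastest (columns), then y (rows).

#' Read a micrograph from MRC, PNG or TIFF
#'
#' MRC files must be mode 2 (32-bit float). PNG/TIFF intensities are returned
#' on their stored scale (8-bit PNG gives values in 0..255).
#'
#' @param path file path; format is chosen by extension (`.mrc`, `.map`,
#'   `.png`, `.tif`, `.tiff`).
#' @return a [micrograph()].
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mrc = , map = , mrcs = read_mrc(path),
    png = {
      v <- png::readPNG(path)
      if (length(dim(v)) == 3) v <- v[, , 1]
      micrograph(v * 255)
    },
    tif = , tiff = {
      v <- tiff::readTIFF(path)
      if (length(dim(v)) == 3) v <- v[, , 1]
      micrograph(v)
    },
    stopf("unsupported micrograph format '.%s' (expect mrc/png/tiff)", ext))
}

read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stopf("MRC read: %s is truncated (no full header)", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  endian <- "little"
  geti <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                 "integer", size = 4, endian = endian)
  getf <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                 "double", size = 4, endian = endian)
  nx <- geti(1)
  if (nx <= 0 || nx > 1e7) {          # likely big-endian header
    endian <- "big"
    nx <- geti(1)
  }
  ny <- geti(2); nz <- geti(3); mode <- geti(4)
  if (nx <= 0 || ny <= 0) stopf("MRC read: corrupt header (nx=%d, ny=%d)", nx, ny)
  if (mode != 2) stopf("MRC read: unsupported mode %d; only mode 2 (float32)", mode)
  mx <- geti(8); cella_x <- getf(11)
  n <- nx * ny
  if (sz < 1024 + 4 * n) {
    stopf("MRC read: %s is truncated (%d data bytes, %d expected)",
          path, sz - 1024, 4 * n)
  }
  vals <- readBin(con, "double", size = 4, n = n, endian = endian)
  px <- if (mx > 0 && cella_x > 0) cella_x / mx else NA_real_
  micrograph(t(matrix(vals, nrow = nx, ncol = ny)), pixel_size = px)
}

#' Write a micrograph
#'
#' MRC output is mode 2 (float32) with pixel-size metadata in the cell
#' dimensions. PNG output is min-max scaled to 8-bit for visualization.
#'
#' @param mic a [micrograph()] or numeric matrix.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(mic, path) {
  if (!inherits(mic, "micrograph")) mic <- micrograph(mic)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mrc = , map = write_mrc(mic, path),
    png = {
      v <- mic$data
      rng <- range(v)
      v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
      png::writePNG(v, path)
    },
    tif = , tiff = tiff::writeTIFF(mic$data, path, bits.per.sample = 32L,
                                   reduce = TRUE),
    stopf("unsupported output format '.%s'", ext))
  invisible(path)
}

write_mrc <- function(mic, path) {
  x <- mic$data
  nx <- ncol(x); ny <- nrow(x)
  px <- ifelse(is.na(mic$pixel_size), 1, mic$pixel_size)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(nx, ny, 1L))                # nx ny nz
  wi(2L)                           # mode 2 = float32
  wi(c(0L, 0L, 0L))                # nxstart nystart nzstart
  wi(c(nx, ny, 1L))                # mx my mz
  wf(c(nx * px, ny * px, px))      # cella
  wf(c(90, 90, 90))                # cellb
  wi(c(1L, 2L, 3L))                # mapc mapr maps
  wf(c(min(x), max(x), mean(x)))   # dmin dmax dmean
  wi(rep(0L, 2))                   # ispg nsymbt
  wi(rep(0L, 25))                  # extra
  wf(c(0, 0, 0))                   # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.vector(x)))             # rms
  wi(0L)                           # nlabl
  writeBin(raw(800), con)          # labels
  wf(as.vector(t(x)))              # x fastest
  invisible(path)
}

## ---- STAR ----

#' Write particle coordinates to a STAR file
#'
#' Emits a single `data_particles` block with a `loop_` of
#' `_rlnCoordinateX` / `_rlnCoordinateY` columns (RELION dialect), one row per
#' particle, 6-decimal floats, 0-based top-left pixel coordinates. The
#' particle diameter is deliberately not written: coordinate STAR files
#' conventionally carry positions only.
#'
#' @param particles a [particle_set()].
#' @param path output path.
#' @param frame optional target [coord_frame()]; when given and different from
#'   the frame attached to `particles`, coordinates are converted before
#'   writing (e.g. model-space picks written in native pixels).
#' @return `path`, invisibly.
#' @export
write_star <- function(particles, path, frame = NULL) {
  if (!is.null(frame)) {
    src <- attr(particles, "frame")
    if (!is.null(src) && (src$width != frame$width || src$height != frame$height ||
                          src$space != frame$space)) {
      particles <- convert_frame(particles, src, frame)
    }
  }
  lines <- c(
    "",
    "data_particles",
    "",
    "loop_",
    "_rlnCoordinateX #1",
    "_rlnCoordinateY #2"
  )
  if (nrow(particles) > 0) {
    lines <- c(lines, sprintf("%.6f %.6f", particles$x, particles$y))
  }
  writeLines(c(lines, ""), path)
  invisible(path)
}

#' Read particle coordinates from a STAR file
#'
#' Parses the first `data_` block containing a `loop_` with recognizable
#' coordinate labels (`_rlnCoordinateX`/`Y`, case-insensitive; any label
#' ending in `coordinatex`/`coordinatey` is accepted). Extra columns are
#' ignored.
#'
#' @param path STAR file path.
#' @param diameter optional particle diameter to attach (not stored in
#'   coordinate STAR files).
#' @param frame optional [coord_frame()] to attach (native assumed).
#' @return a [particle_set()].
#' @export
read_star <- function(path, diameter = NA_real_, frame = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw_lines <- readLines(path, warn = FALSE)
  lines <- trimws(raw_lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) stopf("STAR read: no loop_ block in %s", path)
  i <- loop_at[1] + 1
  labels <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    labels <- c(labels, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1
  }
  lx <- grep("coordinatex$", tolower(labels))
  ly <- grep("coordinatey$", tolower(labels))
  if (length(lx) != 1 || length(ly) != 1) {
    stopf("STAR read: no coordinate columns among labels: %s",
          paste(labels, collapse = ", "))
  }
  xs <- numeric(0); ys <- numeric(0); row_no <- 0
  while (i <= length(lines) && nzchar(lines[i]) && !startsWith(lines[i], "data_")) {
    row_no <- row_no + 1
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (length(tok) < length(labels)) {
      stopf("STAR read: row %d has %d fields, %d labels", row_no,
            length(tok), length(labels))
    }
    v <- suppressWarnings(as.numeric(tok[c(lx, ly)]))
    if (any(is.na(v))) stopf("STAR read: malformed numeric in data row %d", row_no)
    xs <- c(xs, v[1]); ys <- c(ys, v[2])
    i <- i + 1
  }
  particle_set(xs, ys, diameter = diameter, frame = frame)
}

#' Write an overlay image with picked particles marked as circles
#'
#' @param mic a [micrograph()].
#' @param particles a [particle_set()] in the micrograph's native frame.
#' @param path output PNG path.
#' @param radius circle radius in pixels; defaults to half the particle
#'   diameter.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(mic, particles, path, radius = NULL) {
  v <- as_image_matrix(mic)
  rng <- range(v)
  g <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  img <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  r <- radius %||% (attr(particles, "diameter") / 2)
  if (!is.finite(r)) r <- max(3, round(min(dim(g)) / 50))
  th <- seq(0, 2 * pi, length.out = max(16, round(4 * r)))
  for (k in seq_len(nrow(particles))) {
    ri <- round(particles$y[k] + 1 + r * sin(th))
    ci <- round(particles$x[k] + 1 + r * cos(th))
    ok <- ri >= 1 & ri <= nrow(g) & ci >= 1 & ci <= ncol(g)
    img[cbind(ri[ok], ci[ok], 1)] <- 1
    img[cbind(ri[ok], ci[ok], 2)] <- 0
    img[cbind(ri[ok], ci[ok], 3)] <- 0
  }
  png::writePNG(img, path)
  invisible(path)
}
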