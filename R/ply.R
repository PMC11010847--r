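#' Read a PLY point cloud
#'
#' Supports the `ascii` and `binary_little_endian` PLY dialects (the formats
#' written by RealSense tooling and CloudCompare). The vertex element must
#' declare `x`, `y`, `z` (float or double); colours are returned iff all three
#' of `red`, `green`, `blue` (uchar) are present. Point order is preserved as
#' stored. Big-endian files and list properties are rejected.
#'
#' @param path path to a `.ply` file.
#' @param source_id provenance label for the returned cloud; defaults to the
#'   file name.
#' @return a [point_cloud()].
#' @export
read_ply <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("PLY file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  # Read the header byte-wise so the connection stays positioned at the start
  # of the (possibly binary) body.
  read_header_line <- function() {
    bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) stop("malformed PLY: unexpected end of header")
      if (b == as.raw(0x0a)) break
      bytes <- c(bytes, b)
    }
    sub("\r$", "", rawToChar(bytes))
  }

  first <- read_header_line()
  if (trimws(first) != "ply") stop("malformed PLY: missing 'ply' magic line")
  format <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    line <- trimws(read_header_line())
    if (line == "end_header") break
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  types = character(0), names = character(0))
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY: property before element")
      if (tok[2] == "list")
        stop("unsupported PLY: list properties are not handled")
      cur$types <- c(cur$types, tok[2])
      cur$names <- c(cur$names, tok[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(format)) stop("malformed PLY: no format line")
  if (format == "binary_big_endian")
    stop("unsupported PLY: big-endian encoding (only ascii and ",
         "binary_little_endian are supported)")
  if (!format %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", format)
  if (is.null(elements$vertex)) stop("malformed PLY: no vertex element")
  other <- elements[setdiff(names(elements), "vertex")]
  if (any(vapply(other, function(e) e$count > 0L, logical(1))))
    stop("unsupported PLY: non-empty non-vertex elements")

  v <- elements$vertex
  for (need in c("x", "y", "z"))
    if (!need %in% v$names)
      stop("malformed PLY: vertex element lacks property '", need, "'")
  color_present <- all(c("red", "green", "blue") %in% v$names)

  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  unknown <- setdiff(v$types, names(type_size))
  if (length(unknown))
    stop("unsupported PLY property type: ", paste(unknown, collapse = ", "))

  n <- v$count
  if (format == "ascii") {
    if (n == 0L) {
      vals <- matrix(numeric(0), nrow = 0, ncol = length(v$names))
    } else {
      txt <- readLines(con, warn = FALSE)
      txt <- txt[nzchar(trimws(txt))]
      if (length(txt) < n) stop("malformed PLY: fewer vertex rows than declared")
      vals <- matrix(scan(text = txt[seq_len(n)], quiet = TRUE),
                     nrow = n, ncol = length(v$names), byrow = TRUE)
    }
  } else {
    sizes <- type_size[v$types]
    stride <- sum(sizes)
    body <- readBin(con, "raw", n = stride * n)
    if (length(body) < stride * n)
      stop("malformed PLY: binary body shorter than declared")
    rawmat <- matrix(body, nrow = stride, ncol = n)
    offs <- c(0L, cumsum(sizes))
    vals <- matrix(0, nrow = n, ncol = length(v$names))
    for (j in seq_along(v$names)) {
      bytes <- as.vector(rawmat[(offs[j] + 1L):offs[j + 1L], , drop = FALSE])
      tp <- v$types[j]
      vals[, j] <- if (tp %in% c("float", "float32", "double", "float64")) {
        readBin(bytes, "double", n = n, size = sizes[j], endian = "little")
      } else if (tp %in% c("uchar", "uint8")) {
        as.integer(bytes)
      } else {
        readBin(bytes, "integer", n = n, size = sizes[j], endian = "little",
                signed = !grepl("^u", tp))
      }
    }
  }
  colnames(vals) <- v$names
  pts <- vals[, c("x", "y", "z"), drop = FALSE]
  cols <- if (color_present) {
    cm <- vals[, c("red", "green", "blue"), drop = FALSE]
    storage.mode(cm) <- "integer"
    cm
  }
  point_cloud(pts, colors = cols, source_id = source_id)
}

#' Write a point cloud to PLY
#'
#' Coordinates are stored as 32-bit floats (ascii output keeps 7 decimals),
#' so a write/read round-trip preserves coordinates to well under 1e-6 m at
#' pen scale; colours round-trip exactly.
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param encoding `"ascii"` or `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path,
                      encoding = c("ascii", "binary_little_endian")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  hdr <- c("ply",
           paste("format", encoding, "1.0"),
           paste("element vertex", n),
           "property float x", "property float y", "property float z")
  if (has_colors(cloud))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, "end_header")

  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  if (n == 0L) return(invisible(path))

  if (encoding == "ascii") {
    coord <- apply(cloud$points, 1, function(r)
      paste(sprintf("%.7f", r), collapse = " "))
    if (has_colors(cloud)) {
      col <- apply(cloud$colors, 1, paste, collapse = " ")
      coord <- paste(coord, col)
    }
    writeLines(coord, con, sep = "\n")
  } else {
    fl <- writeBin(as.vector(t(cloud$points)), raw(), size = 4,
                   endian = "little")
    if (has_colors(cloud)) {
      fm <- matrix(fl, nrow = 12L)                 # 12 bytes of xyz per point
      cm <- matrix(as.raw(t(cloud$colors)), nrow = 3L)
      writeBin(as.vector(rbind(fm, cm)), con)
    } else {
      writeBin(fl, con)
    }
  }
  invisible(path)
}

#' Write a body-measurement table
#'
#' CSV twin of the on-screen readout: one row per animal with shoulder,
#' abdominal and hip widths (meters, 3 decimals) and, when available, the
#' predicted weight in kg.
#'
#' @param rows data frame (or coercible) with columns `id`, `shoulder`,
#'   `abdomen`, `hip` and optionally `weight` (NA for absent).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(rows, path) {
  rows <- as.data.frame(rows)
  lines <- "id,shoulder,abdomen,hip,weight"
  if (nrow(rows) > 0) {
    if (!"weight" %in% names(rows)) rows$weight <- NA_real_
    fmt_w <- function(w) ifelse(is.na(w), "", sprintf("%.3f", w))
    lines <- c(lines, sprintf("%s,%.3f,%.3f,%.3f,%s",
                              as.character(rows$id), rows$shoulder,
                              rows$abdomen, rows$hip, fmt_w(rows$weight)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a body-measurement table written by [write_measurements()]
#' @param path CSV path.
#' @return data frame with columns id, shoulder, abdomen, hip, weight.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, colClasses = c(id = "character"))
}
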