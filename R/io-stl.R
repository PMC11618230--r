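#' Read an STL surface triangulation (ASCII or binary)
#'
#' Vertices are merged exactly (bitwise-equal coordinates); a watertightness
#' check counts edges not shared by exactly two triangles.
#'
#' @param path an .stl file
#' @return list with `vertices` (n x 3), `triangles` (m x 3),
#'   `watertight` (logical), `open_edges` (count), `area` (total, m^2)
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("read_stl: file too short or missing: ", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(80, sz))
  close(con)
  is_ascii <- grepl("^solid", rawToChar(head[1:5]), ignore.case = TRUE) &&
    .stl_looks_ascii(path)
  tri <- if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path, sz)
  v <- tri$v
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "|")
  uid <- match(key, unique(key))
  vertices <- v[!duplicated(key), , drop = FALSE]
  triangles <- matrix(uid, ncol = 3L, byrow = TRUE)
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
  cnt <- table(ekey)
  open_edges <- sum(cnt != 2L)
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  area <- sum(sqrt(rowSums(.cross3(b - a, c3 - a)^2)) / 2)
  list(vertices = vertices, triangles = triangles,
       watertight = open_edges == 0L, open_edges = open_edges, area = area)
}

.stl_looks_ascii <- function(path) {
  txt <- tryCatch(readLines(path, n = 5L, warn = FALSE), error = function(e) "")
  any(grepl("facet|endsolid", txt))
}

.read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("read_stl: malformed ASCII STL (vertex count ", length(vl),
         " not a multiple of 3)")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4]), numeric(3)))
  if (anyNA(nums)) stop("read_stl: unparsable vertex line")
  list(v = nums)
}

.read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * ntri
  if (sz < expected)
    stop("read_stl: truncated binary STL at byte ", sz, " (expected ",
         expected, " for ", ntri, " triangles)")
  v <- matrix(0, 3L * ntri, 3L)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    v[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  list(v = v)
}

#' Write a surface triangulation as ASCII STL
#'
#' @param vertices n x 3 matrix
#' @param triangles m x 3 index matrix
#' @param path output file
#' @return `path`, invisibly
#' @export
write_stl_ascii <- function(vertices, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  nrm <- .cross3(b - a, c3 - a)
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  for (i in seq_len(nrow(triangles))) {
    writeLines(c(
      sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "    outer loop",
      sprintf("      vertex %.17g %.17g %.17g", a[i, 1], a[i, 2], a[i, 3]),
      sprintf("      vertex %.17g %.17g %.17g", b[i, 1], b[i, 2], b[i, 3]),
      sprintf("      vertex %.17g %.17g %.17g", c3[i, 1], c3[i, 2], c3[i, 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid surface", con)
  invisible(path)
}
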