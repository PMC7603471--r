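# STL / PLY triangle-mesh IO (ASCII and binary STL read, binary STL write,
# ASCII PLY read/write).  Meshes are welded on read via clean_mesh().

#' Read a triangle mesh (STL or PLY)
#'
#' @param path file path ending in `.stl` or `.ply`; both binary and ASCII
#'   STL and ASCII PLY are understood.
#' @param name mesh name (defaults to the file base name).
#' @param clean weld duplicate vertices and drop degenerate faces.
#' @return an `ot_mesh`.
#' @export
read_mesh <- function(path, name = NULL, clean = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  lp <- tolower(path)
  mesh <- if (grepl("\\.stl$", lp)) read_stl(path, name)
  else if (grepl("\\.ply$", lp)) read_ply(path, name)
  else stop("unsupported mesh format (expected .stl or .ply): ", path)
  if (clean) mesh <- clean_mesh(mesh)
  mesh
}

#' Write a triangle mesh (binary STL or ASCII PLY)
#'
#' @param mesh an `ot_mesh`.
#' @param path output path ending in `.stl` (binary) or `.ply` (ASCII).
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "ot_mesh"))
  lp <- tolower(path)
  if (grepl("\\.stl$", lp)) write_stl_binary(mesh, path)
  else if (grepl("\\.ply$", lp)) write_ply_ascii(mesh, path)
  else stop("unsupported mesh format (expected .stl or .ply): ", path)
  invisible(path)
}

read_stl <- function(path, name) {
  # ASCII STL starts with "solid" AND contains "facet"; binary may also start
  # with "solid", so sniff the body (byte-wise, robust to non-text content)
  head <- readBin(path, "raw", n = 512)
  is_ascii <- length(grepRaw("^[[:space:]]*solid", head)) > 0 &&
    length(grepRaw("facet", head, fixed = TRUE)) > 0
  if (is_ascii) read_stl_ascii(path, name) else read_stl_binary(path, name)
}

read_stl_ascii <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3 != 0)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4]), numeric(3)))
  nt <- nrow(nums) / 3
  new_mesh(nums, matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE), name)
}

read_stl_binary <- function(path, name) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(nt) || nt <= 0 || nt > 5e7) stop("malformed binary STL: ", path)
  rec <- readBin(con, "raw", n = nt * 50)
  if (length(rec) < nt * 50) stop("truncated binary STL: ", path)
  m <- matrix(rec, nrow = 50)
  tri <- vapply(seq_len(nt), function(i) {
    readBin(m[13:48, i], "numeric", 9, size = 4, endian = "little")
  }, numeric(9))
  V <- matrix(NA_real_, 3 * nt, 3)
  V[seq(1, 3 * nt, by = 3), ] <- t(tri[1:3, , drop = FALSE])
  V[seq(2, 3 * nt, by = 3), ] <- t(tri[4:6, , drop = FALSE])
  V[seq(3, 3 * nt, by = 3), ] <- t(tri[7:9, , drop = FALSE])
  new_mesh(V, matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE), name)
}

write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", paste("otoplan mesh", mesh$name)))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (t in seq_len(nrow(F))) {
    a <- V[F[t, 1], ]; b <- V[F[t, 2], ]; c <- V[F[t, 3], ]
    n <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
           (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
           (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    ln <- sqrt(sum(n^2)); if (ln > 0) n <- n / ln
    writeBin(as.numeric(c(n, a, b, c)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

read_ply <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported: ", path)
  endh <- match(TRUE, grepl("^end_header", lines))
  ev <- grep("^element vertex", lines[1:endh], value = TRUE)
  ef <- grep("^element face", lines[1:endh], value = TRUE)
  if (!length(ev) || !length(ef)) stop("malformed PLY header: ", path)
  nv <- as.integer(strsplit(ev, "\\s+")[[1]][3])
  nf <- as.integer(strsplit(ef, "\\s+")[[1]][3])
  body <- lines[(endh + 1):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vrows, function(x) as.numeric(x[1:3]), numeric(3)))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(frows, function(x) {
    k <- as.integer(x[1])
    if (k != 3) stop("only triangle faces are supported")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  new_mesh(V, F, name)
}

write_ply_ascii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  vlines <- sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3])
  flines <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}
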