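# Multi-label 3D volumes: construction, NIfTI / MetaImage IO, largest
# connected component, volume-of-interest computation, isosurface extraction.
# Physical coordinates are voxel centres: origin + (index - 1) * spacing.

#' Create a label volume
#'
#' @param data 3D integer array of nonnegative labels (0 = background).
#' @param spacing voxel spacing per axis, mm (> 0).
#' @param origin physical position of the centre of voxel (1,1,1), mm.
#' @param labels named integer vector mapping structure names to label ids
#'   (e.g. `c(ICA = 1, JV = 2, ...)`); optional.
#' @return an `ot_label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         labels = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("label volume data must be a 3D array")
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (any(data < 0, na.rm = TRUE)) stop("labels must be nonnegative")
  if (!is.null(labels)) {
    labels <- setNames(as.integer(labels), names(labels))
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 labels = labels),
            class = "ot_label_volume")
}

#' @export
print.ot_label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ot_label_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, %d labels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

#' Read / write label volumes (NIfTI or MetaImage)
#'
#' Format is chosen by extension: `.nii` / `.nii.gz` (NIfTI, via RNifti) or
#' `.mha` / `.mhd` (MetaImage, uncompressed).  MetaImage round-trips grid,
#' spacing and origin exactly; NIfTI stores spacing as 32-bit floats, so
#' spacing round-trips to single precision there.
#'
#' @param path file path.
#' @param lv an `ot_label_volume`.
#' @return `load_label_volume()` returns an `ot_label_volume`.
#' @export
load_label_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3) stop("expected a 3D NIfTI image: ", path)
    hdr <- RNifti::niftiHeader(img)
    spacing <- as.numeric(hdr$pixdim[2:4])
    xf <- RNifti::xform(img)
    origin <- as.numeric(xf[1:3, 4])
    arr <- array(as.integer(img), dim(img))  # strip image attributes
    label_volume(arr, spacing, origin)
  } else if (grepl("\\.mh[ad]$", lp)) {
    read_metaimage(path)
  } else {
    stop("unsupported label-volume format (expected .nii, .nii.gz, .mha or .mhd): ",
         path)
  }
}

#' @rdname load_label_volume
#' @export
save_label_volume <- function(lv, path) {
  stopifnot(inherits(lv, "ot_label_volume"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    xf <- diag(c(lv$spacing, 1))
    xf[1:3, 4] <- lv$origin
    img <- RNifti::asNifti(lv$data)
    RNifti::pixdim(img) <- lv$spacing
    img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
    img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
    RNifti::writeNifti(img, path, datatype = "int32")
  } else if (grepl("\\.mh[ad]$", lp)) {
    write_metaimage(lv, path)
  } else {
    stop("unsupported label-volume format (expected .nii, .nii.gz, .mha or .mhd): ",
         path)
  }
  invisible(path)
}

# --- minimal MetaImage (.mha local, .mhd + .raw) reader / writer ------------

write_metaimage <- function(lv, path) {
  d <- dim(lv$data)
  local_data <- grepl("\\.mha$", tolower(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    sprintf("BinaryDataByteOrderMSB = %s",
            if (.Platform$endian == "big") "True" else "False"),
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", lv$origin[1], lv$origin[2], lv$origin[3]),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            lv$spacing[1], lv$spacing[2], lv$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    "ElementType = MET_INT",
    sprintf("ElementDataFile = %s",
            if (local_data) "LOCAL" else paste0(basename(sub("\\.mhd$", ".raw", path))))
  )
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.integer(lv$data), con, size = 4,
             endian = .Platform$endian)
  } else {
    writeLines(hdr, path)
    rawpath <- sub("\\.mhd$", ".raw", path)
    con <- file(rawpath, "wb")
    on.exit(close(con))
    writeBin(as.integer(lv$data), con, size = 4, endian = .Platform$endian)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line)) stop("malformed MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3")) stop("only 3D MetaImage volumes are supported")
  if (identical(hdr$CompressedData, "True")) stop("compressed MetaImage not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  else c(0, 0, 0)
  type <- hdr$ElementType
  n <- prod(d)
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"
  readers <- list(
    MET_UCHAR = function(c) as.integer(readBin(c, "integer", n, size = 1, signed = FALSE)),
    MET_CHAR = function(c) readBin(c, "integer", n, size = 1, signed = TRUE),
    MET_USHORT = function(c) readBin(c, "integer", n, size = 2, signed = FALSE, endian = endian),
    MET_SHORT = function(c) readBin(c, "integer", n, size = 2, signed = TRUE, endian = endian),
    MET_INT = function(c) readBin(c, "integer", n, size = 4, endian = endian),
    MET_UINT = function(c) as.integer(readBin(c, "integer", n, size = 4, endian = endian)),
    MET_FLOAT = function(c) as.integer(round(readBin(c, "numeric", n, size = 4, endian = endian))),
    MET_DOUBLE = function(c) as.integer(round(readBin(c, "numeric", n, size = 8, endian = endian)))
  )
  if (is.null(readers[[type]])) stop("unsupported MetaImage element type: ", type)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readers[[type]](con)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- readers[[type]](con2)
  }
  label_volume(array(vals, dim = d), spacing, origin)
}

# ---------------------------------------------------------------------------

lv_mask <- function(lv, label) {
  m <- lv$data == as.integer(label)
  storage.mode(m) <- "integer"
  m
}

#' Largest 26-connected component of a label
#'
#' Keeps the single largest 26-connected component of the voxels carrying
#' `label`; ties in size resolve deterministically to the component whose
#' seed voxel comes first in scan order.
#'
#' @param lv an `ot_label_volume`.
#' @param label label id (or a structure name present in `lv$labels`).
#' @return a binary 3D integer array (mask); an all-zero mask (with a
#'   warning) if the label is absent.
#' @export
largest_component <- function(lv, label) {
  stopifnot(inherits(lv, "ot_label_volume"))
  label <- resolve_label(lv, label)
  m <- lv_mask(lv, label)
  if (!any(m == 1L)) {
    warning(sprintf("label %d is absent from the volume; returning an empty mask", label))
    return(array(0L, dim(lv$data)))
  }
  cc <- cc_label_cpp(as.integer(m), dim(m))
  best <- which.max(cc$sizes)  # which.max takes the first maximum: earliest seed
  out <- array(as.integer(array(cc$labels, dim(m)) == best), dim(m))
  out
}

resolve_label <- function(lv, label) {
  if (is.character(label)) {
    if (is.null(lv$labels) || !label %in% names(lv$labels))
      stop("unknown structure name: ", label)
    return(lv$labels[[label]])
  }
  as.integer(label)
}

mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

#' Volume of interest around the (non-excluded) risk structures
#'
#' Computes the union bounding box of the largest connected components of all
#' labels except the excluded ones (e.g. the internal carotid artery), pads
#' it, then expands the shorter of the X and Y extents symmetrically so the
#' box is square in X--Y, clipping to the grid.  When `include` is given,
#' those labels' component boxes are always unioned in regardless of size
#' (safeguard for thin structures such as the chorda tympani).
#'
#' @param lv an `ot_label_volume`.
#' @param exclude labels (ids or names) left out of the box computation.
#' @param pad padding in voxels applied on all sides before squaring.
#' @param include labels always unioned into the box (default: "ChT" when
#'   named labels are present).
#' @return list with `index_box` (2 x 3 matrix of 1-based inclusive voxel
#'   bounds) and `physical_box` (2 x 3, mm).
#' @export
compute_voi <- function(lv, exclude = integer(0), pad = 5, include = NULL) {
  stopifnot(inherits(lv, "ot_label_volume"))
  excl <- vapply(as.list(exclude), function(l) resolve_label(lv, l), integer(1))
  present <- setdiff(sort(unique(as.vector(lv$data))), 0L)
  use <- setdiff(present, excl)
  if (is.null(include) && !is.null(lv$labels) && "ChT" %in% names(lv$labels))
    include <- intersect(lv$labels[["ChT"]], present)
  use <- union(use, setdiff(as.integer(include), excl))
  if (!length(use)) stop("no non-excluded labels present in the volume")
  box <- NULL
  for (l in use) {
    b <- mask_bbox(largest_component(lv, l))
    if (is.null(b)) next
    box <- if (is.null(box)) b else rbind(lo = pmin(box[1, ], b[1, ]),
                                          hi = pmax(box[2, ], b[2, ]))
  }
  d <- dim(lv$data)
  lo <- pmax(1, box[1, ] - pad)
  hi <- pmin(d, box[2, ] + pad)
  # make the X and Y extents equal (expand the smaller, symmetrically)
  ext <- hi - lo + 1
  if (ext[1] != ext[2]) {
    ax <- if (ext[1] < ext[2]) 1 else 2
    need <- abs(ext[2] - ext[1])
    grow_lo <- need %/% 2
    grow_hi <- need - grow_lo
    lo[ax] <- lo[ax] - grow_lo
    hi[ax] <- hi[ax] + grow_hi
    # shift back inside the grid if clipped, then clip hard
    if (lo[ax] < 1) { hi[ax] <- hi[ax] + (1 - lo[ax]); lo[ax] <- 1 }
    if (hi[ax] > d[ax]) { lo[ax] <- max(1, lo[ax] - (hi[ax] - d[ax])); hi[ax] <- d[ax] }
  }
  idx <- rbind(lo = lo, hi = hi)
  phys <- rbind(lo = lv$origin + (lo - 1) * lv$spacing,
                hi = lv$origin + (hi - 1) * lv$spacing)
  list(index_box = idx, physical_box = phys)
}

#' Extract the surface mesh of a labelled structure
#'
#' Isosurface of the binary mask at level 0.5 (marching tetrahedra over the
#' voxel-centre lattice), with vertices in physical mm coordinates and
#' outward-oriented normals, followed by vertex welding and Taubin
#' smoothing to remove the staircase bias of binary masks.
#'
#' @param lv an `ot_label_volume`.
#' @param label label id or structure name; must occupy at least 8 voxels.
#' @param smooth_iters Taubin smoothing iterations (0 disables smoothing).
#' @return an `ot_mesh` (watertight).
#' @export
extract_surface <- function(lv, label, smooth_iters = 50) {
  stopifnot(inherits(lv, "ot_label_volume"))
  label <- resolve_label(lv, label)
  mask <- lv_mask(lv, label)
  nvox <- sum(mask)
  if (nvox < 8) {
    stop(sprintf("label %d occupies only %d voxels (need >= 8) - structure too small for surface extraction",
                 label, nvox))
  }
  bb <- mask_bbox(mask)
  lo <- pmax(1, bb[1, ] - 1); hi <- pmin(dim(mask), bb[2, ] + 1)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin_sub <- lv$origin + (lo - 1) * lv$spacing
  res <- march_tets_cpp(as.integer(sub), dim(sub), lv$spacing, origin_sub)
  V <- res$vertices
  if (smooth_iters > 0) {
    V <- taubin_smooth_cpp(V, res$faces, as.integer(smooth_iters), 0.8, -0.83)
  }
  name <- if (!is.null(lv$labels)) {
    nm <- names(lv$labels)[match(label, lv$labels)]
    if (is.na(nm)) paste0("label_", label) else nm
  } else paste0("label_", label)
  new_mesh(V, res$faces, name)
}

#' Build an obstacle environment from a label volume
#'
#' Extracts one surface per requested label and assembles the environment.
#'
#' @param lv an `ot_label_volume`.
#' @param labels labels to use as obstacles (default: all named labels except
#'   any named "Skull", else all labels present).
#' @param smooth_iters passed to [extract_surface()].
#' @export
environment_from_labels <- function(lv, labels = NULL, smooth_iters = 50) {
  if (is.null(labels)) {
    labels <- if (!is.null(lv$labels)) {
      lv$labels[setdiff(names(lv$labels), "Skull")]
    } else setdiff(sort(unique(as.vector(lv$data))), 0L)
  }
  meshes <- lapply(labels, function(l) extract_surface(lv, l, smooth_iters))
  environment_from_meshes(meshes, clean = TRUE)
}
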