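#' Read and write volumes (NIfTI-1 and MetaImage)
#'
#' Volumes are exchanged as NIfTI (.nii / .nii.gz, via RNifti) or
#' MetaImage (.mha single file / .mhd + .raw pair). Geometry is stored in
#' the NIfTI sform (axis-aligned, RAS-like with positive spacings) or the
#' MetaImage Offset/ElementSpacing tags; the unit tag travels in the
#' NIfTI `descrip` field or an `AnatomicalOrientation`-adjacent comment
#' tag. Values are stored as float32 (masks as uint8), so a write/read
#' round trip is bitwise lossless for float32 data and preserves
#' geometry to well under 1e-6 mm.
#'
#' @param vol a [volume()].
#' @param path file path ending in .nii, .nii.gz, .mha or .mhd.
#' @return `read_volume` returns a [volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  ext <- file_ext_lower(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(vol$values, datatype = "float")
    sf <- diag(4)
    diag(sf)[1:3] <- vol$grid$spacing
    sf[1:3, 4] <- vol$grid$origin
    RNifti::sform(img) <- structure(sf, code = 2L)
    img$descrip <- vol$unit
    RNifti::writeNifti(img, path, datatype = "float")
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(vol$values, vol$grid, vol$unit, path,
                    type = "MET_FLOAT")
  } else {
    stop("unknown volume file extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param unit unit tag to use if the file carries none.
#' @export
read_volume <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- file_ext_lower(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    spacing <- abs(diag(xf)[1:3])
    if (any(spacing <= 0)) stop("geometry missing or degenerate in ", path)
    origin <- xf[1:3, 4]
    vals <- array(as.numeric(img), dim(img))  # strip niftiImage attrs
    if (length(dim(vals)) == 2) dim(vals) <- c(dim(vals), 1L)
    g <- grid3d(dim(vals), spacing, origin)
    stored <- trimws(RNifti::niftiHeader(img)$descrip)
    u <- if (!is.null(unit)) unit else if (nzchar(stored)) stored else "unitless"
    volume(vals, g, unit = u)
  } else if (ext %in% c("mha", "mhd")) {
    mi <- read_metaimage(path)
    u <- if (!is.null(unit)) unit else mi$unit
    volume(mi$values, mi$grid, unit = u)
  } else {
    stop("unknown volume file extension: ", ext)
  }
}

#' @rdname write_volume
#' @param mask a [binary_mask()]; stored as uint8 \{0, 1\}.
#' @export
write_mask <- function(mask, path) {
  ext <- file_ext_lower(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(array(as.integer(mask$member), mask$grid$shape),
                           datatype = "uint8")
    sf <- diag(4)
    diag(sf)[1:3] <- mask$grid$spacing
    sf[1:3, 4] <- mask$grid$origin
    RNifti::sform(img) <- structure(sf, code = 2L)
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(array(as.integer(mask$member), mask$grid$shape),
                    mask$grid, "mask", path, type = "MET_UCHAR")
  } else {
    stop("unknown mask file extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path, unit = "unitless")
  binary_mask(v$values > 0.5, v$grid)
}

file_ext_lower <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) return("nii.gz")
  sub(".*\\.", "", p)
}

# --- MetaImage (ITK .mha/.mhd), little-endian raw payload ----------------

write_metaimage <- function(values, grid, unit, path, type = "MET_FLOAT") {
  ext <- file_ext_lower(path)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %.9g %.9g %.9g", grid$spacing[1],
            grid$spacing[2], grid$spacing[3]),
    sprintf("DimSize = %d %d %d", grid$shape[1], grid$shape[2],
            grid$shape[3]),
    sprintf("Comment = unit:%s", unit),
    sprintf("ElementType = %s", type)
  )
  payload <- as.vector(values)
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(header, "ElementDataFile = LOCAL"), con)
    write_raw_payload(con, payload, type)
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(header, sprintf("ElementDataFile = %s", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    write_raw_payload(con, payload, type)
  }
}

write_raw_payload <- function(con, payload, type) {
  if (type == "MET_FLOAT") {
    writeBin(as.numeric(payload), con, size = 4, endian = "little")
  } else if (type == "MET_UCHAR") {
    writeBin(as.raw(as.integer(payload)), con)
  } else stop("unsupported ElementType: ", type)
}

read_metaimage <- function(path) {
  ext <- file_ext_lower(path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  tags <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    tags[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementSpacing", "ElementType")
  if (!all(need %in% names(tags))) {
    stop("geometry missing in MetaImage header: ", path)
  }
  shape <- as.integer(strsplit(tags$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(tags$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(tags$Offset)) {
    as.numeric(strsplit(tags$Offset, "\\s+")[[1]])
  } else c(0, 0, 0)
  unit <- "unitless"
  if (!is.null(tags$Comment) && startsWith(tags$Comment, "unit:")) {
    unit <- sub("^unit:", "", tags$Comment)
  }
  n <- prod(shape)
  type <- tags$ElementType
  read_payload <- function(rcon) {
    if (type == "MET_FLOAT") {
      readBin(rcon, "numeric", n = n, size = 4, endian = "little")
    } else if (type == "MET_UCHAR") {
      as.numeric(readBin(rcon, "raw", n = n))
    } else stop("unsupported ElementType: ", type)
  }
  vals <- if (identical(tags$ElementDataFile, "LOCAL")) {
    read_payload(con)
  } else {
    rawpath <- file.path(dirname(path), tags$ElementDataFile)
    if (!file.exists(rawpath)) stop("raw payload not found: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    read_payload(rcon)
  }
  if (length(vals) != n) stop("payload size mismatch in ", path)
  dim(vals) <- shape
  list(values = vals, grid = grid3d(shape, spacing, origin), unit = unit)
}
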