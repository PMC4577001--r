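#' Read a CT volume from NIfTI or MetaImage
#'
#' Supports `.nii` / `.nii.gz` (via RNifti) and `.mhd` / `.mha`
#' (MetaImage).  Values are taken as stored (HU for CT exports), spacing
#' and origin are honored, and the grid axes are taken as the room axes
#' (x, y, z) in the fixed-room convention used throughout the package.
#' The stored offset is interpreted as the center of the first voxel and
#' converted to the package's grid-corner origin.
#'
#' @param path file path.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    sp <- attr(img, "pixdim")[1:3]
    q <- RNifti::xform(img)
    first_center <- q[1:3, 4]
    vals <- array(as.numeric(img), dim(img)[1:3])
    ct_volume(vals, spacing = sp, origin = first_center - sp / 2)
  } else if (grepl("\\.(mhd|mha)$", lower)) {
    read_metaimage(path)
  } else {
    stop("unsupported format: ", path, " (need .nii, .nii.gz, .mhd or .mha)")
  }
}

#' Write a CT volume
#'
#' Counterpart of [read_volume()]; the format follows the file extension.
#' Values round-trip bitwise (`.nii`/`.mha` store doubles).
#'
#' @param v a [ct_volume()].
#' @param path output path (`.nii`, `.nii.gz`, `.mhd` or `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  lower <- tolower(path)
  first_center <- v$origin + v$spacing / 2
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(v$values)
    aff <- diag(4)
    diag(aff)[1:3] <- v$spacing
    aff[1:3, 4] <- first_center
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::pixdim(img) <- v$spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.(mhd|mha)$", lower)) {
    write_metaimage(v, path)
  } else {
    stop("unsupported format: ", path)
  }
  invisible(path)
}

# minimal MetaImage (.mhd + .raw, or single-file .mha) reader/writer;
# little-endian, MET_DOUBLE/MET_FLOAT/MET_SHORT/MET_UCHAR element types
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, 1, warn = FALSE)
    if (length(line) == 0) break
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("format error in MetaImage header: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  for (k in need) if (is.null(hdr[[k]]))
    stop("format error: MetaImage header misses field ", k)
  if (hdr$NDims != "3") stop("format error: NDims must be 3")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  offset <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else spacing / 2
  type <- switch(hdr$ElementType,
                 MET_DOUBLE = list(what = "double", size = 8),
                 MET_FLOAT = list(what = "double", size = 4),
                 MET_SHORT = list(what = "integer", size = 2),
                 MET_UCHAR = list(what = "integer", size = 1),
                 stop("format error: unsupported ElementType ",
                      hdr$ElementType))
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, type$what, n = n, size = type$size, endian = "little",
                   signed = type$size > 1)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("file not found: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, type$what, n = n, size = type$size,
                   endian = "little", signed = type$size > 1)
  }
  if (length(raw) != n) stop("format error: truncated MetaImage data")
  ct_volume(array(as.numeric(raw), dims), spacing = spacing,
            origin = offset - spacing / 2)
}

write_metaimage <- function(v, path) {
  single <- grepl("\\.mha$", tolower(path))
  datafile <- if (single) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(v$values), collapse = " ")),
           paste("ElementSpacing =", paste(v$spacing, collapse = " ")),
           paste("Offset =", paste(v$origin + v$spacing / 2, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (single) {
    writeBin(as.numeric(v$values), con, size = 8, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(v$values), rcon, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read / write a radiograph image
#'
#' PNG and TIFF store counts scaled by 1/65535 (the 16-bit full-scale
#' convention): 16-bit PNGs read back as counts, and TIFF is written as
#' 32-bit float preserving sub-integer precision.  PNG *output* is 8-bit
#' (a display export; use TIFF or CSV to preserve counts).  `.csv` holds
#' the `[u, v]` pixel matrix verbatim.  PNG/TIFF images are stored with
#' `v` up / `u` right matching the detector axes.
#'
#' @param path image path (`.png`, `.tif`/`.tiff` or `.csv`).
#' @param pitch pixel pitch in mm.
#' @param view view label.
#' @return a [radiograph()].
#' @export
read_radiograph <- function(path, pitch, view = "custom") {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG radiographs")
    m <- png::readPNG(path) * 65535
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF radiographs")
    m <- tiff::readTIFF(path) * 65535
  } else if (grepl("\\.csv$", lower)) {
    px <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(px) <- NULL
    return(radiograph(px, pitch, view))
  } else {
    stop("unsupported radiograph format: ", path)
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  # image rows run top-down; detector v runs bottom-up
  px <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  dimnames(px) <- NULL
  radiograph(px, pitch, view)
}

#' @rdname read_radiograph
#' @param r a [radiograph()] to write.
#' @export
write_radiograph <- function(r, path) {
  stopifnot(inherits(r, "radiograph"))
  lower <- tolower(path)
  if (grepl("\\.csv$", lower)) {
    # CSV stores the [u, v] pixel matrix verbatim
    utils::write.table(r$pixels, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  m <- t(r$pixels)[rev(seq_len(ncol(r$pixels))), , drop = FALSE]
  if (grepl("\\.png$", lower)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to write PNG radiographs")
    png::writePNG(pmin(pmax(m / 65535, 0), 1), path)
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF radiographs")
    tiff::writeTIFF(pmin(pmax(m / 65535, 0), 1), path, bits.per.sample = 32)
  } else {
    stop("unsupported radiograph format: ", path)
  }
  invisible(path)
}

pose_as_list <- function(p) as.list(unclass(as_rigid_pose(p)))

#' Write registration or experiment results
#'
#' A [drr_register()] result is written as JSON (pose, per-stage trace,
#' final metric scores, configuration echo, package version).  A
#' [run_accuracy_experiment()] result writes `<stem>.csv` (one row per run:
#' run, metric_set, dx..dtheta, tre_mm, ae_deg, converged) and
#' `<stem>.json` (the mean +/- SD summary).
#'
#' @param x a `drr_registration` or `drr_experiment`.
#' @param path output path (`.json` for registrations; any stem for
#'   experiments).
#' @return the path(s) written, invisibly.
#' @export
write_result <- function(x, path) {
  if (inherits(x, "drr_registration")) {
    out <- list(
      software = paste("drrreg", as.character(utils::packageVersion("drrreg"))),
      pose = pose_as_list(x$pose),
      pose0 = pose_as_list(x$pose0),
      converged = x$converged,
      mode = x$mode,
      counts = as.list(x$counts),
      scores = lapply(x$scores, as.list),
      metrics = unclass(x$metrics),
      pyramid = unclass(x$pyramid),
      runtime_s = x$runtime,
      trace = x$trace)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(path))
  }
  if (inherits(x, "drr_experiment")) {
    stem <- sub("\\.(json|csv)$", "", path)
    csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
    utils::write.csv(x$runs, csv, row.names = FALSE)
    jsonlite::write_json(list(summary = x$summary,
                              n_excluded = x$n_excluded,
                              perturbation = pose_as_list(x$perturbation),
                              seed = x$seed),
                         json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(c(csv, json)))
  }
  stop("write_result understands drr_registration and drr_experiment objects")
}

#' Read back a registration result JSON
#'
#' @param path a file written by [write_result()].
#' @return a list with the stored fields; `$pose` is a [rigid_pose()].
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pose <- do.call(rigid_pose, as.list(x$pose))
  x$pose0 <- do.call(rigid_pose, as.list(x$pose0))
  x
}

#' Load a run configuration
#'
#' JSON schema: `volume`, `fpd_vertical`, `fpd_horizontal` (paths),
#' `geometry` (per-view `sad`/`sid`/`pitch`/`size` shorthand or explicit
#' source/detector), optional `roi` per view, `metrics`, `weights`, `bins`,
#' `pyramid`, `preprocess`, `experiment` (perturbation, repeats, seed) and
#' `pose0`.  Referenced paths must exist; violations name the offending
#' key.
#'
#' @param path JSON config path.
#' @return a validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("volume", "fpd_vertical", "fpd_horizontal")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config error at key '", key, "': file not found: ", cfg[[key]])
  }
  if (!is.null(cfg$metrics)) {
    bad <- setdiff(tolower(cfg$metrics), c("nmi", "gd", "zncc"))
    if (length(bad))
      stop("config error at key 'metrics': unknown metric ", bad[1])
  }
  if (!is.null(cfg$geometry)) {
    for (vw in names(cfg$geometry)) {
      gg <- cfg$geometry[[vw]]
      if (!is.null(gg$sad) && !is.null(gg$sid) && gg$sid <= gg$sad)
        stop("config error at key 'geometry.", vw, "': need sid > sad")
    }
  }
  structure(cfg, class = "run_config")
}

# expand a config geometry entry into a projection_geometry
config_geometry <- function(gg, view) {
  args <- list(view = view)
  for (k in c("sad", "sid", "pitch", "size")) if (!is.null(gg[[k]]))
    args[[k]] <- gg[[k]]
  do.call(projection_geometry, args)
}
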