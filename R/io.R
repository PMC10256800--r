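#' Read a volume from NIfTI or MetaImage
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`, via \pkg{RNifti}) and
#' MetaImage (`.mha` single-file or `.mhd` header plus raw).  Spacing and
#' origin are taken from the header; the data array is returned in x-fastest
#' order, matching the on-disk layout of both formats.
#'
#' @param path filesystem path to the volume.
#' @param frame_label optional label attached to the returned volume.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, frame_label = "") {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[^.]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
    if (length(dim(a)) != 3L)
      stop("dimensionality error: expected a 3D payload in ", path,
           " (got ", length(dim(a)), "D)", call. = FALSE)
    xf <- RNifti::xform(img)
    sp <- RNifti::pixdim(img)[1:3]
    or <- as.numeric(xf[1:3, 4])
    # the stored xform may be RAS-flipped; geometry convention here is the
    # axis-aligned one declared in the header translation + pixdim
    or <- or * sign(diag(xf)[1:3])
    v <- image_volume(a, spacing = sp, origin = or, frame_label = frame_label)
    return(v)
  }
  if (ext %in% c(".mha", ".mhd"))
    return(read_metaimage(path, frame_label))
  stop("format error: unsupported volume format ", sQuote(ext),
       " (use .nii, .nii.gz, .mha or .mhd)", call. = FALSE)
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param vol an [image_volume()].
#' @param path output path; format chosen by extension as in [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[^.]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(c(vol$spacing, 1))
    m[1:3, 4] <- vol$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (ext %in% c(".mha", ".mhd"))
    return(write_metaimage(vol, path))
  stop("format error: unsupported volume format ", sQuote(ext), call. = FALSE)
}

# ---- MetaImage (.mha/.mhd) -------------------------------------------------
# MetaImage is a plain key = value ASCII header optionally followed (mha) by
# the raw little-endian voxel block; no installed R package reads it, so the
# (small) format is handled here directly.

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_UINT = "integer",
                     MET_FLOAT = "double", MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                     MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                     MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path, frame_label = "") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("format error: MetaImage header has no ElementDataFile in ",
           path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("format error: malformed MetaImage header line: ", line,
           call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "0")
  if (ndims != 3L)
    stop("dimensionality error: expected NDims = 3, got ", ndims,
         call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  or <- as.numeric(strsplit(hdr[["Offset"]] %||% hdr[["Position"]] %||%
                              "0 0 0", "\\s+")[[1]])
  etype <- hdr[["ElementType"]] %||% "MET_FLOAT"
  if (!etype %in% names(metaimage_types))
    stop("format error: unsupported ElementType ", etype, call. = FALSE)
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    raw <- readBin(con, metaimage_types[[etype]], n = n,
                   size = metaimage_sizes[[etype]], endian = "little")
  } else {
    dpath <- file.path(dirname(path), data_file)
    if (!file.exists(dpath))
      stop("format error: ElementDataFile not found: ", dpath, call. = FALSE)
    dcon <- file(dpath, "rb")
    raw <- readBin(dcon, metaimage_types[[etype]], n = n,
                   size = metaimage_sizes[[etype]], endian = "little")
    close(dcon)
  }
  if (length(raw) != n)
    stop("format error: truncated MetaImage payload in ", path, call. = FALSE)
  image_volume(array(as.numeric(raw), dims), spacing = sp, origin = or,
               frame_label = frame_label)
}

write_metaimage <- function(vol, path) {
  ext <- tolower(sub("^.*(\\.[^.]+)$", "\\1", path))
  local <- ext == ".mha"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 15),
                                           collapse = " ")),
           paste("Offset =", paste(format(vol$origin, digits = 15),
                                   collapse = " ")),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "ElementType = MET_DOUBLE")
  if (local) {
    con <- file(path, "wb")
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
    close(con)
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste("ElementDataFile =", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tables, configuration, logging ----------------------------------------

#' Read / write the package's delimited tables
#'
#' All tabular artifacts (contrast curves, collagen grades, concordance
#' tables) are comma-separated UTF-8 text with a header row.
#'
#' @param path file path.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' @rdname read_table_csv
#' @param df data frame to write.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a YAML run configuration
#'
#' Configurations hold paths, thresholds and seeds for scripted runs.
#' Missing keys fall back to [lungfx_default_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- lungfx_default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

#' Default analysis configuration
#'
#' Thresholds follow the operative classification rules: high ventilation
#' at LER-N >= 1.2, low at <= 1.1, decline at a post/pre ratio < 0.94 and
#' increase at > 1.06.
#' @export
lungfx_default_config <- function() {
  list(high_min = 1.2, low_max = 1.1,
       decline_max = 0.94, increase_min = 1.06,
       tidal_volume_reference = 1.0,
       roi_ratio_method = "ratio_of_means",   # or "mean_of_ratios"
       auc_baseline_subtract = TRUE,
       dose_stat = "mean",                    # or "max"
       agreement_policy = default_agreement_policy(),
       seed = 1L)
}

#' Structured log line to stderr
#' @param stage pipeline stage name.
#' @param ... message parts, pasted.
#' @export
lfx_log <- function(stage, ...) {
  message(sprintf("[lungfx:%s] %s", stage, paste0(...)))
  invisible(NULL)
}
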