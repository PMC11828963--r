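# Micrograph containers, MRC 2014 / multi-page TIFF stack reading, and
# preprocessing to model-ready images.
#
# Images are stored as (rows, cols) matrices, row 1 = top of the image,
# 0-based pixel-center coordinates at integer positions (matching the
# annotation parser's (x = col, y = row) convention).

#' A single preprocessed micrograph with acquisition metadata
#'
#' @param image 2-D numeric matrix (>= 8 rows and columns)
#' @param pixel_size_A pixel size in Angstrom/pixel, or NA
#' @param source_id,lamella_id,series_id free-text identifiers
#' @param tilt_index integer >= 0, position within the tilt series
#' @export
micrograph <- function(image, pixel_size_A = NA_real_, source_id = "",
                       lamella_id = "", series_id = "", tilt_index = 0L) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < 8L || ncol(image) < 8L) {
    stop("micrograph image must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (!is.na(pixel_size_A) && pixel_size_A <= 0) {
    stop("pixel_size_A must be positive or NA", call. = FALSE)
  }
  structure(list(image = image, pixel_size_A = pixel_size_A,
                 source_id = source_id, lamella_id = lamella_id,
                 series_id = series_id, tilt_index = as.integer(tilt_index)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph %dx%d px, %s A/px, source='%s', tilt %d>\n",
              nrow(x$image), ncol(x$image),
              ifelse(is.na(x$pixel_size_A), "?", format(x$pixel_size_A)),
              x$source_id, x$tilt_index))
  invisible(x)
}

#' An ordered stack of micrographs from one tilt series file
#' @param micrographs list of [micrograph()] with identical dimensions and
#'   unique tilt indices
#' @param stack_path origin path (informational)
#' @export
tilt_series_stack <- function(micrographs, stack_path = "") {
  stopifnot(is.list(micrographs))
  if (length(micrographs) > 0) {
    dims <- vapply(micrographs, function(m) dim(m$image), integer(2))
    if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
      stop("all micrographs in a stack must share dimensions", call. = FALSE)
    }
    ti <- vapply(micrographs, function(m) m$tilt_index, integer(1))
    if (anyDuplicated(ti)) stop("tilt_index values must be unique", call. = FALSE)
  }
  structure(list(micrographs = micrographs, stack_path = stack_path),
            class = "tilt_series_stack")
}

#' @export
length.tilt_series_stack <- function(x) length(x$micrographs)

#' Binary crystalline/vitreous segmentation mask
#' @param mask 2-D matrix of 0/1 (1 = crystalline, i.e. non-vitrified)
#' @param image_ref identifier of the micrograph it labels
#' @export
seg_mask <- function(mask, image_ref = "") {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0/1", call. = FALSE)
  structure(list(mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
                 image_ref = image_ref), class = "seg_mask")
}

as_mask_matrix <- function(m) {
  if (inherits(m, "seg_mask")) m$mask else {
    stopifnot(is.matrix(m))
    m
  }
}

# --- MRC 2014 ------------------------------------------------------------------

mrc_mode_info <- function(mode) {
  switch(as.character(mode),
         "0" = list(what = "integer", size = 1L, signed = TRUE),
         "1" = list(what = "integer", size = 2L, signed = TRUE),
         "2" = list(what = "numeric", size = 4L, signed = TRUE),
         "6" = list(what = "integer", size = 2L, signed = FALSE),
         stop(sprintf("unsupported MRC mode %d (modes 0/1/2/6 supported)", mode),
              call. = FALSE))
}

#' Read an MRC 2014 image stack
#'
#' Little-endian MRC 2014 files, modes 0/1/2/6. Files flagged as volumes
#' (`ispg != 0`) are rejected: this reader is for micrograph stacks.
#' @param path file path
#' @return a [tilt_series_stack()]
#' @export
read_mrc_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024L)
  if (length(hdr) < 1024L) stop(sprintf("'%s' is not a valid MRC file (truncated header)", path), call. = FALSE)
  ints <- readBin(hdr, "integer", 256L, size = 4L, endian = "little")
  flts <- readBin(hdr, "numeric", 256L, size = 4L, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]
  xlen <- flts[11]
  ispg <- ints[23]; nsymbt <- ints[24]
  if (nx <= 0 || ny <= 0 || nz <= 0) {
    stop(sprintf("'%s' is not a valid MRC file (bad dimensions)", path), call. = FALSE)
  }
  if (ispg != 0L) {
    stop(sprintf("'%s' is flagged as a 3-D volume (ispg = %d), not a micrograph stack", path, ispg),
         call. = FALSE)
  }
  mi <- mrc_mode_info(mode)
  px <- if (mx > 0 && is.finite(xlen) && xlen > 0) xlen / mx else NA_real_
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  micros <- vector("list", nz)
  for (z in seq_len(nz)) {
    v <- readBin(con, mi$what, nx * ny, size = mi$size, signed = mi$signed,
                 endian = "little")
    if (length(v) < nx * ny) stop(sprintf("'%s': truncated slice %d", path, z), call. = FALSE)
    img <- t(matrix(as.numeric(v), nrow = nx))  # x fastest on disk -> cols
    micros[[z]] <- micrograph(img, pixel_size_A = px, source_id = basename(path),
                              tilt_index = z - 1L)
  }
  tilt_series_stack(micros, stack_path = path)
}

#' Write an MRC 2014 stack (float32)
#'
#' Fixture-grade writer used for round-trip tests and the synthetic export
#' path; always little-endian mode 2.
#' @param stack a [tilt_series_stack()] or list of matrices
#' @param path output path
#' @param pixel_size_A pixel size recorded in the cell header, or NA
#' @export
write_mrc_stack <- function(stack, path, pixel_size_A = NA_real_) {
  imgs <- if (inherits(stack, "tilt_series_stack")) {
    if (is.na(pixel_size_A) && length(stack) > 0) {
      pixel_size_A <- stack$micrographs[[1]]$pixel_size_A
    }
    lapply(stack$micrographs, function(m) m$image)
  } else if (is.matrix(stack)) list(stack) else stack
  stopifnot(length(imgs) >= 1L)
  ny <- nrow(imgs[[1]]); nx <- ncol(imgs[[1]])
  nz <- length(imgs)
  ih <- integer(256)
  ih[1:3] <- c(nx, ny, nz)
  ih[4] <- 2L                      # mode 2 = float32
  ih[8:10] <- c(nx, ny, nz)        # mx, my, mz
  ih[23] <- 0L                     # ispg = 0: stack
  ih[24] <- 0L                     # nsymbt
  hdr <- writeBin(ih, raw(), size = 4L, endian = "little")
  px <- if (is.na(pixel_size_A)) 1 else pixel_size_A
  cella <- writeBin(as.numeric(c(nx, ny, nz) * px), raw(), size = 4L, endian = "little")
  hdr[41:52] <- cella              # words 11-13
  all_vals <- unlist(lapply(imgs, function(m) as.vector(t(m))))
  dmin <- min(all_vals); dmax <- max(all_vals); dmean <- mean(all_vals)
  stats <- writeBin(as.numeric(c(dmin, dmax, dmean)), raw(), size = 4L, endian = "little")
  hdr[77:88] <- stats              # words 20-22
  hdr[209:212] <- charToRaw("MAP ")      # word 53
  hdr[213:216] <- as.raw(c(0x44, 0x44, 0x00, 0x00))  # little-endian stamp
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (m in imgs) writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  micros <- lapply(seq_along(pages), function(z) {
    img <- pages[[z]]
    if (length(dim(img)) == 3L) {
      warning("multi-channel TIFF page: using first channel", call. = FALSE)
      img <- img[, , 1L]
    }
    micrograph(img, source_id = basename(path), tilt_index = z - 1L)
  })
  tilt_series_stack(micros, stack_path = path)
}

#' Load a tilt-series micrograph stack (MRC 2014 or multi-page TIFF)
#'
#' @param path file path
#' @param fmt `"auto"` (by extension), `"mrc"` or `"tiff"`
#' @return a [tilt_series_stack()]; one micrograph per stored slice, in order,
#'   `tilt_index` = slice index (0-based); MRC pixel size propagated when the
#'   header records one.
#' @export
load_micrograph_stack <- function(path, fmt = c("auto", "mrc", "tiff")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("mrc", "mrcs", "st", "ali")) "mrc"
           else if (ext %in% c("tif", "tiff")) "tiff"
           else stop(sprintf("cannot infer format from extension '.%s'; pass fmt=", ext),
                     call. = FALSE)
  }
  if (fmt == "mrc") read_mrc_stack(path) else read_tiff_stack(path)
}

# --- preprocessing -------------------------------------------------------------

resize_bilinear <- function(img, out_rows, out_cols) {
  if (nrow(img) == out_rows && ncol(img) == out_cols) return(img)
  # EBImage maps w/h onto the first/second array dimension of a plain matrix
  out <- EBImage::imageData(EBImage::resize(img, w = out_rows, h = out_cols,
                                            filter = "bilinear"))
  matrix(out, out_rows, out_cols)
}

#' Preprocess a micrograph to a model-ready image
#'
#' Intensities are z-scored, clipped to `+/- clip_sigma` standard deviations,
#' rescaled to `[0, 1]`, and the image is resized (bilinear, aspect preserved)
#' so its longer side equals `target_long_side`. Constant images cannot be
#' z-scored and come back as all-0.5 with a warning. Metadata is carried
#' through unchanged.
#'
#' @param m a [micrograph()]
#' @param target_long_side target length of the longer side, >= 32
#' @param clip_sigma clipping bound in standard deviations (> 0)
#' @return a preprocessed [micrograph()]
#' @export
preprocess <- function(m, target_long_side = 1024L, clip_sigma = 3) {
  stopifnot(inherits(m, "micrograph"), clip_sigma > 0)
  if (target_long_side < 32L) stop("target_long_side must be >= 32", call. = FALSE)
  img <- m$image
  s <- stats::sd(img)
  if (!is.finite(s) || s == 0) {
    warning(sprintf("constant image '%s': z-scoring skipped, output is all 0.5",
                    m$source_id), call. = FALSE)
    img <- matrix(0.5, nrow(img), ncol(img))
  } else {
    img <- (img - mean(img)) / s
    img <- pmin(pmax(img, -clip_sigma), clip_sigma)
    img <- (img + clip_sigma) / (2 * clip_sigma)
  }
  d <- dim(img)
  if (d[1] >= d[2]) {
    out_rows <- as.integer(target_long_side)
    out_cols <- max(1L, as.integer(round(d[2] * target_long_side / d[1])))
  } else {
    out_cols <- as.integer(target_long_side)
    out_rows <- max(1L, as.integer(round(d[1] * target_long_side / d[2])))
  }
  img <- resize_bilinear(img, out_rows, out_cols)
  img[!is.finite(img)] <- 0.5
  micrograph(img, pixel_size_A = m$pixel_size_A, source_id = m$source_id,
             lamella_id = m$lamella_id, series_id = m$series_id,
             tilt_index = m$tilt_index)
}

#' Zero-pad an image (bottom/right) so both sides are multiples of `f`
#' @noRd
pad_to_multiple <- function(img, f) {
  d <- dim(img)
  H <- as.integer(ceiling(d[1] / f) * f)
  W <- as.integer(ceiling(d[2] / f) * f)
  if (H == d[1] && W == d[2]) return(list(image = img, orig = d))
  out <- matrix(0, H, W)
  out[seq_len(d[1]), seq_len(d[2])] <- img
  list(image = out, orig = d)
}

#' Export a mask as single-channel PNG (0/255)
#' @param mask a [seg_mask()] or 0/1 matrix
#' @param path output path
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m + 0, path)  # writePNG wants doubles; 0/1 maps to 0/255
  invisible(path)
}
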