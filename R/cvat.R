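# CVAT-for-images polygon annotations: parsing, fixture serialization, and
# rasterization to binary masks.
#
# CVAT stores points as "x1,y1;x2,y2;..." with x = column and y = row in image
# pixel coordinates (0-based, origin top-left). The conversion to the
# package's internal (row, col) matrix indexing happens only at this boundary.

#' A polygon annotation in image pixel coordinates
#'
#' @param vertices numeric matrix with columns `(col, row)` (CVAT x, y);
#'   at least 3 vertices
#' @param label annotation label text
#' @param image_name name of the annotated image
#' @export
polygon_annotation <- function(vertices, label = "ice", image_name = "") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L || !is.numeric(vertices)) {
    stop("a polygon needs a numeric n x 2 vertex matrix with n >= 3", call. = FALSE)
  }
  colnames(vertices) <- c("col", "row")
  structure(list(vertices = vertices, label = label, image_name = image_name),
            class = "polygon_annotation")
}

#' Parse polygons from a CVAT-for-images XML export
#'
#' @param xml_text XML document as a string, or a path to an XML file
#' @param label_filter optional character vector; keep only these labels.
#'   By default every label is treated as crystalline ice (binary problem).
#' @return list of [polygon_annotation()]
#' @export
parse_cvat_xml <- function(xml_text, label_filter = NULL) {
  if (length(xml_text) == 1L && !grepl("<", xml_text, fixed = TRUE) && file.exists(xml_text)) {
    xml_text <- paste(readLines(xml_text, warn = FALSE), collapse = "\n")
  }
  doc <- xml2::read_xml(xml_text)
  out <- list()
  for (img in xml2::xml_find_all(doc, ".//image")) {
    name <- xml2::xml_attr(img, "name")
    for (poly in xml2::xml_find_all(img, "./polygon")) {
      label <- xml2::xml_attr(poly, "label")
      pts <- xml2::xml_attr(poly, "points")
      pairs <- strsplit(strsplit(pts, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
      v <- suppressWarnings(t(vapply(pairs, function(p) as.numeric(p[1:2]), numeric(2))))
      if (anyNA(v) || nrow(v) < 3L) {
        stop(sprintf("malformed polygon points in image '%s': '%s'", name, pts),
             call. = FALSE)
      }
      if (!is.null(label_filter) && !(label %in% label_filter)) next
      out[[length(out) + 1L]] <- polygon_annotation(v, label = label, image_name = name)
    }
  }
  out
}

#' Serialize annotations to CVAT-for-images XML (fixture writer)
#'
#' @param annotations list of [polygon_annotation()]
#' @param width,height image dimensions recorded per image element
#' @param path optional output file; when NULL the XML text is returned
#' @export
write_cvat_xml <- function(annotations, width, height, path = NULL) {
  doc <- xml2::xml_new_root("annotations")
  xml2::xml_add_child(doc, "version", "1.1")
  by_img <- split(annotations,
                  vapply(annotations, function(a) a$image_name, character(1)))
  id <- 0L
  for (nm in names(by_img)) {
    img <- xml2::xml_add_child(doc, "image", id = as.character(id), name = nm,
                               width = as.character(width),
                               height = as.character(height))
    id <- id + 1L
    for (a in by_img[[nm]]) {
      pts <- paste(apply(a$vertices, 1L, function(v)
        paste0(format(v[1], trim = TRUE, scientific = FALSE), ",",
               format(v[2], trim = TRUE, scientific = FALSE))), collapse = ";")
      xml2::xml_add_child(img, "polygon", label = a$label, points = pts,
                          occluded = "0", source = "manual")
    }
  }
  txt <- as.character(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Even-odd point-in-polygon test with boundary counted as inside
#' @noRd
pip_evenodd <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    d <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg <- abs(d) < tol &
      px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_edge <- on_edge | seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Rasterize polygon annotations to a binary mask
#'
#' A pixel is set to 1 iff its center (integer grid position, 0-based, origin
#' top-left) lies inside or on the boundary of any polygon (union, even-odd
#' rule). Vertices outside the valid frame are clipped to it.
#'
#' @param annotations list of [polygon_annotation()] (possibly empty)
#' @param height,width mask dimensions in pixels
#' @return a [seg_mask()]
#' @export
rasterize <- function(annotations, height, width) {
  stopifnot(height >= 1L, width >= 1L)
  mask <- matrix(0L, height, width)
  for (a in annotations) {
    vx <- pmin(pmax(a$vertices[, "col"], -0.5), width - 0.5)
    vy <- pmin(pmax(a$vertices[, "row"], -0.5), height - 0.5)
    c0 <- max(0L, floor(min(vx))); c1 <- min(width - 1L, ceiling(max(vx)))
    r0 <- max(0L, floor(min(vy))); r1 <- min(height - 1L, ceiling(max(vy)))
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1
    rows <- r0:r1
    px <- rep(cols, each = length(rows))
    py <- rep(rows, times = length(cols))
    hit <- pip_evenodd(px, py, vx, vy)
    if (any(hit)) {
      mask[cbind(py[hit] + 1L, px[hit] + 1L)] <- 1L
    }
  }
  ref <- if (length(annotations)) annotations[[1]]$image_name else ""
  seg_mask(mask, image_ref = ref)
}

#' Signed polygon area by the shoelace formula (oracle utility)
#' @param vertices n x 2 matrix of (col, row) vertices
#' @return absolute enclosed area in square pixels
#' @export
shoelace_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
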