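#' Construct a raster trace
#'
#' A raster trace is the binary image of a digitised enamel-band outline:
#' a 0/1 pixel matrix in which 1 marks the traced ink.
#'
#' @param pixels integer or logical matrix; non-zero entries are foreground.
#' @param specimen_id character scalar identifying the specimen.
#' @return An object of class \code{raster_trace}: a list with elements
#'   \code{pixels} (integer matrix of 0/1), \code{width}, \code{height}
#'   (pixel counts) and \code{specimen_id}.
#' @export
raster_trace <- function(pixels, specimen_id = NA_character_) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("trace must be at least 2 x 2 pixels")
  px <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  structure(
    list(pixels = px, width = ncol(px), height = nrow(px),
         specimen_id = as.character(specimen_id)),
    class = "raster_trace")
}

#' @export
print.raster_trace <- function(x, ...) {
  cat(sprintf("raster_trace '%s': %d x %d px, %d foreground\n",
              x$specimen_id, x$height, x$width, sum(x$pixels)))
  invisible(x)
}

#' Threshold a grayscale image matrix to binary foreground
#'
#' Polarity: the traced enamel line is assumed to be dark ink on a light
#' background, so pixels with luminance strictly below \code{threshold}
#' become foreground (1). Set \code{invert = TRUE} for light-on-dark
#' images. Thresholding an already binary 0/1 image at the default
#' threshold returns it unchanged (idempotence): 0 is ink, 1 is ground.
#'
#' @param gray numeric matrix of luminance values in [0, 1].
#' @param threshold gray level in [0, 1]; default 0.5.
#' @param invert if TRUE, foreground = luminance strictly above threshold.
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize <- function(gray, threshold = 0.5, invert = FALSE) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  fg <- if (invert) gray > threshold else gray < threshold
  matrix(as.integer(fg), nrow(gray), ncol(gray))
}

#' Read an enamel-trace image as a binary raster
#'
#' Reads a PNG or TIFF image (8/16-bit gray or RGB; any alpha channel is
#' ignored), converts RGB to luminance (Rec. 601 weights 0.299, 0.587,
#' 0.114), and thresholds it with [binarize()]. The image format is taken
#' from the file extension.
#'
#' @param path path to a .png, .tif or .tiff file.
#' @param threshold gray level in [0, 1] passed to [binarize()].
#' @param invert passed to [binarize()].
#' @param specimen_id identifier stored on the trace; defaults to the
#'   file name without extension.
#' @return a [raster_trace()].
#' @export
read_trace <- function(path, threshold = 0.5, invert = FALSE,
                       specimen_id = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)"))
  gray <- luminance(img)
  px <- binarize(gray, threshold = threshold, invert = invert)
  if (sum(px) == 0L) stop("empty trace: no foreground pixels in ", path)
  if (is.null(specimen_id))
    specimen_id <- tools::file_path_sans_ext(basename(path))
  raster_trace(px, specimen_id = specimen_id)
}

# Collapse a decoded image array to a [0,1] luminance matrix.
# 3rd-dim layout: 1 = gray, 2 = gray+alpha, 3 = RGB, 4 = RGBA.
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  nc <- dim(img)[3]
  if (nc == 1L) img[, , 1]
  else if (nc == 2L) img[, , 1]
  else 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Write a raster trace to a PNG file
#'
#' Foreground pixels are written black (0), background white (1), so that
#' [read_trace()] at the default polarity round-trips the trace.
#'
#' @param trace a [raster_trace()].
#' @param path output .png path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raster_trace"))
  png::writePNG(1 - trace$pixels, path)
  invisible(path)
}

valid_tooth_positions <- c("P3", "P4", "M1", "M2")
valid_tribes <- c("Hipparionini", "Equini")

#' Load a specimen metadata table
#'
#' Reads a CSV with columns \code{specimen_id}, \code{taxon},
#' \code{tribe}, \code{tooth_position}, \code{area_cm2}. Rows with tooth
#' positions outside P3--M2 are excluded (tooth position is known to
#' affect occlusal enamel complexity at the P2 and M3) and the exclusion
#' count is reported as an attribute and a message. Missing areas are
#' kept as NA: such specimens contribute to D-only analyses but are
#' dropped from area-dependent regressions downstream.
#'
#' @param path CSV file path, or a data.frame already in that shape.
#' @return data.frame with columns \code{specimen_id}, \code{taxon},
#'   \code{tribe}, \code{tooth_position}, \code{area} and attribute
#'   \code{n_excluded}.
#' @export
load_specimens <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "taxon", "tribe", "tooth_position")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("specimen table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"area" %in% names(df)) {
    if (!"area_cm2" %in% names(df))
      stop("specimen table lacks an area_cm2 column")
    df$area <- df$area_cm2
  }
  if (nrow(df) == 0L) {
    warning("empty specimen table")
    out <- df[, c("specimen_id", "taxon", "tribe", "tooth_position", "area")]
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  if (anyDuplicated(df$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]),
               collapse = ", "))
  bad_tribe <- setdiff(unique(df$tribe), valid_tribes)
  if (length(bad_tribe))
    stop("unknown tribe label(s): ", paste(bad_tribe, collapse = ", "))
  keep <- df$tooth_position %in% valid_tooth_positions
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(n_excluded, " specimen(s) excluded: tooth position outside P3-M2")
  out <- df[keep, c("specimen_id", "taxon", "tribe", "tooth_position", "area")]
  if (any(!is.na(out$area) & out$area <= 0))
    stop("occlusal area must be positive where present")
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Normalize a taxon name for matching across tables and tree tips
#'
#' Strips quotation marks and asterisks (typographic conventions for
#' questionable generic assignments), collapses whitespace, and maps
#' underscores (newick convention) to spaces.
#'
#' @param x character vector of taxon names.
#' @return normalized character vector.
#' @export
normalize_taxon <- function(x) {
  x <- gsub("[\"'“”‘’*]", "", x)
  x <- gsub("_", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Summarise specimen records to species means
#'
#' Computes per-taxon n, mean and sample SD (n - 1 denominator) for D
#' and for occlusal area separately; specimens with missing area are
#' ignored for the area columns only. SD is NA for n = 1 and taxa with
#' no area observations get \code{n_area = 0}, matching the convention
#' of published species-summary tables. Species averages are what the
#' phylogenetic regressions consume.
#'
#' @param records data.frame with columns \code{taxon}, \code{tribe},
#'   \code{D} and optionally \code{area}.
#' @return data.frame with one row per taxon: \code{tribe}, \code{taxon},
#'   \code{n_D}, \code{mean_D}, \code{sd_D}, \code{n_area},
#'   \code{mean_area}, \code{sd_area}, ordered by tribe then taxon.
#' @export
summarize_species <- function(records) {
  stopifnot(all(c("taxon", "D") %in% names(records)))
  if (anyNA(records$D)) stop("every record must carry a D value")
  if (!"area" %in% names(records)) records$area <- NA_real_
  if (!"tribe" %in% names(records)) records$tribe <- NA_character_
  sp <- split(records, records$taxon)
  rows <- lapply(sp, function(g) {
    a <- g$area[!is.na(g$area)]
    data.frame(
      tribe = g$tribe[1], taxon = g$taxon[1],
      n_D = nrow(g), mean_D = mean(g$D),
      sd_D = if (nrow(g) > 1L) stats::sd(g$D) else NA_real_,
      n_area = length(a),
      mean_area = if (length(a)) mean(a) else NA_real_,
      sd_area = if (length(a) > 1L) stats::sd(a) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tribe, out$taxon), ]
  rownames(out) <- NULL
  out
}
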