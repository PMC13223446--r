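# File I/O: grayscale images as PNG / TIFF / single-slice NIfTI-1, masks
# as {0, 255} PNG, decision systems as CSV (first column object id, last
# column decision), network checkpoints as JSON, configs as YAML, dataset
# manifests as CSV.

#' Write a grayscale image
#'
#' Format is chosen from the file extension: `.png` (8-bit), `.tif` /
#' `.tiff` (8- or 16-bit integer), `.nii` / `.nii.gz` (single-slice
#' NIfTI-1 volume, float).
#'
#' @param img image matrix in `[0, 1]`.
#' @param path output path.
#' @param bits TIFF bit depth, 8 or 16 (default 16).
#' @return the path, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  check_image(img)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(array(img, dim = c(dim(img), 1L))),
                       path)
  } else if (ext == "png") {
    png::writePNG(clip01(img), path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
    tiff::writeTIFF(clip01(img), path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' Read a grayscale image
#'
#' @param path a PNG, TIFF, or NIfTI-1 file.
#' @return numeric image matrix in `[0, 1]` (NIfTI volumes are reduced to
#'   their first slice; multi-channel rasters to the first channel).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    v <- as.array(RNifti::readNifti(path))
    img <- if (length(dim(v)) >= 3) v[, , 1] else v
    return(minmax_clamp(img))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image extension: ", ext))
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  minmax_clamp(raw)
}

# clamp without stretching; rescale only if the source exceeds [0, 1]
minmax_clamp <- function(img) {
  if (min(img) < 0 || max(img) > 1) {
    img <- (img - min(img)) / max(max(img) - min(img), .Machine$double.eps)
  }
  img
}

#' Write a binary mask as a {0, 255} PNG
#' @param mask logical (or 0/1) matrix.
#' @param path output path (`.png`).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a {0, 255} PNG mask
#' @param path mask file.
#' @return logical matrix.
#' @export
read_mask <- function(path) read_image(path) > 0.5

#' Read a decision system from CSV
#'
#' Layout: first column object id, last column decision, middle columns
#' conditional attributes.
#'
#' @param path CSV file.
#' @return a [decision_system()].
#' @export
read_decision_system <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("decision-system CSV needs id, attributes, decision")
  decision_system(df[, -c(1, ncol(df)), drop = FALSE],
                  df[[ncol(df)]], ids = df[[1]])
}

#' Write a decision system to CSV
#' @param ds a [decision_system()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_decision_system <- function(ds, path) {
  df <- cbind(data.frame(id = ds$ids), ds$attributes,
              data.frame(decision = ds$decision))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save a rough network checkpoint as JSON
#' @param net a `rough_network`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_network <- function(net, path) {
  payload <- list(
    layer_sizes = net$layer_sizes,
    classes = net$classes,
    half_width = net$half_width,
    layers = lapply(net$layers, function(ly) {
      list(w_low = as.vector(ly$w_low), w_up = as.vector(ly$w_up),
           b_low = ly$b_low, b_up = ly$b_up,
           dim = dim(ly$w_low))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a rough network checkpoint
#' @param path JSON checkpoint written by [write_network()].
#' @return a `rough_network`.
#' @export
read_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow_or_len(p$layers)), function(i) {
    ly <- if (is.data.frame(p$layers)) lapply(p$layers, `[[`, i) else p$layers[[i]]
    d <- unlist(ly$dim)
    list(w_low = matrix(unlist(ly$w_low), d[1], d[2]),
         w_up = matrix(unlist(ly$w_up), d[1], d[2]),
         b_low = unlist(ly$b_low), b_up = unlist(ly$b_up))
  })
  structure(list(layers = layers,
                 layer_sizes = as.integer(unlist(p$layer_sizes)),
                 classes = unlist(p$classes),
                 half_width = p$half_width),
            class = "rough_network")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Write a dataset manifest
#' @param manifest data frame with columns like `path`, `stage`, `seed`,
#'   `transform`.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
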