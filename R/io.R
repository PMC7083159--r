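# Readers and writers for the package's plain-text interchange formats:
# box annotations (RSNA dialect `patientId,x,y,width,height,Target` and the
# generic `image_id,x,y,width,height[,confidence]`), per-model class
# probability tables, and relevance-map serialization (max-scaled PNG
# preview + lossless CSV + JSON sidecar).

#' Convert an RSNA-dialect manifest to the internal ground-truth table
#'
#' `Target = 1` rows carry `(x, y, width, height)` boxes, converted to
#' 0-based half-open `[x, x + width) x [y, y + height)`; `Target = 0` rows
#' have empty coordinates and mark box-less (normal) images.
#'
#' @param df Data frame with columns `patientId, x, y, width, height,
#'   Target`.
#' @return Ground-truth data frame (`image_id, x_min, y_min, x_max,
#'   y_max`; NA coordinates for box-less records).
#' @export
rsna_to_gt <- function(df) {
  need <- c("patientId", "x", "y", "width", "height", "Target")
  if (!all(need %in% names(df))) stop("not an RSNA-dialect table")
  bad <- which(df$Target == 1 & (is.na(df$width) | is.na(df$height) |
                                   df$width <= 0 | df$height <= 0))
  if (length(bad))
    stop("non-positive box dimensions in row(s) ", paste(bad, collapse = ", "))
  data.frame(image_id = as.character(df$patientId),
             x_min = ifelse(df$Target == 1, df$x, NA_real_),
             y_min = ifelse(df$Target == 1, df$y, NA_real_),
             x_max = ifelse(df$Target == 1, df$x + df$width, NA_real_),
             y_max = ifelse(df$Target == 1, df$y + df$height, NA_real_),
             stringsAsFactors = FALSE)
}

#' Read box annotations or detections from CSV
#'
#' Dialects are recognized by header: RSNA (`patientId,x,y,width,height,
#' Target`), generic ground truth (`image_id,x,y,width,height`), and
#' detections (`image_id,x,y,width,height,confidence`). All are converted
#' to 0-based half-open boxes; rows with non-positive width or height are
#' rejected with the offending row number.
#'
#' @param path CSV file.
#' @return Ground-truth data frame, or a detection data frame when the
#'   header carries `confidence`.
#' @export
read_boxes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("patientId" %in% names(df)) return(rsna_to_gt(df))
  if (!all(c("image_id", "x", "y", "width", "height") %in% names(df)))
    stop("unrecognized box CSV header in ", path)
  bad <- which(df$width <= 0 | df$height <= 0)
  if (length(bad))
    stop("non-positive box dimensions in row(s) ", paste(bad, collapse = ", "))
  out <- data.frame(image_id = as.character(df$image_id),
                    x_min = df$x, y_min = df$y,
                    x_max = df$x + df$width, y_max = df$y + df$height,
                    stringsAsFactors = FALSE)
  if ("confidence" %in% names(df)) out$confidence <- df$confidence
  out
}

#' Write detections or ground truth to the generic CSV dialect
#'
#' Inverse of [read_boxes_csv()]: half-open boxes become
#' `(x, y, width, height)`; a `confidence` column is carried through when
#' present. Box-less (NA) ground-truth rows are dropped.
#'
#' @param boxes Detection or ground-truth data frame.
#' @param path Output CSV file.
#' @export
write_boxes_csv <- function(boxes, path) {
  b <- boxes[!is.na(boxes$x_min), , drop = FALSE]
  out <- data.frame(image_id = b$image_id, x = b$x_min, y = b$y_min,
                    width = b$x_max - b$x_min, height = b$y_max - b$y_min)
  if ("confidence" %in% names(b)) out$confidence <- b$confidence
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-model class-probability tables
#'
#' CSV dialect `image_id,p_abnormal,p_normal`; the model id is stored as a
#' comment-free side fact (the file name stem on read, unless given).
#'
#' @param path CSV file.
#' @param model_id Model identifier; defaults to the file name stem.
#' @return A [probability_table()].
#' @export
read_probability_csv <- function(path, model_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "p_abnormal", "p_normal") %in% names(df)))
    stop("unrecognized probability CSV header in ", path)
  probability_table(df$p_abnormal, df$p_normal,
                    model_id = model_id %||%
                      tools::file_path_sans_ext(basename(path)),
                    image_id = df$image_id)
}

#' @rdname read_probability_csv
#' @param table A [probability_table()].
#' @export
write_probability_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a relevance map
#'
#' Writes three files sharing one stem: a max-scaled 8-bit grayscale PNG
#' preview, a lossless CSV of the raw scores, and a JSON sidecar
#' `{source_id, raw_max, map_shape, input_size}` from which the raw scale
#' is recoverable.
#'
#' @param map A [relevance_map()].
#' @param stem Output path without extension.
#' @return The sidecar path, invisibly.
#' @export
write_relevance_map <- function(map, stem) {
  v <- unclass(map)
  mx <- max(v)
  png::writePNG(if (mx > 0) v / mx else v, paste0(stem, ".png"))
  utils::write.table(v, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(source_id = attr(map, "source_id"),
                            raw_max = mx,
                            map_shape = dim(v),
                            input_size = attr(map, "input_size")),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_relevance_map
#' @export
read_relevance_map <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ","))
  dimnames(v) <- NULL
  relevance_map(v, source_id = meta$source_id, input_size = meta$input_size)
}

#' Read a grayscale image (PNG or TIFF) as a numeric matrix
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path Image file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                           c(1, 2), mean)
  img
}
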