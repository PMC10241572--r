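# ImageJ .roi rectangle parser/writer and tabular annotation I/O.
# The .roi header is big-endian: "Iout" magic, version short, type byte at
# offset 6 (1 = rectangle), then top/left/bottom/right as signed shorts at
# offsets 8/10/12/14; the full header is 64 bytes.

.be16 <- function(x) as.raw(c((x %/% 256) %% 256, x %% 256))

#' Read a rectangle from an ImageJ `.roi` file
#'
#' Parses the binary ImageJ ROI format (big-endian, magic bytes `"Iout"`)
#' and returns the rectangle as a 0-based, top-left-origin, half-open box.
#' Only rectangle ROIs are accepted.
#'
#' @param path path to a `.roi` file.
#' @return numeric length-4 `(x0, y0, width, height)` with
#'   `width = right - left`, `height = bottom - top`.
#' @export
read_imagej_roi <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 64 || rawToChar(r[1:4]) != "Iout")
    stop("not an ImageJ ROI file (missing 'Iout' magic): ", path)
  u16 <- function(off) 256L * as.integer(r[off + 1L]) + as.integer(r[off + 2L])
  type <- as.integer(r[7L])      # offset 6, 0-based
  if (type != 1L) stop("only rectangle ROIs are supported (type byte ", type, ")")
  top <- u16(8L); left <- u16(10L); bottom <- u16(12L); right <- u16(14L)
  w <- right - left; h <- bottom - top
  if (w < 1 || h < 1) stop("degenerate (zero-area) rectangle ROI")
  c(x0 = left, y0 = top, width = w, height = h)
}

#' Write a rectangle as an ImageJ `.roi` file
#'
#' @param box numeric length-4 `(x0, y0, width, height)`, 0-based half-open.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_imagej_roi <- function(box, path) {
  stopifnot(length(box) == 4)
  box <- as.integer(box)
  if (box[3] < 1 || box[4] < 1) stop("box width and height must be >= 1")
  hdr <- raw(64)
  hdr[1:4] <- charToRaw("Iout")
  hdr[5:6] <- .be16(228L)        # header version
  hdr[7] <- as.raw(1L)           # rectangle
  hdr[9:10] <- .be16(box[2])               # top
  hdr[11:12] <- .be16(box[1])              # left
  hdr[13:14] <- .be16(box[2] + box[4])     # bottom
  hdr[15:16] <- .be16(box[1] + box[3])     # right
  con <- file(path, "wb")
  writeBin(hdr, con)
  close(con)
  invisible(path)
}

#' Read a tabular annotation manifest
#'
#' Reads a CSV with columns `patient_id, slice_index, x0, y0, width, height,
#' label` into a list of [box_annotation()] objects, preserving row order.
#' Label strings not present in `allowed_labels` are rejected.
#'
#' @param path CSV file path.
#' @param allowed_labels character vector of permitted class labels; `NULL`
#'   disables the check.
#' @return list of [box_annotation()].
#' @export
read_annotation_table <- function(path, allowed_labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "slice_index", "x0", "y0", "width", "height", "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  if (!is.null(allowed_labels)) {
    bad <- setdiff(unique(df$label), allowed_labels)
    if (length(bad))
      stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    box_annotation(df$patient_id[i], df$slice_index[i],
                   c(df$x0[i], df$y0[i], df$width[i], df$height[i]),
                   df$label[i])
  })
}

#' Write annotations as a CSV table
#'
#' @param annotations list of [box_annotation()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_annotation_table <- function(annotations, path) {
  df <- annotations_to_df(annotations)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert a list of annotations to a data frame
#' @param annotations list of [box_annotation()].
#' @return data frame with one row per annotation.
#' @export
annotations_to_df <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(patient_id = a$patient_id, slice_index = a$slice_index,
               x0 = a$box[1], y0 = a$box[2], width = a$box[3],
               height = a$box[4], label = a$label,
               stringsAsFactors = FALSE)
  }))
}

#' Map class labels to the binary coding used by the classifier
#'
#' The positive class is the disease the study's confusion-matrix
#' definitions treat as positive (appendicitis in the clinical setting;
#' `"tubular"` for the phantom generator).
#'
#' @param labels character vector of class labels.
#' @param positive_label the label mapped to 1.
#' @return numeric vector of 0/1.
#' @export
labels_to_binary <- function(labels, positive_label) {
  as.numeric(labels == positive_label)
}
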