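#' Read a Pascal VOC XML annotation file
#'
#' Parses the annotation dialect used by the BCCD blood-cell dataset (one
#' XML file per image; `size` with `width`/`height`/`depth`; one `object`
#' element per box with `name` and a `bndbox` holding 1-based inclusive
#' `xmin`, `ymin`, `xmax`, `ymax`). Unknown elements are ignored and class
#' names are preserved verbatim ("RBC", "WBC", "Platelets" in BCCD).
#'
#' @param path path to the XML file.
#' @return A `voc_record` list: `filename`, `width`, `height`, `depth`, and
#'   `objects` (data frame `class`, `xmin`, `ymin`, `xmax`, `ymax`).
#' @seealso [write_voc_xml()], [voc_to_internal()]
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "./size")
  num <- function(node, tag) {
    v <- xml2::xml_text(xml2::xml_find_first(node, paste0("./", tag)))
    suppressWarnings(as.numeric(v))
  }
  width <- num(size, "width"); height <- num(size, "height")
  depth <- num(size, "depth")
  filename <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  objs <- xml2::xml_find_all(doc, "./object")
  rows <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    cls <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    bb <- xml2::xml_find_first(o, "./bndbox")
    if (inherits(bb, "xml_missing")) {
      stop("missing bndbox for object ", i, " in ", path)
    }
    co <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(t) num(bb, t),
                 numeric(1))
    if (anyNA(co)) {
      stop("missing bndbox coordinate for object ", i, " in ", path)
    }
    data.frame(class = cls, xmin = co[["xmin"]], ymin = co[["ymin"]],
               xmax = co[["xmax"]], ymax = co[["ymax"]],
               stringsAsFactors = FALSE)
  })
  objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), xmin = numeric(0), ymin = numeric(0),
               xmax = numeric(0), ymax = numeric(0), stringsAsFactors = FALSE)
  rec <- voc_record(filename = filename, width = width, height = height,
                    depth = depth, objects = objects)
  rec
}

#' Construct and validate a VOC annotation record
#'
#' @param filename image file name the annotation refers to.
#' @param width,height,depth image dimensions in pixels; depth is 1 or 3.
#' @param objects data frame with `class` and 1-based inclusive `xmin`,
#'   `ymin`, `xmax`, `ymax`.
#' @return A `voc_record` list.
#' @export
voc_record <- function(filename, width, height, depth = 3,
                       objects = data.frame()) {
  stopifnot(is.finite(width), is.finite(height), width >= 1, height >= 1)
  if (!depth %in% c(1, 3)) stop("depth must be 1 or 3")
  if (nrow(objects)) {
    bad <- objects$xmin < 1 | objects$ymin < 1 |
      objects$xmax < objects$xmin | objects$ymax < objects$ymin |
      objects$xmax > width | objects$ymax > height
    if (any(bad)) {
      stop("invalid bndbox for object(s) ",
           paste(which(bad), collapse = ", "),
           " (need 1 <= xmin <= xmax <= width, 1 <= ymin <= ymax <= height)")
    }
  }
  structure(list(filename = filename, width = width, height = height,
                 depth = depth, objects = objects), class = "voc_record")
}

#' Write a VOC annotation record to XML
#'
#' `read_voc_xml(write_voc_xml(rec, path))` reproduces `rec`'s semantic
#' content (filename, size, classes and coordinates).
#'
#' @param record a [voc_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(record, path) {
  stopifnot(inherits(record, "voc_record"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", record$filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(record$width))
  xml2::xml_add_child(size, "height", format(record$height))
  xml2::xml_add_child(size, "depth", format(record$depth))
  xml2::xml_add_child(doc, "segmented", "0")
  if (nrow(record$objects)) {
    for (i in seq_len(nrow(record$objects))) {
      o <- record$objects[i, ]
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", o$class)
      xml2::xml_add_child(obj, "pose", "Unspecified")
      xml2::xml_add_child(obj, "truncated", "0")
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", format(o$xmin))
      xml2::xml_add_child(bb, "ymin", format(o$ymin))
      xml2::xml_add_child(bb, "xmax", format(o$xmax))
      xml2::xml_add_child(bb, "ymax", format(o$ymax))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Convert between VOC and internal box coordinates
#'
#' VOC boxes are 1-based with inclusive upper edges; internal boxes are
#' 0-based half-open. The conversion `(xmin, ymin, xmax, ymax) ->
#' (xmin - 1, ymin - 1, xmax, ymax)` preserves widths and heights
#' (`xmax - xmin + 1` inclusive equals `xmax - (xmin - 1)` half-open) and
#' composes with [internal_to_voc()] to the identity.
#'
#' @param box data frame with `xmin`, `ymin`, `xmax`, `ymax` (other columns
#'   pass through untouched).
#' @return The box table in the other convention.
#' @examples
#' voc_to_internal(data.frame(xmin = 1, ymin = 1, xmax = 10, ymax = 10))
#' @export
voc_to_internal <- function(box) {
  box$xmin <- box$xmin - 1
  box$ymin <- box$ymin - 1
  box
}

#' @rdname voc_to_internal
#' @export
internal_to_voc <- function(box) {
  box$xmin <- box$xmin + 1
  box$ymin <- box$ymin + 1
  box
}

#' Convert a scene's ground truth to a VOC record, and back
#'
#' @param scene a [generate_scene()] result.
#' @return `scene_to_voc()`: a [voc_record()] (coordinates converted to the
#'   VOC convention); `voc_to_gt()`: an internal-coordinate ground-truth
#'   table with `image_id` taken from the record's filename stem.
#' @export
scene_to_voc <- function(scene) {
  gt <- internal_to_voc(scene$gt)
  voc_record(filename = paste0(scene$image_id, ".jpg"),
             width = scene$width, height = scene$height, depth = 3,
             objects = gt[c("class", "xmin", "ymin", "xmax", "ymax")])
}

#' @rdname scene_to_voc
#' @param record a [voc_record()].
#' @export
voc_to_gt <- function(record) {
  image_id <- sub("\\.[A-Za-z]+$", "", record$filename)
  obj <- voc_to_internal(record$objects)
  data.frame(image_id = image_id, class = obj$class,
             xmin = obj$xmin, ymin = obj$ymin,
             xmax = obj$xmax, ymax = obj$ymax,
             stringsAsFactors = FALSE)
}

#' Seeded random train/test split of image ids
#'
#' Uniform partition without replacement; the training set holds
#' `round(N * fraction_train)` ids using round-half-away-from-zero (364
#' images at 80% give 291 training and 73 test images). Deterministic for a
#' given seed.
#'
#' @param image_ids vector of at least two ids.
#' @param fraction_train training proportion in (0, 1).
#' @param seed RNG seed for the draw.
#' @return A `split_spec` list: `train`, `test`, `fraction_train`, `seed`.
#' @examples
#' split_dataset(sprintf("im%03d", 1:10), 0.8, seed = 1)
#' @export
split_dataset <- function(image_ids, fraction_train = 0.80, seed = 1) {
  n <- length(image_ids)
  if (n < 2L) stop("need at least 2 image ids to split")
  if (fraction_train <= 0 || fraction_train >= 1) {
    stop("fraction_train must lie strictly between 0 and 1")
  }
  n_train <- as.integer(round_half_up(n * fraction_train))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  structure(list(
    train = image_ids[sort(idx)],
    test = image_ids[sort(setdiff(seq_len(n), idx))],
    fraction_train = fraction_train, seed = seed
  ), class = "split_spec")
}

#' Persist or reload a split specification as JSON
#'
#' @param split a [split_dataset()] result.
#' @param path file path.
#' @return `write_split()` returns `path` invisibly; `read_split()` the
#'   `split_spec`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("train", "test", "fraction_train", "seed")],
            class = "split_spec")
}
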