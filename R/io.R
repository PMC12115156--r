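# Dataset writers/readers for the two de-facto annotation formats:
# per-image YOLO text labels and single-file COCO JSON.

#' Write scenes to disk as an annotated detection dataset
#'
#' YOLO format: `images/scene_%04d.png` plus `labels/scene_%04d.txt` with
#' one `class cx cy w h` line per object (normalised centre coordinates).
#' COCO format: the same images plus one `annotations.json` with the
#' standard `images` / `annotations` / `categories` fields and `xywh` pixel
#' boxes.
#'
#' @param scenes list of scenes (`$image`, `$boxes`).
#' @param out_dir output directory (created if missing).
#' @param format `"yolo"` or `"coco"`.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(scenes, out_dir, format = c("yolo", "coco")) {
  format <- match.arg(format)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create output directory: ", out_dir)
  anns <- list(); imgs <- list()
  if (format == "yolo")
    dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
  aid <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    h <- dim(sc$image)[1]; w <- dim(sc$image)[2]
    name <- sprintf("scene_%04d", i)
    png::writePNG(sc$image, file.path(img_dir, paste0(name, ".png")))
    b <- sc$boxes
    if (format == "yolo") {
      lines <- character(0)
      if (!is.null(b) && nrow(b)) {
        lines <- sprintf("%d %.9f %.9f %.9f %.9f", b$class,
                         (b$xmin + b$xmax) / 2 / w, (b$ymin + b$ymax) / 2 / h,
                         (b$xmax - b$xmin) / w, (b$ymax - b$ymin) / h)
      }
      writeLines(lines, file.path(out_dir, "labels", paste0(name, ".txt")))
    } else {
      imgs[[i]] <- list(id = i, file_name = paste0(name, ".png"),
                        width = w, height = h)
      if (!is.null(b) && nrow(b)) {
        for (j in seq_len(nrow(b))) {
          aid <- aid + 1L
          anns[[aid]] <- list(id = aid, image_id = i,
                              category_id = b$class[j] + 1L,
                              bbox = c(b$xmin[j], b$ymin[j],
                                       b$xmax[j] - b$xmin[j],
                                       b$ymax[j] - b$ymin[j]),
                              area = (b$xmax[j] - b$xmin[j]) * (b$ymax[j] - b$ymin[j]),
                              iscrowd = 0L)
        }
      }
    }
  }
  if (format == "coco") {
    n_cl <- max(c(0L, unlist(lapply(scenes, function(s) s$boxes$class)))) + 1L
    cats <- lapply(seq_len(n_cl), function(k)
      list(id = k, name = paste0("class", k - 1L)))
    jsonlite::write_json(list(images = imgs, annotations = anns, categories = cats),
                         file.path(out_dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @param format `"yolo"` or `"coco"`.
#' @return list of scenes (`$image`, `$boxes`).
#' @export
read_dataset <- function(dir, format = c("yolo", "coco")) {
  format <- match.arg(format)
  img_files <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                               full.names = TRUE))
  if (format == "yolo") {
    lapply(img_files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
      h <- dim(img)[1]; w <- dim(img)[2]
      lab <- file.path(dir, "labels",
                       sub("\\.png$", ".txt", basename(f)))
      b <- if (file.exists(lab) && length(readLines(lab))) {
        m <- do.call(rbind, lapply(strsplit(readLines(lab), " "), as.numeric))
        data.frame(xmin = (m[, 2] - m[, 4] / 2) * w,
                   ymin = (m[, 3] - m[, 5] / 2) * h,
                   xmax = (m[, 2] + m[, 4] / 2) * w,
                   ymax = (m[, 3] + m[, 5] / 2) * h,
                   class = as.integer(m[, 1]))
      } else data.frame(xmin = numeric(0), ymin = numeric(0),
                        xmax = numeric(0), ymax = numeric(0), class = integer(0))
      list(image = img, boxes = b)
    })
  } else {
    j <- jsonlite::read_json(file.path(dir, "annotations.json"))
    by_img <- split(j$annotations,
                    vapply(j$annotations, function(a) a$image_id, numeric(1)))
    lapply(j$images, function(im) {
      img <- png::readPNG(file.path(dir, "images", im$file_name))
      if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
      anns <- by_img[[as.character(im$id)]]
      b <- if (!is.null(anns) && length(anns)) {
        do.call(rbind, lapply(anns, function(a) {
          bb <- as.numeric(unlist(a$bbox))
          data.frame(xmin = bb[1], ymin = bb[2], xmax = bb[1] + bb[3],
                     ymax = bb[2] + bb[4],
                     class = as.integer(a$category_id) - 1L)
        }))
      } else data.frame(xmin = numeric(0), ymin = numeric(0),
                        xmax = numeric(0), ymax = numeric(0), class = integer(0))
      list(image = img, boxes = b)
    })
  }
}
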