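# Grayscale image IO.  Supported formats: PNG (via the png package) and
# plain-text PGM (P2), the portable fixture format used by the test suite.
# RGB(A) input is reduced with the Rec. 601 luminance weights.

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      ch <- dim(a)[3]
      a <- if (ch >= 3)
        0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      else a[, , 1]
    }
    return(pmin(pmax(a, 0), 1))
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format '.", ext, "' for ", path,
       " (supported: png, pgm)", call. = FALSE)
}

write_gray_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image, 0), 1), path)
  } else if (ext == "pgm") {
    write_pgm(image, path)
  } else stop("unsupported image format: ", path, call. = FALSE)
  invisible(path)
}

# Plain-text PGM (P2).  16-bit maxvals are scaled by 1/65535.
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != H * W) stop("corrupt PGM: ", path, call. = FALSE)
  matrix(vals, H, W, byrow = TRUE) / maxval
}

write_pgm <- function(image, path, maxval = 255) {
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a class-subfolder image dataset
#'
#' Loads a directory whose immediate subfolders are class names, each holding
#' the images of that class (PNG or plain-text PGM; RGB reduced to luminance,
#' intensities rescaled to \code{[0, 1]}).  Files are ordered
#' lexicographically so runs are deterministic.
#'
#' @param root dataset root directory.
#' @param skip_bad if \code{TRUE}, unreadable files are dropped with a
#'   warning instead of aborting.
#' @return list with \code{images} (list of matrices), \code{labels}
#'   (factor), and \code{manifest} (data.frame: path, class, H, W).
#' @export
read_dataset <- function(root, skip_bad = FALSE) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0)
    stop("dataset root has no class subfolders: ", root, call. = FALSE)
  images <- list(); labels <- character(); manifest <- NULL
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl), full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0)
      stop("empty class subfolder: ", file.path(root, cl), call. = FALSE)
    for (f in files) {
      img <- tryCatch(read_gray_image(f), error = function(e) {
        if (skip_bad) {
          warning("skipping unreadable file ", f, ": ", conditionMessage(e))
          NULL
        } else stop("failed to read ", f, ": ", conditionMessage(e),
                    call. = FALSE)
      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
      manifest <- rbind(manifest,
                        data.frame(path = f, class = cl,
                                   H = nrow(img), W = ncol(img)))
    }
  }
  list(images = images, labels = factor(labels), manifest = manifest)
}

#' Write a dataset as a class-subfolder image directory
#'
#' @param dataset list with \code{images} and \code{labels}.
#' @param root output directory (created if missing).
#' @param format \code{"png"} or \code{"pgm"}.
#' @return the root path, invisibly.
#' @export
write_dataset <- function(dataset, root, format = "png") {
  for (cl in levels(dataset$labels))
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
  counters <- stats::setNames(rep(0L, nlevels(dataset$labels)),
                              levels(dataset$labels))
  for (i in seq_along(dataset$images)) {
    cl <- as.character(dataset$labels[i])
    counters[cl] <- counters[cl] + 1L
    write_gray_image(dataset$images[[i]],
                     file.path(root, cl,
                               sprintf("img%04d.%s", counters[cl], format)))
  }
  invisible(root)
}

#' Write a feature matrix as CSV (with metadata sidecar)
#'
#' Writes one row per image with the file path and class label first, then
#' the named feature columns at full double precision (\code{\%.17g}, so the
#' read-write round trip is exact).  A JSON sidecar
#' (\code{<out>.meta.json}) records the descriptor name, the moment
#' specification (including \code{alpha} for fractional families), the
#' package version and the seed.
#'
#' @param features numeric matrix with column names.
#' @param labels class labels, one per row.
#' @param paths image paths, one per row (may be \code{NA}).
#' @param out output CSV path.
#' @param descriptor descriptor name for the sidecar.
#' @param spec optional [moment_spec] for the sidecar.
#' @param seed seed recorded in the sidecar.
#' @return \code{out}, invisibly.
#' @export
write_features <- function(features, labels, paths = NULL, out,
                           descriptor = "features", spec = NULL, seed = NA) {
  if (length(labels) != nrow(features))
    stop("row count must equal label count", call. = FALSE)
  if (is.null(paths)) paths <- rep(NA_character_, nrow(features))
  # feature labels like "(p=2,q=3)" contain commas and must be quoted
  header <- c("path", "label",
              paste0('"', gsub('"', '""', colnames(features)), '"'))
  rows <- vapply(seq_len(nrow(features)), function(i)
    paste(c(paths[i], as.character(labels[i]),
            sprintf("%.17g", features[i, ])), collapse = ","),
    character(1))
  writeLines(c(paste(header, collapse = ","), rows), out)
  meta <- list(descriptor = descriptor,
               spec = if (!is.null(spec)) unclass(spec),
               package_version = as.character(utils::packageVersion("orthim")),
               seed = seed, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, paste0(out, ".meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(out)
}

#' Read a feature CSV written by [write_features]
#'
#' @param path CSV path.
#' @return list with \code{features} (numeric matrix), \code{labels}
#'   (factor), \code{paths}.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(path = "character",
                                       label = "character"))
  feats <- as.matrix(df[, -(1:2), drop = FALSE])
  list(features = feats, labels = factor(df$label), paths = df$path)
}
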