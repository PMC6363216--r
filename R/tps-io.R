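#' Read a TPS landmark file
#'
#' Parses the tpsDig dialect of the TPS format: records start with `LM=k`,
#' followed by `k` whitespace-separated coordinate lines, optionally followed
#' by `IMAGE=`, `ID=` and `SCALE=` lines. When `SCALE=` is present the raw
#' pixel coordinates are multiplied by it, so returned coordinates are in
#' image units.
#'
#' Digitizers disagree on the direction of the y axis; with
#' `invert_y = TRUE` the y coordinates are negated so that profiles digitized
#' in an image coordinate system (y growing downward) come out anatomically
#' upright.
#'
#' When `IMAGE=` values look like `horseID_condition_photoID` the three
#' metadata columns are filled from them; otherwise the raw strings are kept.
#'
#' @param path path to a TPS file.
#' @param scheme [method_scheme()] attached to the returned sample; default
#'   `NULL` builds an SSL scheme sized to the records' landmark count.
#' @param invert_y logical; negate y on input.
#' @return A [shape_sample()], one configuration per TPS record.
#' @export
read_tps <- function(path, scheme = NULL, invert_y = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lm_at <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(lm_at) == 0) {
    if (all(lines == "")) {
      if (is.null(scheme)) scheme <- method_scheme("ssl")
      return(empty_sample(scheme))
    }
    stop("no LM= records found in ", path, call. = FALSE)
  }
  configs <- vector("list", length(lm_at))
  image <- id <- character(length(lm_at))
  scale <- rep(NA_real_, length(lm_at))
  bounds <- c(lm_at, length(lines) + 1L)

  for (r in seq_along(lm_at)) {
    block <- lines[lm_at[r]:(bounds[r + 1L] - 1L)]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE)))
    if (is.na(k) || k < 1) {
      stop(sprintf("record %d: invalid LM= count", r), call. = FALSE)
    }
    coord_lines <- block[-1][!grepl("^[A-Za-z]+\\s*=", block[-1]) & block[-1] != ""]
    if (length(coord_lines) != k) {
      stop(sprintf("record %d: LM=%d but %d coordinate lines found",
                   r, k, length(coord_lines)), call. = FALSE)
    }
    xy <- matrix(NA_real_, k, 2)
    for (i in seq_len(k)) {
      vals <- suppressWarnings(as.numeric(strsplit(coord_lines[i], "\\s+")[[1]]))
      if (length(vals) != 2 || anyNA(vals)) {
        stop(sprintf("record %d, coordinate line %d (file line %d): non-numeric coordinate '%s'",
                     r, i, lm_at[r] + which(block == coord_lines[i])[1] - 1L,
                     coord_lines[i]), call. = FALSE)
      }
      xy[i, ] <- vals
    }
    img <- grep("^IMAGE\\s*=", block, value = TRUE, ignore.case = TRUE)
    idl <- grep("^ID\\s*=", block, value = TRUE, ignore.case = TRUE)
    scl <- grep("^SCALE\\s*=", block, value = TRUE, ignore.case = TRUE)
    image[r] <- if (length(img)) sub("^IMAGE\\s*=\\s*", "", img[1], ignore.case = TRUE) else ""
    id[r] <- if (length(idl)) sub("^ID\\s*=\\s*", "", idl[1], ignore.case = TRUE) else as.character(r)
    if (length(scl)) {
      scale[r] <- as.numeric(sub("^SCALE\\s*=\\s*", "", scl[1], ignore.case = TRUE))
      xy <- xy * scale[r]
    }
    if (invert_y) xy[, 2] <- -xy[, 2]
    configs[[r]] <- xy
  }

  k0 <- vapply(configs, nrow, integer(1))
  if (length(unique(k0)) != 1) {
    stop("records have differing landmark counts: ",
         paste(unique(k0), collapse = ", "), call. = FALSE)
  }
  info <- parse_image_metadata(image, id, scale)
  shape_sample(configs, info, scheme)
}

empty_sample <- function(scheme) {
  structure(list(
    coords = array(numeric(0), dim = c(length(scheme$window), 2, 0)),
    info = data.frame(horse_id = character(0), condition = character(0),
                      photo_id = character(0), scale = numeric(0)),
    scheme = scheme
  ), class = "shape_sample")
}

parse_image_metadata <- function(image, id, scale) {
  parts <- strsplit(image, "_", fixed = TRUE)
  std <- lengths(parts) == 3 &
    vapply(parts, function(p) p[2] %in% c("standing", "walking"), logical(1))
  horse <- ifelse(std, vapply(parts, `[`, "", 1), ifelse(image == "", id, image))
  cond <- ifelse(std, vapply(parts, `[`, "", 2), "standing")
  photo <- ifelse(std, vapply(parts, `[`, "", 3), id)
  data.frame(horse_id = horse, condition = cond, photo_id = photo,
             scale = scale, image = image, id = id,
             stringsAsFactors = FALSE)
}

#' Write a shape sample as a TPS file
#'
#' One `LM=` record per configuration, re-readable by [read_tps()]. Metadata
#' is written as `IMAGE=horseID_condition_photoID` and `ID=` lines. If a
#' configuration carries a scale factor, raw pixel coordinates
#' (image units divided by the scale) are stored together with a `SCALE=`
#' line, mirroring how digitizing software writes calibrated files.
#'
#' @param sample a [shape_sample()].
#' @param path output file path.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_tps <- function(sample, path, digits = 12) {
  stopifnot(inherits(sample, "shape_sample"))
  n <- n_configurations(sample)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(n)) {
    xy <- sample$coords[, , r]
    scl <- sample$info$scale[r]
    if (!is.na(scl) && scl != 0) xy <- xy / scl
    writeLines(sprintf("LM=%d", nrow(xy)), con)
    writeLines(paste(format(xy[, 1], digits = digits, trim = TRUE, scientific = FALSE),
                     format(xy[, 2], digits = digits, trim = TRUE, scientific = FALSE)), con)
    writeLines(sprintf("IMAGE=%s_%s_%s", sample$info$horse_id[r],
                       sample$info$condition[r], sample$info$photo_id[r]), con)
    writeLines(sprintf("ID=%s", sample$info$photo_id[r]), con)
    if (!is.na(scl)) writeLines(sprintf("SCALE=%s", format(scl, digits = digits)), con)
  }
  invisible(path)
}
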