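#' Read a single-channel image
#'
#' Supported formats: PNG (8/16-bit, via the png package; values scaled to
#' `[0, 1]`), plain-text NetPBM PGM (`P2`; values scaled by the stated
#' maximum), and headerless CSV matrices (values passed through unchanged
#' after a finiteness check — the lossless float route). File rows are
#' stored top-first; on load they are flipped so that the row index
#' increases with y and angles are counter-clockwise from +x ("y-up").
#'
#' @param path file path; format from the extension (`.png`, `.pgm`,
#'   `.csv`).
#' @param channel 1-based channel index, required for multi-channel PNG
#'   input.
#' @return An [image2d()].
#' @export
read_image <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) {
        if (is.null(channel))
          stop("multi-channel image: supply a channel index")
        if (channel < 1 || channel > dim(a)[3]) stop("channel out of range")
        a[, , channel]
      } else a
    },
    pgm = read_pgm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (any(!is.finite(m))) stop("image contains non-finite values")
  image2d(m[rev(seq_len(nrow(m))), , drop = FALSE])
}

read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only plain-text (P2) PGM is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
  matrix(vals, h, w, byrow = TRUE) / maxval
}

#' Write a single-channel image
#'
#' Inverse of [read_image()]: flips the y-up matrix back to top-first file
#' order. PNG output clips to `[0, 1]` and quantizes (16-bit by default);
#' CSV output is lossless full-precision text.
#'
#' @param image an [image2d()] or matrix.
#' @param path output path (`.png`, `.pgm` or `.csv`).
#' @param bits PNG/PGM bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16) {
  v <- as_image2d(image)$values
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(v, 0), 1), path)  # arg order keeps dim attributes
  } else if (ext == "pgm") {
    maxval <- 2^bits - 1
    q <- round(pmin(pmax(v, 0), 1) * maxval)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(v), nrow(v)), as.character(maxval)), con)
    utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  } else if (ext == "csv") {
    utils::write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read / write a fluorescence trace CSV
#'
#' Column format: `time_s`, `F`, with an optional comment header line
#' `# stimulus_time_s: <t>` carrying the stimulus annotation. Written
#' traces include the `dFF0` column when present.
#'
#' @param path CSV path.
#' @return A `calcium_trace`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  stim <- NULL
  if (grepl("^#\\s*stimulus_time_s:", first))
    stim <- as.numeric(sub("^#\\s*stimulus_time_s:\\s*", "", first))
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "F") %in% names(d)))
    stop("trace CSV needs columns time_s, F")
  structure(list(time_s = d$time_s, F = d$F, stimulus_time_s = stim),
            class = "calcium_trace")
}

#' @rdname read_trace_csv
#' @param trace a `calcium_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trace$stimulus_time_s))
    writeLines(sprintf("# stimulus_time_s: %.10g", trace$stimulus_time_s), con)
  d <- data.frame(time_s = trace$time_s, F = trace$F)
  if (!is.null(trace$dFF0)) d$dFF0 <- trace$dFF0
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Read a stimulation protocol from YAML
#'
#' Expected layout: a top-level `phases` list (each entry with a `type` of
#' `ramp`, `rest` or `cyclic` and that phase's fields, as in
#' [protocol_spec()]), optional `params` (fields of [membrane_params()])
#' and optional `dt_s`.
#'
#' @param path YAML file.
#' @return List: `spec` ([protocol_spec()]), `params`
#'   ([membrane_params()]), `dt_s`.
#' @export
read_protocol_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$phases)) stop("protocol YAML needs a `phases` list")
  phases <- lapply(y$phases, function(p) {
    a <- p[setdiff(names(p), "type")]
    switch(p$type,
           ramp = do.call(phase_ramp, a),
           rest = do.call(phase_rest, a),
           cyclic = do.call(phase_cyclic, a),
           stop("unknown phase type: ", p$type))
  })
  params <- do.call(membrane_params, if (is.null(y$params)) list() else y$params)
  list(spec = protocol_spec(phases), params = params,
       dt_s = if (is.null(y$dt_s)) 1 else y$dt_s)
}

#' Write an orientation map, histogram or waveform to CSV/JSON
#'
#' Tile coordinates are 0-based pixel positions in the y-up frame; angles
#' are degrees in `[-90, 90)`.
#'
#' @param x the object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orientation_csv <- function(x, path) {
  stopifnot(inherits(x, "orientation_map"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orientation_csv
#' @export
write_histogram_csv <- function(x, path) {
  stopifnot(inherits(x, "orientation_histogram"))
  utils::write.csv(data.frame(bin_center_deg = x$bin_centers_deg,
                              weight = x$weights), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orientation_csv
#' @export
write_waveform_csv <- function(x, path) {
  stopifnot(inherits(x, "stimulation_waveform"))
  utils::write.csv(data.frame(time_s = x$time_s,
                              strain_percent = x$strain_percent,
                              delta_volume_uL = x$delta_volume_uL),
                   path, row.names = FALSE)
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
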