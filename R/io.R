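# ---- minimal float32 TIFF writer -------------------------------------------
# The tiff package reads IEEE-float TIFFs but writes 32-bit data as scaled
# integers, so true float output is written here directly: little-endian,
# uncompressed, one strip per page, SampleFormat = 3 (IEEE float).

write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wi2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  n_pages <- length(pages)
  dims <- lapply(pages, dim)
  data_sizes <- vapply(dims, function(d) 4L * d[1] * d[2], integer(1))
  data_offsets <- 8L + c(0L, cumsum(data_sizes))[seq_len(n_pages)]
  n_tags <- 10L
  ifd_size <- 2L + 12L * n_tags + 4L
  ifd_offsets <- 8L + sum(data_sizes) + (seq_len(n_pages) - 1L) * ifd_size
  # header
  writeBin(charToRaw("II"), con)
  wi2(42L)
  wi4(ifd_offsets[1])
  # pixel data (row-major within a page, as TIFF expects)
  for (p in pages)
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  # IFDs
  tag <- function(code, type, count, value) {
    wi2(code); wi2(type); wi4(count)
    if (type == 3L) { wi2(value); wi2(0L) } else wi4(value)
  }
  for (i in seq_len(n_pages)) {
    d <- dims[[i]]
    wi2(n_tags)
    tag(256L, 4L, 1L, d[2])             # ImageWidth
    tag(257L, 4L, 1L, d[1])             # ImageLength
    tag(258L, 3L, 1L, 32L)              # BitsPerSample
    tag(259L, 3L, 1L, 1L)               # Compression: none
    tag(262L, 3L, 1L, 1L)               # Photometric: black is zero
    tag(273L, 4L, 1L, data_offsets[i])  # StripOffsets
    tag(277L, 3L, 1L, 1L)               # SamplesPerPixel
    tag(278L, 4L, 1L, d[1])             # RowsPerStrip
    tag(279L, 4L, 1L, data_sizes[i])    # StripByteCounts
    tag(339L, 3L, 1L, 3L)               # SampleFormat: IEEE float
    wi4(if (i < n_pages) ifd_offsets[i + 1L] else 0L)
  }
  invisible(path)
}

# ---- stack reading ----------------------------------------------------------

#' Read a grayscale multi-page TIFF stack
#'
#' Pages are interpreted per the `layout` string: `"TYX"` (plain time-lapse),
#' `"TZYX"` (volumetric time-lapse, z-fastest page order) or `"CTZYX"`
#' (multi-channel volumetric, channel outermost, then time, then z). Integer
#' pages (8/16-bit) are converted to floating point intensity values; 32-bit
#' pages are read as IEEE float.
#'
#' @param path TIFF file path.
#' @param layout one of `"TYX"`, `"TZYX"`, `"CTZYX"`. Mandatory beyond 3-D to
#'   avoid silent misinterpretation of page order.
#' @param nz number of z planes (required for `"TZYX"`/`"CTZYX"`).
#' @param nchannels number of channels (required for `"CTZYX"`).
#' @param frame_interval,pixel_size optional metadata attached to the result.
#' @return For `"TYX"`, a [video_stack()]; for `"TZYX"`, an H x W x Z x T
#'   array; for `"CTZYX"`, a list of per-channel H x W x Z x T arrays.
#' @export
read_stack <- function(path, layout = c("TYX", "TZYX", "CTZYX"), nz = NULL,
                       nchannels = NULL, frame_interval = NULL,
                       pixel_size = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  bits <- meta$bits.per.sample[1]
  for (p in pages)
    if (length(dim(p)) > 2L && dim(p)[3] > 1L)
      stop("RGB/multi-sample pages are not supported; expected grayscale")
  pages <- lapply(pages, function(p) if (length(dim(p)) > 2L) p[, , 1] else p)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) stop("inconsistent page shapes in ", path)
  if (bits %in% c(8L, 16L)) {
    # readTIFF scales integer data to [0, 1]; restore original counts
    pages <- lapply(pages, function(p) round(p * (2^bits - 1)))
  }
  d2 <- dim(pages[[1]])
  P <- length(pages)
  flat <- array(unlist(pages), c(d2[1], d2[2], P))
  if (layout == "TYX")
    return(video_stack(pmax(flat, 0), frame_interval = frame_interval,
                       pixel_size = pixel_size))
  if (is.null(nz)) stop("layout ", layout, " requires nz")
  nz <- as.integer(nz)
  if (layout == "TZYX") {
    if (P %% nz != 0L) stop("page count ", P, " not divisible by nz = ", nz)
    T_ <- P %/% nz
    # page order: z fastest, then t
    return(array(flat[, , order_pages_tz(nz, T_)], c(d2[1], d2[2], nz, T_)))
  }
  if (is.null(nchannels)) stop("layout CTZYX requires nchannels")
  nchannels <- as.integer(nchannels)
  if (P %% (nz * nchannels) != 0L)
    stop("page count ", P, " not divisible by nz * nchannels")
  T_ <- P %/% (nz * nchannels)
  lapply(seq_len(nchannels), function(ch) {
    offset <- (ch - 1L) * T_ * nz
    array(flat[, , offset + order_pages_tz(nz, T_)], c(d2[1], d2[2], nz, T_))
  })
}

# Page index permutation mapping (z, t) storage (z fastest within t) onto an
# H x W x Z x T array: target position (z, t) <- page (t-1)*nz + z, which is
# already the natural order, so this is the identity sequence.
order_pages_tz <- function(nz, T_) seq_len(nz * T_)

#' Write a stack to a multi-page TIFF
#'
#' Integer output (`dtype = "uint16"`) rounds to nearest with clipping to
#' [0, 65535]; `dtype = "float32"` writes IEEE-float pages (values pass
#' through unscaled, quantized only to float32 precision).
#'
#' @param stack a [video_stack()], 3-D array, 4-D array (written z-fastest) or
#'   list of per-channel 4-D arrays (channel outermost, matching
#'   [read_stack()]'s `"CTZYX"`).
#' @param path output file path.
#' @param dtype `"uint16"` (default) or `"float32"`.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("uint16", "float32")) {
  dtype <- match.arg(dtype)
  pages <- stack_to_pages(stack)
  if (length(pages) == 0L) stop("empty stack")
  if (!all(vapply(pages, function(p) all(is.finite(p)), logical(1))))
    stop("non-finite pixels cannot be written")
  if (dtype == "uint16") {
    pages <- lapply(pages, function(p) pmin(pmax(round(p), 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    write_float_tiff(pages, path)
  }
  invisible(path)
}

stack_to_pages <- function(stack) {
  if (is.list(stack) && !is.array(stack)) {
    return(unlist(lapply(stack, stack_to_pages), recursive = FALSE))
  }
  a <- if (inherits(stack, "video_stack")) as_stack_array(stack) else stack
  d <- dim(a)
  if (length(d) == 2L) return(list(a))
  if (length(d) == 3L)
    return(lapply(seq_len(d[3]), function(t) a[, , t]))
  if (length(d) == 4L) {
    pages <- list()
    for (t in seq_len(d[4]))
      for (z in seq_len(d[3]))
        pages[[length(pages) + 1L]] <- a[, , z, t]
    return(pages)
  }
  stop("cannot serialize an array with ", length(d), " dimensions")
}

# ---- run configuration and logging ------------------------------------------

#' Write the effective run configuration beside an output artifact
#'
#' Every artifact-writing command records its full effective configuration
#' (tool version, master seed, all options, timestamp) as JSON next to its
#' output, so a run can be reproduced from the file alone.
#'
#' @param config named list of options.
#' @param out_path the artifact whose configuration is being recorded; the
#'   config is written to `paste0(out_path, ".config.json")`.
#' @return The config file path, invisibly.
#' @export
write_run_config <- function(config, out_path) {
  cfg_path <- paste0(out_path, ".config.json")
  config$provenance <- list(
    tool = "fastdenoise",
    version = as.character(utils::packageVersion("fastdenoise")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(cfg_path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path the `.config.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

log_msg <- function(level, ...) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...))
  cat(line, "\n", sep = "", file = stderr())
  logfile <- getOption("fastdenoise.logfile")
  if (!is.null(logfile)) cat(line, "\n", sep = "", file = logfile, append = TRUE)
  invisible(line)
}
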