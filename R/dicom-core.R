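# Minimal DICOM codec: Explicit VR Little Endian only, defined-length
# sequences on write, defined- or undefined-length on read. This is not a
# general DICOM toolkit; it covers exactly the CT Image / RT Structure Set /
# RT Dose attributes this package reads and writes.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
SOP_DETACHED_STUDY <- "1.2.840.10008.3.1.2.3.1"

# VRs encoded with a 4-byte length after 2 reserved bytes
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16r <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

.u32r <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, floor(x / 256) %% 256,
           floor(x / 65536) %% 256, floor(x / 16777216) %% 256))
}

.r2u16 <- function(bytes, i) {
  as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
}

.r2u32 <- function(bytes, i) {
  as.numeric(bytes[i]) + 256 * as.numeric(bytes[i + 1L]) +
    65536 * as.numeric(bytes[i + 2L]) + 16777216 * as.numeric(bytes[i + 3L])
}

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

#' @noRd
dcm_el <- function(vr, value) list(vr = vr, value = value)

# Decimal String: up to 16 bytes per value, %.10g fits and round-trips mm
# coordinates and scaling factors far below the tolerances used here.
.fmt_ds <- function(x) sprintf("%.10g", x)

.pad_even <- function(bytes, pad) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dcm_encode_value <- function(vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, function(item) {
      body <- dcm_encode_dataset(item)
      c(.u16r(0xFFFE), .u16r(0xE000), .u32r(length(body)), body)
    })
    return(do.call(c, c(list(raw(0)), items)))
  }
  if (vr %in% c("OB", "OW", "UN")) {
    stopifnot(is.raw(value))
    return(.pad_even(value, as.raw(0)))
  }
  if (vr == "US") return(writeBin(as.integer(value), raw(), size = 2, endian = "little"))
  if (vr == "UL") return(writeBin(as.integer(value), raw(), size = 4, endian = "little"))
  if (vr == "AT") return(c(.u16r(value[1]), .u16r(value[2])))
  if (vr == "FD") return(writeBin(as.numeric(value), raw(), size = 8, endian = "little"))
  s <- switch(vr,
    DS = paste(.fmt_ds(value), collapse = "\\"),
    IS = paste(sprintf("%d", as.integer(value)), collapse = "\\"),
    paste(as.character(value), collapse = "\\"))
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  .pad_even(charToRaw(s), pad)
}

dcm_encode_element <- function(tag, el) {
  g <- strtoi(substr(tag, 1, 4), 16L)
  e <- strtoi(substr(tag, 6, 9), 16L)
  val <- dcm_encode_value(el$vr, el$value)
  hdr <- if (el$vr %in% .long_vrs) {
    c(.u16r(g), .u16r(e), charToRaw(el$vr), as.raw(c(0, 0)), .u32r(length(val)))
  } else {
    c(.u16r(g), .u16r(e), charToRaw(el$vr), .u16r(length(val)))
  }
  c(hdr, val)
}

# Encode a dataset (named list "GGGG,EEEE" -> dcm_el) in ascending tag order.
dcm_encode_dataset <- function(ds) {
  tags <- names(ds)
  key <- strtoi(substr(tags, 1, 4), 16L) * 65536 + strtoi(substr(tags, 6, 9), 16L)
  parts <- lapply(tags[order(key)], function(tg) dcm_encode_element(tg, ds[[tg]]))
  do.call(c, c(list(raw(0)), parts))
}

# File = 128-byte preamble + "DICM" + group-0002 meta (Explicit VR LE) + dataset.
dcm_write_file <- function(path, ds, sop_class_uid, sop_instance_uid) {
  meta <- list(
    "0002,0001" = dcm_el("OB", as.raw(c(0, 1))),
    "0002,0002" = dcm_el("UI", sop_class_uid),
    "0002,0003" = dcm_el("UI", sop_instance_uid),
    "0002,0010" = dcm_el("UI", TS_EXPLICIT_LE),
    "0002,0012" = dcm_el("UI", paste0(.uid_root(), "0.1"))
  )
  meta_raw <- dcm_encode_dataset(meta)
  glen <- dcm_encode_element("0002,0000", dcm_el("UL", length(meta_raw)))
  body <- c(raw(128), charToRaw("DICM"), glen, meta_raw, dcm_encode_dataset(ds))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(body, con)
  invisible(path)
}

dcm_decode_value <- function(vr, bytes) {
  n <- length(bytes)
  if (vr %in% c("OB", "OW", "UN", "OF")) return(bytes)
  if (vr == "US") return(readBin(bytes, "integer", n %/% 2L, size = 2, signed = FALSE, endian = "little"))
  if (vr == "UL") {
    v <- readBin(bytes, "integer", n %/% 4L, size = 4, endian = "little")
    v <- as.numeric(v)
    return(ifelse(v < 0, v + 4294967296, v))
  }
  if (vr == "AT") return(c(.r2u16(bytes, 1L), .r2u16(bytes, 3L)))
  if (vr == "FD") return(readBin(bytes, "double", n %/% 8L, size = 8, endian = "little"))
  s <- rawToChar(bytes[bytes != as.raw(0)])
  s <- sub("[ ]+$", "", s)
  parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
  switch(vr,
    DS = as.numeric(parts),
    IS = as.integer(parts),
    trimws(parts))
}

# Parse elements from `p` until `end` or an item delimiter; returns the
# dataset and the position after the last byte consumed.
dcm_parse_dataset <- function(bytes, p, end) {
  out <- list()
  while (p + 7L <= end + 1L && p + 3L <= length(bytes)) {
    g <- .r2u16(bytes, p)
    e <- .r2u16(bytes, p + 2L)
    if (g == 0xFFFE) {           # item / sequence delimiter
      p <- p + 8L
      if (e == 0xE00D || e == 0xE0DD) break
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(bytes[(p + 4L):(p + 5L)])
    if (vr %in% .long_vrs) {
      len <- .r2u32(bytes, p + 8L)
      vp <- p + 12L
    } else {
      len <- .r2u16(bytes, p + 6L)
      vp <- p + 8L
    }
    tag <- dcm_tag(g, e)
    if (vr == "SQ") {
      sq <- dcm_parse_sequence(bytes, vp, len)
      out[[tag]] <- dcm_el("SQ", sq$items)
      p <- sq$pos
    } else {
      if (len == 4294967295) stop("undefined length on non-sequence element ", tag)
      val <- if (len > 0) bytes[vp:(vp + len - 1L)] else raw(0)
      out[[tag]] <- dcm_el(vr, dcm_decode_value(vr, val))
      p <- vp + len
    }
  }
  list(ds = out, pos = p)
}

dcm_parse_sequence <- function(bytes, p, len) {
  defined <- len != 4294967295
  end <- if (defined) p + len - 1L else length(bytes)
  items <- list()
  while (p + 7L <= end + 1L) {
    g <- .r2u16(bytes, p)
    e <- .r2u16(bytes, p + 2L)
    if (g != 0xFFFE) stop("malformed sequence item tag")
    if (e == 0xE0DD) { p <- p + 8L; break }
    ilen <- .r2u32(bytes, p + 4L)
    p <- p + 8L
    iend <- if (ilen == 4294967295) end else p + ilen - 1L
    parsed <- dcm_parse_dataset(bytes, p, iend)
    items[[length(items) + 1L]] <- parsed$ds
    p <- parsed$pos
  }
  list(items = items, pos = p)
}

dcm_read_file <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 140) stop_io("not a DICOM file (too small): ", path)
  bytes <- readBin(path, "raw", size)
  if (rawToChar(bytes[129:132]) != "DICM") {
    stop_io("missing DICM marker: ", path)
  }
  # group length (0002,0000) first, then the meta group it delimits
  hdr <- dcm_parse_dataset(bytes, 133L, 144L)
  glen <- hdr$ds[["0002,0000"]]$value
  meta <- dcm_parse_dataset(bytes, hdr$pos, hdr$pos + glen - 1L)
  ts <- meta$ds[["0002,0010"]]$value
  if (!identical(ts, TS_EXPLICIT_LE)) {
    stop_io("unsupported transfer syntax ", ts, " in ", path)
  }
  body <- dcm_parse_dataset(bytes, meta$pos, length(bytes))
  body$ds
}

# Element lookup helpers -------------------------------------------------

dcm_value <- function(ds, tag, default = NULL) {
  el <- ds[[tag]]
  if (is.null(el)) default else el$value
}

dcm_require <- function(ds, tag, what) {
  el <- ds[[tag]]
  if (is.null(el)) stop_io("missing required DICOM attribute ", tag, " (", what, ")")
  el$value
}

# UID generation ----------------------------------------------------------

.rt_env <- new.env(parent = emptyenv())
.rt_env$uid_seed <- NULL
.rt_env$uid_counter <- 0L

.uid_root <- function() "1.2.826.0.1.3680043.10.424."

#' Seed DICOM UID generation
#'
#' New SOP instance / series UIDs are normally derived from the clock and
#' process id. Setting a seed makes UID generation deterministic, so that two
#' runs on identical inputs produce bit-identical output files.
#'
#' @param seed Integer seed, or `NULL` to return to non-deterministic UIDs.
#' @return The previous seed, invisibly.
#' @export
set_uid_seed <- function(seed = NULL) {
  old <- .rt_env$uid_seed
  .rt_env$uid_seed <- if (is.null(seed)) NULL else as.integer(seed)
  .rt_env$uid_counter <- 0L
  invisible(old)
}

new_uid <- function() {
  .rt_env$uid_counter <- .rt_env$uid_counter + 1L
  if (!is.null(.rt_env$uid_seed)) {
    paste0(.uid_root(), .rt_env$uid_seed, ".", .rt_env$uid_counter)
  } else {
    paste0(.uid_root(),
           sprintf("%.0f", as.numeric(Sys.time()) %% 1e7 * 1000), ".",
           Sys.getpid(), ".", .rt_env$uid_counter)
  }
}

# Condition constructors: the CLI maps these classes to exit codes.
stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("rtdeface_io_error", "error")))
}

stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("rtdeface_geometry_error", "error")))
}

stop_no_eyes <- function(...) {
  stop(errorCondition(paste0(...), class = c("rtdeface_no_eyes_error", "error")))
}
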