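# Minimal ZIP container support: reading via utils::unzip, writing via a
# store-only (method 0) writer.  Deterministic output: fixed timestamps, entry
# order preserved, so identical inputs give byte-identical archives.

.crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L) # 0xEDB88320 as signed 32-bit
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  stopifnot(is.raw(bytes))
  crc <- -1L # 0xFFFFFFFF
  if (length(bytes)) {
    ints <- as.integer(bytes)
    for (b in ints) {
      idx <- bitwAnd(bitwXor(crc, b), 255L)
      crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx + 1L])
    }
  }
  bitwXor(crc, -1L)
}

# little-endian raw encoding of a non-negative value (possibly stored as the
# signed 32-bit pattern produced by crc32)
int_le <- function(x, width) {
  out <- raw(width)
  if (width == 4L && is.integer(x)) {
    v <- x
    for (i in 1:4) {
      out[i] <- as.raw(bitwAnd(v, 255L))
      v <- bitwShiftR(v, 8L)
    }
    return(out)
  }
  v <- as.numeric(x)
  for (i in seq_len(width)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

#' @noRd
zip_write <- function(path, entries) {
  # entries: named list of raw vectors; names are archive-internal paths
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  offsets <- numeric(length(entries))
  crcs <- integer(length(entries))
  off <- 0
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    dat <- entries[[i]]
    stopifnot(is.raw(dat))
    crcs[i] <- crc32(dat)
    offsets[i] <- off
    hdr <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      int_le(20L, 2L),          # version needed
      int_le(0L, 2L),           # flags
      int_le(0L, 2L),           # method: stored
      int_le(0L, 2L),           # mod time
      int_le(0x21, 2L),         # mod date (fixed, 1980-01-01)
      int_le(crcs[i], 4L),
      int_le(length(dat), 4L),  # compressed size
      int_le(length(dat), 4L),  # uncompressed size
      int_le(length(nm), 2L),
      int_le(0L, 2L)            # extra len
    )
    writeBin(hdr, con)
    writeBin(nm, con)
    if (length(dat)) writeBin(dat, con)
    off <- off + length(hdr) + length(nm) + length(dat)
  }
  cd_off <- off
  cd_size <- 0
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    dat <- entries[[i]]
    rec <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      int_le(20L, 2L), int_le(20L, 2L),
      int_le(0L, 2L), int_le(0L, 2L),
      int_le(0L, 2L), int_le(0x21, 2L),
      int_le(crcs[i], 4L),
      int_le(length(dat), 4L), int_le(length(dat), 4L),
      int_le(length(nm), 2L),
      int_le(0L, 2L), int_le(0L, 2L),  # extra, comment
      int_le(0L, 2L),                  # disk start
      int_le(0L, 2L), int_le(0L, 4L),  # internal/external attrs
      int_le(offsets[i], 4L)
    )
    writeBin(rec, con)
    writeBin(nm, con)
    cd_size <- cd_size + length(rec) + length(nm)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    int_le(0L, 2L), int_le(0L, 2L),
    int_le(length(entries), 2L), int_le(length(entries), 2L),
    int_le(cd_size, 4L), int_le(cd_off, 4L),
    int_le(0L, 2L)
  )
  writeBin(eocd, con)
  invisible(path)
}

#' @noRd
zip_read <- function(path) {
  listing <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e) stop("unreadable ZIP container: ",
                                               conditionMessage(e), call. = FALSE),
                      warning = function(w) stop("unreadable ZIP container: ",
                                                 conditionMessage(w), call. = FALSE))
  names <- listing$Name
  keep <- !grepl("/$", names)
  names <- names[keep]
  sizes <- listing$Length[keep]
  if (!length(names)) stop("archive error: empty ZIP container", call. = FALSE)
  exdir <- tempfile("zipread")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)
  out <- vector("list", length(names))
  for (i in seq_along(names)) {
    f <- file.path(exdir, names[i])
    out[[i]] <- if (sizes[i] > 0) readBin(f, "raw", n = file.size(f)) else raw(0)
  }
  names(out) <- names
  out
}

is_zip_file <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 4) return(FALSE)
  magic <- readBin(path, "raw", n = 4)
  identical(magic, as.raw(c(0x50, 0x4b, 0x03, 0x04))) ||
    identical(magic, as.raw(c(0x50, 0x4b, 0x05, 0x06)))  # empty archive
}
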