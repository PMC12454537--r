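#' Read and write MRtrix TCK streamline files
#'
#' TCK stores world-mm coordinates: a short ASCII header (key-value
#' lines, ending with \code{END}) followed by little-endian float32
#' triplets; streamlines are separated by NaN triplets and the file is
#' terminated by an Inf triplet. Only \code{Float32LE} data are
#' supported.
#'
#' @param path file path.
#' @return a \code{streamline_set}.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks"))
    stop("read_tck: not a TCK file: ", path)
  offset <- NULL; datatype <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_tck: truncated header")
    if (line == "END") break
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      if (kv[2] == "file") offset <- as.integer(sub("^\\. *", "", kv[3]))
      if (kv[2] == "datatype") datatype <- kv[3]
    }
  }
  if (is.null(offset)) stop("read_tck: missing 'file' header field")
  if (!identical(datatype, "Float32LE"))
    stop("read_tck: unsupported datatype: ", datatype)
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  fin <- is.finite(m[, 1])
  breaks <- which(!fin)
  lines <- list(); start <- 1L
  for (b in breaks) {
    if (b > start)
      lines[[length(lines) + 1L]] <- m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (is.infinite(m[b, 1])) break
  }
  streamline_set(lines)
}

#' @rdname read_tck
#' @param set a \code{streamline_set}.
#' @return \code{write_tck} returns \code{path} invisibly.
#' @export
write_tck <- function(set, path) {
  header <- c("mrtrix tracks", "datatype: Float32LE",
              paste0("count: ", length(set)))
  # 'file: . <offset>' must state the byte offset of the binary section
  probe <- paste0("file: . ", "0000000000")
  hdr_len <- sum(nchar(c(header, probe, "END"), type = "bytes")) +
    length(c(header, probe, "END"))   # newlines
  offset_line <- sprintf("file: . %d", hdr_len)
  # keep the byte length stable by padding with spaces
  offset_line <- formatC(offset_line, width = nchar(probe), flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, offset_line, "END"), con, sep = "\n")
  dat <- do.call(rbind, lapply(unclass(set), function(p)
    rbind(p, c(NaN, NaN, NaN))))
  dat[nrow(dat), ] <- c(Inf, Inf, Inf)
  writeBin(as.numeric(t(dat)), con, size = 4L, endian = "little")
  invisible(path)
}
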