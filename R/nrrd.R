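# Minimal NRRD reader/writer for 3-D scalar volumes.
#
# Subset of the NRRD0004 format sufficient for micro-CT interchange:
# uint8/uint16 sample types, raw or gzip encodings, little/big endian,
# spacing via "space directions".  NRRD stores the fastest axis first, so
# files are written x-fastest (sizes: nx ny nz) and permuted to the
# package's (z, y, x) array convention on read.

nrrd_type_table <- c(
  "uint8" = 8L, "uchar" = 8L, "unsigned char" = 8L,
  "uint8_t" = 8L,
  "uint16" = 16L, "ushort" = 16L, "unsigned short" = 16L,
  "unsigned short int" = 16L, "uint16_t" = 16L
)

write_nrrd <- function(v, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  bd <- bit_depth(v)
  vs <- voxel_size(v)            # (z, y, x)
  arr <- as_array(v)
  d <- dim(arr)                  # (nz, ny, nx)
  vec <- as.vector(aperm(arr, c(3L, 2L, 1L)))  # x fastest

  if (bd == 8L) {
    payload <- as.raw(vec)
  } else {
    lo <- vec %% 256L
    hi <- vec %/% 256L
    payload <- as.raw(as.vector(rbind(lo, hi)))  # little endian pairs
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")

  hdr <- c(
    "NRRD0004",
    "# trabsep volume",
    paste0("type: ", if (bd == 8L) "uint8" else "uint16"),
    "dimension: 3",
    paste0("sizes: ", d[3L], " ", d[2L], " ", d[1L]),
    "endian: little",
    paste0("encoding: ", encoding),
    "space dimension: 3",
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   vs[3L], vs[2L], vs[1L])),
    ""
  )
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io("cannot open '", path,
                                              "' for writing"))
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(payload, con)
  invisible(path)
}

read_nrrd <- function(path) {
  raw_all <- tryCatch(readBin(path, "raw", n = file.size(path)),
                      error = function(e) stop_io("cannot read '", path, "'"))
  if (length(raw_all) < 8L ||
      !identical(rawToChar(raw_all[1:4]), "NRRD"))
    stop_format("'", path, "' is not an NRRD file")

  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    # tolerate \r\n
    if (p == prev + 2L && raw_all[p - 1L] == as.raw(13L)) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop_format("NRRD header in '", path,
                                  "' has no terminating blank line")
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\r?\n")[[1L]]
  hdr_lines <- hdr_lines[-1L]                       # magic
  hdr_lines <- hdr_lines[!grepl("^#", hdr_lines)]   # comments
  hdr_lines <- hdr_lines[nzchar(hdr_lines)]
  kv <- regmatches(hdr_lines, regexec("^([^:]+):[ =]?\\s*(.*)$", hdr_lines))
  fields <- stats::setNames(
    vapply(kv, function(x) trimws(x[3L]), ""),
    tolower(vapply(kv, function(x) trimws(x[2L]), ""))
  )

  need <- function(key) {
    if (!key %in% names(fields))
      stop_format("NRRD header missing required field '", key, "'")
    fields[[key]]
  }
  ndim <- as.integer(need("dimension"))
  if (ndim != 3L)
    stop_dim("NRRD in '", path, "' is ", ndim, "-D; expected a 3-D volume")
  type <- tolower(need("type"))
  if (!type %in% names(nrrd_type_table))
    stop_format("unsupported NRRD sample type '", type,
                "' (uint8/uint16 only)")
  bd <- nrrd_type_table[[type]]
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1L]])  # (nx, ny, nz)
  if (length(sizes) != 3L || any(is.na(sizes)) || any(sizes < 1L))
    stop_format("invalid NRRD sizes field")
  encoding <- tolower(need("encoding"))
  if (!encoding %in% c("raw", "gzip", "gz"))
    stop_format("unsupported NRRD encoding '", encoding, "'")
  endian <- if ("endian" %in% names(fields)) tolower(fields[["endian"]])
            else "little"

  vs <- c(1, 1, 1)
  got_spacing <- FALSE
  if ("space directions" %in% names(fields)) {
    m <- gregexpr("\\(([^)]*)\\)", fields[["space directions"]])
    vecs <- regmatches(fields[["space directions"]], m)[[1L]]
    if (length(vecs) == 3L) {
      dirs <- t(vapply(vecs, function(s)
        as.numeric(strsplit(gsub("[()]", "", s), ",")[[1L]]), numeric(3L)))
      # axis-aligned rows keep their entry bit-exactly; oblique rows fall
      # back to the L2 norm
      vs_xyz <- apply(dirs, 1L, function(r) {
        nz <- which(r != 0)
        if (length(nz) == 1L) abs(r[nz]) else sqrt(sum(r^2))
      })
      vs <- rev(vs_xyz)                 # to (z, y, x)
      got_spacing <- TRUE
    }
  } else if ("spacings" %in% names(fields)) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1L]])
    if (length(sp) == 3L && !anyNA(sp)) { vs <- rev(sp); got_spacing <- TRUE }
  }
  if (!got_spacing)
    warning("NRRD '", path, "' carries no spacing; defaulting to (1, 1, 1)",
            call. = FALSE)

  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (encoding %in% c("gzip", "gz"))
    payload <- memDecompress(payload, type = "gzip")
  n <- prod(sizes)
  if (bd == 8L) {
    if (length(payload) < n) stop_format("NRRD payload truncated")
    vec <- as.integer(payload[seq_len(n)])
  } else {
    if (length(payload) < 2L * n) stop_format("NRRD payload truncated")
    vec <- readBin(payload, "integer", n = n, size = 2L, signed = FALSE,
                   endian = if (endian == "big") "big" else "little")
  }
  arr <- aperm(array(vec, dim = sizes), c(3L, 2L, 1L))  # to (z, y, x)
  volume3d(arr, voxel_size = vs, bit_depth = bd)
}
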