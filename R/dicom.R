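# Minimal read-only DICOM support: uncompressed, explicit-VR little-endian,
# single-frame CT slices. Enough to assemble a series into a volume with
# correct geometry and HU rescaling; anything fancier should be converted to
# NIfTI upstream.

dcm_long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")

dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(at) readBin(raw[at + 0:1], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at + 0:3], "integer", size = 4,
                              endian = "little")
  elems <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dcm_long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    if (len < 0L)
      stop("undefined-length DICOM elements are not supported: ", path,
           call. = FALSE)
    tag <- sprintf("%04x,%04x", group, elem)
    body <- if (len > 0L) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    elems[[tag]] <- list(vr = vr, bytes = body)
    pos <- pos + hdr + len
  }
  elems
}

dcm_str <- function(e, tag) {
  x <- e[[tag]]
  if (is.null(x)) return(NULL)
  trimws(rawToChar(x$bytes))
}

dcm_num <- function(e, tag) {
  s <- dcm_str(e, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_u16val <- function(e, tag) {
  x <- e[[tag]]
  if (is.null(x)) return(NULL)
  readBin(x$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, function(f) {
    e <- dcm_parse_file(f)
    rows <- dcm_u16val(e, "0028,0010"); cols <- dcm_u16val(e, "0028,0011")
    ipp <- dcm_num(e, "0020,0032"); iop <- dcm_num(e, "0020,0037")
    ps <- dcm_num(e, "0028,0030")
    if (is.null(rows) || is.null(cols) || is.null(ipp) || is.null(iop) ||
        is.null(ps))
      stop("DICOM slice missing required geometry tags: ", f, call. = FALSE)
    slope <- dcm_num(e, "0028,1053"); icpt <- dcm_num(e, "0028,1052")
    if (is.null(slope)) slope <- 1; if (is.null(icpt)) icpt <- 0
    signed <- identical(dcm_u16val(e, "0028,0103"), 1L)
    px <- e[["7fe0,0010"]]
    if (is.null(px)) stop("DICOM slice has no pixel data: ", f, call. = FALSE)
    stored <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
                      endian = "little", signed = signed)
    list(file = f, rows = rows, cols = cols, ipp = ipp,
         rdir = iop[1:3], cdir = iop[4:6], ps = ps,
         hu = slope * stored + icpt)
  })
  rdir <- slices[[1]]$rdir; cdir <- slices[[1]]$cdir
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  z <- vapply(slices, function(s) sum(s$ipp * normal), 0.0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(z)
    if (any(dz <= 0))
      stop("DICOM series has coincident slice positions", call. = FALSE)
    med <- stats::median(dz)
    bad <- which(abs(dz - med) > 1e-3 * max(1, med))
    if (length(bad) > 0L)
      stop(sprintf(paste0("inconsistent slice spacing in DICOM series ",
                          "(expected %.4f mm) between slices: %s"),
                   med, paste(vapply(bad, function(b)
                     sprintf("%s -> %s", basename(slices[[b]]$file),
                             basename(slices[[b + 1L]]$file)), ""),
                     collapse = ", ")),
           call. = FALSE)
    dz <- med
  } else dz <- 1
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  vals <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    if (s$cols != nx || s$rows != ny)
      stop("DICOM series has inconsistent slice dimensions", call. = FALSE)
    vals[, , k] <- array(s$hu, c(nx, ny))   # column index varies fastest
  }
  ps <- slices[[1]]$ps  # (row spacing, column spacing)
  volume(vals, spacing = c(ps[2], ps[1], dz), origin = slices[[1]]$ipp,
         axes = cbind(rdir, cdir, normal))
}
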