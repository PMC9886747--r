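# Programmatic fixtures: small analytic volumes and minimal DICOM series.

# a small axis-aligned volume filled by f(x, y, z) of world coordinates (mm)
fun_volume <- function(f, dim = c(12, 12, 12), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  g <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]), k = seq_len(dim[3]))
  x <- origin[1] + spacing[1] * (g$i - 1)
  y <- origin[2] + spacing[2] * (g$j - 1)
  z <- origin[3] + spacing[3] * (g$k - 1)
  volume(array(f(x, y, z), dim), spacing, origin)
}

# a compact phantom on a 58^3 grid at 1 mm spacing covering the same 57 mm
# world extent as the default (the residual cut plane at x = 40.5 again falls
# midway between voxel centers)
quick_spec <- function(...) {
  phantom_spec(grid_shape = c(58, 58, 58), spacing_mm = 1, ...)
}

# ---- minimal DICOM writer (explicit VR little endian) ----------------------

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, body) {
  if (length(body) %% 2 == 1) body <- c(body, as.raw(0))
  hdr <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "OD", "SQ", "UT", "UN"))
    c(hdr, as.raw(c(0, 0)), dcm_u32(length(body)), body)
  else
    c(hdr, dcm_u16(length(body)), body)
}

dcm_ds <- function(group, elem, values)
  dcm_element(group, elem, "DS", charToRaw(paste(format(values, trim = TRUE),
                                                 collapse = "\\")))
dcm_us <- function(group, elem, value)
  dcm_element(group, elem, "US", dcm_u16(value))

# one single-frame CT slice; `stored` is an integer vector of length
# rows * cols in row-major order (column index fastest)
write_dicom_slice <- function(path, stored, rows, cols, ipp,
                              iop = c(1, 0, 0, 0, 1, 0),
                              pixel_spacing = c(1, 1),
                              slope = 1, intercept = 0, signed = TRUE) {
  px <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  body <- c(
    dcm_ds(0x0020L, 0x0032L, ipp),
    dcm_ds(0x0020L, 0x0037L, iop),
    dcm_us(0x0028L, 0x0010L, rows),
    dcm_us(0x0028L, 0x0011L, cols),
    dcm_ds(0x0028L, 0x0030L, pixel_spacing),
    dcm_us(0x0028L, 0x0100L, 16),
    dcm_us(0x0028L, 0x0103L, if (signed) 1 else 0),
    dcm_ds(0x0028L, 0x1052L, intercept),
    dcm_ds(0x0028L, 0x1053L, slope),
    dcm_element(0x7FE0L, 0x0010L, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# a z-stack of nz slices with value_fun(k) filling slice k
write_dicom_series <- function(dir, nz = 4, rows = 6, cols = 5, dz = 1,
                               value_fun = function(k) rep(k, 6 * 5),
                               z_positions = NULL, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- z_positions %||% ((seq_len(nz) - 1) * dz)
  for (k in seq_len(nz))
    write_dicom_slice(file.path(dir, sprintf("slice%02d.dcm", k)),
                      stored = value_fun(k), rows = rows, cols = cols,
                      ipp = c(0, 0, z[k]), ...)
  dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero deformation field on a volume's grid
zero_field <- function(vol) {
  deformation_field(array(0, c(dim(vol$values), 3)), vol)
}

# spec with a pre+post feeder plus a post-only collateral reaching the same
# residual cap from the opposite side
two_vessel_spec <- function(...) {
  feeder <- list(points = rbind(c(40.5, 11, 40), c(44, 18, 38),
                                c(45, 24, 36), c(45, 28.5, 34)),
                 radius_mm = 1.2, phase = "both", role = "feeder")
  collateral <- list(points = rbind(c(40.5, 46, 40), c(44, 39, 38),
                                    c(45, 33, 36), c(45, 28.5, 34)),
                     radius_mm = 1.2, phase = "post_only", role = "collateral")
  phantom_spec(vessel_tree = list(feeder, collateral), ...)
}
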