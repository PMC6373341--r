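#' Read an image volume or mask from NIfTI or NRRD
#'
#' NIfTI-1 (`.nii`, `.nii.gz`) is read through RNifti; NRRD (`.nrrd`) with
#' a built-in reader supporting `raw` and `gzip` encodings. The returned
#' grid carries spacing and origin from the file header. Voxel order
#' follows the package convention: x fastest, axial slices along z (the
#' native order of both formats).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"nifti"` or `"nrrd"`.
#' @return a [voxel_grid].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  }
  if (format == "nifti") read_nifti_grid(path) else read_nrrd_grid(path)
}

#' Write a volume to NIfTI or NRRD
#'
#' @param grid a [voxel_grid] (logical values are written as 8-bit integers).
#' @param path destination; extension selects the format under `"auto"`.
#' @inheritParams read_volume
#' @return invisibly `path`.
#' @export
write_volume <- function(grid, path, format = c("auto", "nifti", "nrrd")) {
  stopifnot(inherits(grid, "voxel_grid"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  }
  if (format == "nifti") write_nifti_grid(grid, path) else write_nrrd_grid(grid, path)
  invisible(path)
}

read_nifti_grid <- function(path) {
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e)
                    stop(sprintf("cannot read '%s' as NIfTI: %s",
                                 path, conditionMessage(e))))
  values <- as.array(img)
  d <- dim(values)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) {
    stop(sprintf("'%s' is %dD; a 3D volume is required", path, length(d)))
  }
  values <- array(as.vector(values), d)  # drop RNifti header attributes
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  voxel_grid(values, spacing, origin)
}

write_nifti_grid <- function(grid, path) {
  vals <- grid$values
  if (is.logical(vals)) vals <- array(as.integer(vals), dim(vals))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 1L))
  RNifti::writeNifti(img, path)
}

# --- minimal NRRD support (no reader exists on CRAN/Bioconductor) --------

NRRD_TYPES <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE))

read_nrrd_grid <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) {
    stop(sprintf("cannot read '%s' as NRRD: bad magic '%s'", path, magic))
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop(sprintf("'%s': header not terminated", path))
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(m[2])]] <- m[3]
  }
  dim_n <- as.integer(fields[["dimension"]])
  if (is.na(dim_n) || dim_n != 3L) {
    stop(sprintf("'%s' is %sD; a 3D volume is required", path, fields[["dimension"]]))
  }
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  type <- NRRD_TYPES[[trimws(fields[["type"]])]]
  if (is.null(type)) stop(sprintf("'%s': unsupported NRRD type '%s'",
                                  path, fields[["type"]]))
  enc <- trimws(fields[["encoding"]])
  endian <- if (!is.null(fields[["endian"]])) trimws(fields[["endian"]]) else "little"
  n <- prod(sizes)
  if (enc == "raw") {
    values <- readBin(con, type$what, n = n, size = type$size,
                      signed = type$signed || type$size > 2, endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    payload <- readBin(con, "raw", n = file.info(path)$size)
    values <- readBin(memDecompress(payload, type = "gzip"), type$what, n = n,
                      size = type$size, signed = type$signed || type$size > 2,
                      endian = endian)
  } else {
    stop(sprintf("'%s': unsupported NRRD encoding '%s'", path, enc))
  }
  if (length(values) != n) stop(sprintf("'%s': truncated NRRD payload", path))
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spacing <- sqrt(colSums(mat^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  }
  voxel_grid(array(values, sizes), spacing, origin)
}

write_nrrd_grid <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- grid$values
  logical_mask <- is.logical(vals)
  header <- c(
    "NRRD0004",
    "# written by deltarad",
    sprintf("type: %s", if (logical_mask) "uchar" else "double"),
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(vals), collapse = " ")),
    sprintf("spacings: %s", paste(format(grid$spacing, digits = 17),
                                  collapse = " ")),
    sprintf("space origin: (%s)", paste(format(grid$origin, digits = 17),
                                        collapse = ",")),
    "encoding: raw",
    "endian: little",
    "")
  writeLines(header, con, sep = "\n")
  if (logical_mask) {
    writeBin(as.integer(vals), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
  }
}
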