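# Self-describing array files for dose grids and masks: a one-line JSON
# header (shape, origin, spacing, dtype) followed by a little-endian
# binary payload.

#' Write a dose grid to a self-describing array file
#'
#' @param grid a [DoseGrid-class].
#' @param path output file.
#' @export
writeDoseGrid <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(
    list(type = "DoseGrid", shape = dim(grid@values),
         origin_mm = grid@origin, spacing_mm = grid@spacing,
         dtype = "float64-le"),
    auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), con)
  writeBin(as.numeric(grid@values), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeDoseGrid
#' @export
readDoseGrid <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1))
  if (!identical(hdr$type, "DoseGrid")) stop("not a DoseGrid file")
  n <- prod(hdr$shape)
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  doseGrid(array(vals, hdr$shape), hdr$origin_mm, hdr$spacing_mm)
}

#' Write a structure mask to a self-describing array file
#'
#' @param mask a [StructureMask-class].
#' @param path output file.
#' @export
writeStructureMask <- function(mask, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(
    list(type = "StructureMask", name = mask@name, role = mask@role,
         shape = dim(mask@members), origin_mm = mask@origin,
         spacing_mm = mask@spacing, dtype = "uint8"),
    auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), con)
  writeBin(as.integer(mask@members), con, size = 1)
  invisible(path)
}

#' @rdname writeStructureMask
#' @export
readStructureMask <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1))
  if (!identical(hdr$type, "StructureMask")) stop("not a StructureMask file")
  n <- prod(hdr$shape)
  vals <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  structureMask(hdr$name, hdr$role, array(vals > 0, hdr$shape),
                hdr$origin_mm, hdr$spacing_mm)
}
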