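#' Write a 3D grid as an ASCII NRRD volume
#'
#' Minimal NRRD writer for density / material-id / dose grids: header with
#' dimension, sizes, spacings (mm) and axis mins, followed by
#' ASCII-encoded values in NRRD's fastest-first (x fastest) order, which
#' matches R's column-major array layout.
#'
#' @param grid 3D numeric array, optionally carrying `voxel_mm` /
#'   `origin_mm` attributes (e.g. from [export_ct()]).
#' @param path Output file path.
#' @param voxel_mm,origin_mm Lattice metadata; defaults to the grid's
#'   attributes, else 1 mm voxels at the origin.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(grid, path, voxel_mm = NULL, origin_mm = NULL) {
  stopifnot(length(dim(grid)) == 3L)
  if (is.null(voxel_mm)) voxel_mm <- attr(grid, "voxel_mm")
  if (is.null(origin_mm)) origin_mm <- attr(grid, "origin_mm")
  if (is.null(voxel_mm)) voxel_mm <- 1
  if (is.null(origin_mm)) origin_mm <- c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(grid), collapse = " ")),
    paste("spacings:", paste(rep(voxel_mm, 3), collapse = " ")),
    paste("axis mins:", paste(origin_mm, collapse = " ")),
    "encoding: ascii",
    ""
  ), con)
  writeLines(format(as.vector(grid), digits = 17, trim = TRUE,
                    scientific = TRUE), con)
  invisible(path)
}

#' Read an ASCII NRRD volume written by [write_nrrd()]
#'
#' @param path File path.
#' @return 3D array with `voxel_mm` and `origin_mm` attributes.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD"))
    stop("not an NRRD file", call. = FALSE)
  blank <- which(lines == "")[1]
  hdr <- lines[2:(blank - 1)]
  field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0(key, ":"))]
    if (!length(ln)) return(NULL)
    as.numeric(strsplit(sub(paste0(key, ": *"), "", ln[1]), " +")[[1]])
  }
  enc <- sub("encoding: *", "", hdr[startsWith(hdr, "encoding:")])
  if (enc != "ascii") stop("only ascii encoding supported", call. = FALSE)
  sizes <- as.integer(field("sizes"))
  vals <- as.numeric(unlist(strsplit(lines[(blank + 1):length(lines)],
                                     " +")))
  vals <- vals[!is.na(vals)]
  stopifnot(length(vals) == prod(sizes))
  grid <- array(vals, dim = sizes)
  attr(grid, "voxel_mm") <- field("spacings")[1]
  attr(grid, "origin_mm") <- field("axis mins")
  grid
}
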