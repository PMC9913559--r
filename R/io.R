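#' Read a CT volume from a NIfTI file
#'
#' Loads a 3D image and reorders it to the package's (slice, row, column)
#' axis convention, carrying the voxel spacing in mm. Values are taken as
#' Hounsfield units as stored (any rescue slope/intercept must already be
#' applied by the producer of the file).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [ct_volume()].
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stopf("expected a 3D volume, got %d dims", length(dim(a)))
  pix <- RNifti::pixdim(img)
  # NIfTI stores (x, y, z); internal order is (z, y, x)
  ct_volume(aperm(a, c(3L, 2L, 1L)), spacing = rev(pix[1:3]))
}

#' Read a per-slice mask stack (PNG or TIFF)
#'
#' Each file holds one slice's binary mask; files are stacked in
#' lexicographic order. Non-zero pixels are foreground.
#'
#' @param paths character vector of image files, one per slice.
#' @return logical 3D array (slice, row, column).
#' @export
read_mask_stack <- function(paths) {
  paths <- sort(paths)
  slices <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    m <- switch(ext,
      png = png::readPNG(p),
      tif = ,
      tiff = tiff::readTIFF(p),
      stopf("unsupported mask format '%s'", ext))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m > 0
  })
  d <- dim(slices[[1L]])
  if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1L))))
    stopf("mask slices differ in size")
  out <- array(FALSE, c(length(slices), d))
  for (k in seq_along(slices)) out[k, , ] <- slices[[k]]
  out
}

#' Plain-text array container
#'
#' A tiny whitespace format for exchanging numeric arrays with other
#' tools and for fixtures: the first line gives the dimensions, the rest
#' the values in R's column-major order.
#'
#' @param x numeric array.
#' @param path file path.
#' @return `read_array_text` returns the array; `write_array_text` its
#'   path, invisibly.
#' @export
write_array_text <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dim(x) %||% length(x), collapse = " "), con)
  writeLines(paste(format(as.vector(x), digits = 17, trim = TRUE),
                   collapse = " "), con)
  invisible(path)
}

#' @rdname write_array_text
#' @export
read_array_text <- function(path) {
  lines <- readLines(path, n = 2L)
  d <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  v <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  if (length(v) != prod(d)) stopf("array container is truncated")
  if (length(d) > 1L) array(v, d) else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export boundary curves as CSV
#'
#' Writes one row per vertex with columns `slice_index`, `vertex_order`,
#' `row`, `col`.
#'
#' @param curves list of [boundary_curve()] objects.
#' @param path output CSV path.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(slice_index = cv$slice_index,
               vertex_order = seq_len(nrow(cv$points)) - 1L,
               row = cv$points[, 1L], col = cv$points[, 2L])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
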