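# Full-precision CSV writing: %.17g round-trips IEEE doubles exactly.
write_full_precision_csv <- function(df, path) {
  df2 <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  names(df2) <- names(df)
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a multichannel image or sinogram as CSV
#'
#' Long-format table (`row`, `channel`, `value`) written with 17
#' significant digits so `float64` values round-trip exactly.
#'
#' @param X Numeric matrix (rows x channels).
#' @param path CSV path.
#' @return `write_channels_csv`: invisibly, `path`;
#'   `read_channels_csv`: the matrix.
#' @export
write_channels_csv <- function(X, path) {
  X <- as.matrix(X)
  df <- data.frame(
    row = rep(seq_len(nrow(X)), times = ncol(X)),
    channel = rep(seq_len(ncol(X)), each = nrow(X)),
    value = as.vector(X)
  )
  write_full_precision_csv(df, path)
}

#' @rdname write_channels_csv
#' @export
read_channels_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("row", "channel", "value") %in% names(df)))
  matrix(df$value, nrow = max(df$row), ncol = max(df$channel))
}

#' Reshape between image vectors and arrays
#'
#' The package stores an `n x n`, `M`-channel image as an `Nx x M` matrix
#' with the x pixel index fastest. These helpers convert to and from an
#' `n x n x M` array (x, y, material).
#'
#' @param X `Nx x M` matrix.
#' @param arr `n x n x M` array.
#' @param n Image side length.
#' @return An array, or a matrix.
#' @export
image_to_array <- function(X, n) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == n * n)
  array(X, dim = c(n, n, ncol(X)))
}

#' @rdname image_to_array
#' @export
array_to_image <- function(arr) {
  stopifnot(length(dim(arr)) == 3L)
  matrix(arr, nrow = dim(arr)[1] * dim(arr)[2], ncol = dim(arr)[3])
}
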