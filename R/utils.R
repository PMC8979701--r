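`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Coerce an image (H x W matrix or H x W x C array) or a batch (H x W x C x N)
# or a list of images into a 4-d (H, W, C, N) array.
as_image_batch <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, as_image_array)
    d <- dim(x[[1]])
    if (!all(vapply(x, function(im) identical(dim(im), d), logical(1))))
      stop("all images in a batch must share dimensions")
    return(array(unlist(x, use.names = FALSE), dim = c(d, length(x))))
  }
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L, 1L)))
  d <- dim(x)
  if (is.null(d)) stop("images must be matrices or arrays")
  if (length(d) == 3) return(array(x, dim = c(d, 1L)))
  if (length(d) == 4) return(x)
  stop("cannot interpret an array with ", length(d), " dimensions as an image batch")
}

# Single image as H x W x C.
as_image_array <- function(x) {
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  d <- dim(x)
  if (is.null(d) || length(d) != 3)
    stop("an image must be an H x W matrix or H x W x C array")
  x
}

batch_size_of <- function(x) dim(x)[4]

# index a 4-d batch along the sample axis
batch_subset <- function(x, idx) x[, , , idx, drop = FALSE]

clamp01 <- function(x) pmin(pmax(x, 0), 1)
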