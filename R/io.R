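#' Read a training manifest
#'
#' A manifest is a CSV with columns `filename,label`; `label` is the 0-based
#' integer class index for labeled rows and `-1` for unlabeled rows.
#' Filenames must be unique.
#'
#' @param path path to the CSV file.
#' @return A tibble with columns `filename` (character) and `label`
#'   (integer).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(df)))
    stop("manifest must have columns filename,label: ", path, call. = FALSE)
  if (anyDuplicated(df$filename))
    stop("duplicate filenames in manifest: ", path, call. = FALSE)
  if (nrow(df) && any(df$label < -1))
    stop("labels must be -1 (unlabeled) or a 0-based class index", call. = FALSE)
  tibble::tibble(filename = as.character(df$filename),
                 label = as.integer(df$label))
}

read_image_file <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  img <- as_image_array(img)
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Resize an image by bilinear interpolation
#'
#' @param image H x W x C array (or H x W matrix), intensities in [0, 1].
#' @param size target side length; output is `size` x `size` x C.
#' @return The resized array. A no-op when the image is already the target
#'   size.
#' @export
resize_image <- function(image, size) {
  image <- as_image_array(image)
  d <- dim(image)
  if (d[1] == size && d[2] == size) return(image)
  sr <- if (size == 1) matrix((d[1] + 1) / 2, 1, 1) else
    matrix(1 + (seq_len(size) - 1) * (d[1] - 1) / (size - 1), size, size)
  sc <- if (size == 1) matrix((d[2] + 1) / 2, 1, 1) else
    matrix(1 + (seq_len(size) - 1) * (d[2] - 1) / (size - 1), size, size, byrow = TRUE)
  bilinear_sample(image, sr, sc)
}

#' Load a dataset from a manifest of image files
#'
#' Reads every image referenced by the manifest, rescales intensities to
#' [0, 1] (PNG decoding already yields this scale), optionally resizes to
#' `target_size`, and splits rows into the labeled (label >= 0) and
#' unlabeled (label == -1) collections.
#'
#' @param manifest_path path to the manifest CSV.
#' @param image_root directory the manifest's filenames are relative to;
#'   defaults to the manifest's own directory.
#' @param target_size optional side length images are resized to.
#' @return A list with `labeled` (`x`, `y`, `filename`) and `unlabeled`
#'   (`x`, `filename`).
#' @export
load_dataset <- function(manifest_path, image_root = dirname(manifest_path),
                         target_size = NULL) {
  man <- read_manifest(manifest_path)
  imgs <- lapply(file.path(image_root, man$filename), read_image_file)
  if (!is.null(target_size))
    imgs <- lapply(imgs, resize_image, size = target_size)
  lab <- man$label >= 0
  empty <- function() array(0, dim = c(0, 0, 0, 0))
  list(labeled = list(
         x = if (any(lab)) as_image_batch(imgs[lab]) else empty(),
         y = man$label[lab],
         filename = man$filename[lab]),
       unlabeled = list(
         x = if (any(!lab)) as_image_batch(imgs[!lab]) else empty(),
         filename = man$filename[!lab]))
}

# ---- run configuration -----------------------------------------------------

check_known_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where, paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

#' Load and validate a run configuration from YAML
#'
#' The file describes a complete run: where the data come from (a manifest
#' or a synthetic spec), the training hyperparameters, the augmentation
#' policy, the evaluation options, and the root seed. Unknown keys anywhere
#' in the file are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A validated list with elements `seed`, `output_dir`, `data`,
#'   `config` (a [train_config()]), and `positive_class`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  resolve_run_config(raw)
}

#' @rdname load_run_config
#' @param raw a nested list with the same structure as the YAML file.
#' @export
resolve_run_config <- function(raw) {
  check_known_keys(raw, c("seed", "output_dir", "data", "train",
                          "augmentation", "evaluation"), "config")
  seed <- as.integer(raw$seed %||% 1L)
  aug <- raw$augmentation %||% list()
  check_known_keys(aug, names(formals(augmentation_policy)), "augmentation")
  policy <- do.call(augmentation_policy, aug)
  tr <- raw$train %||% list()
  check_known_keys(tr, setdiff(names(formals(train_config)), c("policy", "seed")),
                   "train")
  tr$gammas <- if (!is.null(tr$gammas)) as.numeric(unlist(tr$gammas))
  tr <- Filter(Negate(is.null), tr)
  config <- do.call(train_config, c(tr, list(policy = policy, seed = seed)))
  dat <- raw$data %||% list()
  if (!is.null(dat$manifest)) {
    check_known_keys(dat, c("manifest", "image_root", "target_size"), "data")
  } else {
    check_known_keys(dat, names(formals(synthetic_spec)), "data")
    if (is.null(dat$seed)) dat$seed <- seed
    dat <- list(synthetic = do.call(synthetic_spec, dat))
  }
  ev <- raw$evaluation %||% list()
  check_known_keys(ev, "positive_class", "evaluation")
  list(seed = seed, output_dir = raw$output_dir %||% ".", data = dat,
       config = config, positive_class = as.integer(ev$positive_class %||% 1L))
}

#' Write the fully resolved configuration of a run for provenance
#'
#' Every run records its resolved configuration, root seed and the package
#' version into `resolved-config.yaml` in the output directory, so the run
#' can be reproduced exactly. The written file re-parses to an equal
#' configuration.
#'
#' @param resolved a list as returned by [resolve_run_config()] or any
#'   serialisable configuration list.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the file path.
#' @export
write_run_provenance <- function(resolved, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(x) {
    if (inherits(x, c("train_config", "augmentation_policy", "synthetic_spec")))
      x <- unclass(x)
    if (is.list(x)) lapply(Filter(Negate(is.function), x), strip) else x
  }
  payload <- c(strip(resolved),
               list(package_version = as.character(utils::packageVersion("accnet"))))
  path <- file.path(out_dir, "resolved-config.yaml")
  yaml::write_yaml(payload, path)
  invisible(path)
}
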