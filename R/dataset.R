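# On-disk datasets: paired 8-bit RGB image / single-channel mask PNGs with
# a CSV manifest (filename, category, provenance), class-imbalance
# emulation with augmented top-up of rare categories, and seeded 6:2:2
# train/validation/test splitting with augmented items confined to train.

#' Write / read an 8-bit RGB image PNG
#' @param img numeric `[H, W, 3]` in `[0, 1]`; `path` file path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3), c(dim(v), 3))
  v[, , 1:3, drop = FALSE]
}

#' Write / read a single-channel class-code mask PNG
#'
#' Codes `0..n-1` are stored as the byte values `0..n-1`; the reader also
#' accepts 0/255-style binary masks.
#' @param mask integer matrix; `path` file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  b <- round(v * 255)
  if (any(b > 127)) b <- (b > 127) * 1 # 0/255-style binary mask
  matrix(as.integer(b), nrow(v), ncol(v))
}

# pseudo-category flavours of the scene generator: emulate the variety of
# field imagery (many fine pests; fewer large ones; barely visible ones)
category_spec <- function(category, height, width, seed) {
  switch(category,
    dense_small = scene_spec(height, width, n_pests = c(3L, 6L),
                             scale_range = c(0.04, 0.09), seed = seed),
    large_sparse = scene_spec(height, width, n_pests = c(1L, 2L),
                              scale_range = c(0.1, 0.16), seed = seed),
    low_contrast = scene_spec(height, width, n_pests = c(2L, 4L),
                              scale_range = c(0.05, 0.12), contrast = 0.18,
                              seed = seed),
    scene_spec(height, width, seed = seed))
}

scene_with_retry <- function(spec, seed) {
  for (k in 0:4) {
    spec$seed <- seed + k * 100003L
    sc <- tryCatch(generate_scene(spec), error = function(e) NULL)
    if (!is.null(sc)) return(sc)
  }
  stop("scene generation failed repeatedly")
}

#' Generate a synthetic dataset on disk
#'
#' Draws per-category image counts from `profile` (emulating class
#' imbalance), renders the scenes, then tops up categories below `floor`
#' with augmented copies of their own images. Writes paired PNGs and a
#' manifest CSV with per-image pseudo-category and provenance.
#'
#' @param out_dir output directory (created if needed).
#' @param n_images total original images when `profile` is `NULL`
#'   (distributed over the default categories with imbalanced weights).
#' @param profile named integer vector of per-category original counts;
#'   overrides `n_images`.
#' @param floor minimum images per category after augmented top-up.
#' @param height,width scene size.
#' @param seed RNG seed controlling scenes and augmentations.
#' @return the manifest `data.frame` (columns `image`, `mask`, `category`,
#'   `provenance`, `source`), invisibly; also written to
#'   `<out_dir>/manifest.csv`.
#' @export
generate_dataset <- function(out_dir, n_images = NULL, profile = NULL,
                             floor = 0L, height = 64L, width = 64L,
                             seed = 1L) {
  if (is.null(profile)) {
    if (is.null(n_images) || n_images < 1) stop("need n_images or profile")
    w <- c(dense_small = 0.6, large_sparse = 0.3, low_contrast = 0.1)
    cnt <- split_sizes(as.integer(n_images), w)
    profile <- stats::setNames(cnt, names(w))
  }
  if (is.null(names(profile))) stop("profile must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  id <- 0L
  for (cat in names(profile)) {
    for (i in seq_len(profile[[cat]])) {
      id <- id + 1L
      sc <- scene_with_retry(category_spec(cat, height, width, NA),
                             seed + id * 977L)
      fi <- sprintf("img_%04d.png", id)
      fm <- sprintf("mask_%04d.png", id)
      write_image_png(sc$image, file.path(out_dir, fi))
      write_mask_png(sc$mask, file.path(out_dir, fm))
      rows[[id]] <- data.frame(image = fi, mask = fm, category = cat,
                               provenance = "original", source = NA_character_)
    }
  }
  manifest <- do.call(rbind, rows)
  # top up rare categories with augmented copies of their own images
  for (cat in names(profile)) {
    have <- sum(manifest$category == cat)
    need <- max(0L, as.integer(floor) - have)
    if (need == 0L || have == 0L) next
    pool <- which(manifest$category == cat &
                    manifest$provenance == "original")
    for (j in seq_len(need)) {
      id <- id + 1L
      src <- manifest[pool[(j - 1L) %% length(pool) + 1L], ]
      img <- read_image_png(file.path(out_dir, src$image))
      msk <- read_mask_png(file.path(out_dir, src$mask))
      au <- augment(img, msk, augment_spec(seed = seed + id * 977L))
      fi <- sprintf("img_%04d.png", id)
      fm <- sprintf("mask_%04d.png", id)
      write_image_png(au$image, file.path(out_dir, fi))
      write_mask_png(au$mask, file.path(out_dir, fm))
      manifest <- rbind(manifest,
                        data.frame(image = fi, mask = fm, category = cat,
                                   provenance = "augmented",
                                   source = src$image))
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset directory into memory
#' @param dir directory written by [generate_dataset()].
#' @return list of items (`image`, `mask`) with the manifest as attribute.
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  items <- lapply(seq_len(nrow(manifest)), function(i)
    list(image = read_image_png(file.path(dir, manifest$image[i])),
         mask = read_mask_png(file.path(dir, manifest$mask[i]))))
  attr(items, "manifest") <- manifest
  items
}

# largest-remainder apportionment of n into length(ratios) parts
split_sizes <- function(n, ratios) {
  r <- ratios / sum(ratios)
  raw <- n * r
  sz <- floor(raw)
  rem <- n - sum(sz)
  if (rem > 0) {
    o <- order(raw - sz, decreasing = TRUE)
    sz[o[seq_len(rem)]] <- sz[o[seq_len(rem)]] + 1
  }
  as.integer(sz)
}

#' Split a dataset into train/validation/test indices
#'
#' Seeded shuffle then contiguous slicing, with subset sizes given by the
#' largest-remainder rule on the total count. Augmented items (per the
#' manifest's `provenance` column) are confined to the training subset;
#' validation and test are drawn from originals only.
#'
#' @param manifest a manifest `data.frame` (needs `provenance`), or a
#'   plain item count for an all-original dataset.
#' @param ratios train/val/test proportions (default 6:2:2).
#' @param seed shuffle seed.
#' @return an object of class `dataset_split`: list with integer index
#'   vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  n <- if (is.data.frame(manifest)) nrow(manifest) else as.integer(manifest)
  if (n < 3) stop("dataset must have at least 3 items")
  sz <- split_sizes(n, ratios)
  orig <- if (is.data.frame(manifest) && "provenance" %in% names(manifest))
    which(manifest$provenance != "augmented") else seq_len(n)
  if (length(orig) < sz[2] + sz[3])
    stop("not enough original items for validation and test subsets")
  with_seed(seed, {
    so <- sample(orig)
    val <- so[seq_len(sz[2])]
    test <- so[sz[2] + seq_len(sz[3])]
    train <- setdiff(seq_len(n), c(val, test))
    structure(list(train = sort(train), val = sort(val), test = sort(test)),
              class = "dataset_split")
  })
}
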