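# Dataset curation pipeline for whole-slide-derived patches: blank-patch
# filtering by white-pixel fraction, RGB-mean-distance ranking, top-k
# selection, and the seeded train/test split. The whole pipeline is a pure
# function of (directory listing, config, seed); rebuilding with the same
# inputs yields a byte-identical manifest.

#' Builder configuration
#'
#' Defaults reproduce the published curation recipe: grayscale binarization
#' threshold 224 (white = gray 225-255), removal of patches with more than
#' 60 percent white area, top 1,200 patches by distance of the per-image
#' RGB mean from the global RGB mean, split 1,000 train / 200 test.
#' @param gray_threshold 8-bit grayscale threshold; a pixel is white iff
#'   its gray value is strictly above it
#' @param white_fraction_max removal bound (strictly-greater fractions are
#'   dropped)
#' @param keep_top_k number of patches kept after ranking
#' @param train_count,test_count split sizes; must sum to `keep_top_k`
#' @param patch_size expected patch side length (informational)
#' @export
bcsr_config <- function(gray_threshold = 224L, white_fraction_max = 0.60,
                        keep_top_k = 1200L, train_count = 1000L,
                        test_count = 200L, patch_size = 1024L) {
  if (gray_threshold < 0L || gray_threshold > 255L)
    stop_validation("gray_threshold must be in [0, 255]")
  if (train_count + test_count != keep_top_k)
    stop_validation("train_count + test_count must equal keep_top_k")
  structure(list(gray_threshold = as.integer(gray_threshold),
                 white_fraction_max = white_fraction_max,
                 keep_top_k = as.integer(keep_top_k),
                 train_count = as.integer(train_count),
                 test_count = as.integer(test_count),
                 patch_size = as.integer(patch_size)),
            class = "bcsr_config")
}

#' White-pixel fraction of a patch
#'
#' Converts to 8-bit grayscale with the BT.601 luma
#' (0.299 R + 0.587 G + 0.114 B, rounded to integer) and returns the
#' fraction of pixels whose gray value is strictly above `gray_threshold`
#' (i.e. in 225-255 for the default threshold 224).
#' @param img RGB array in `[0,1]`
#' @param gray_threshold 8-bit threshold (default 224)
#' @export
white_fraction <- function(img, gray_threshold = 224L) {
  assert_image(img)
  gray <- round(255 * (0.299 * img[, , 1] + 0.587 * img[, , 2] +
                         0.114 * img[, , 3]))
  mean(gray > gray_threshold)
}

#' Scan patches into ranking records
#'
#' One record per file: path, white fraction, per-channel means, pixel
#' count. Distances are filled in by [rank_and_select()].
#' @param paths character vector of PNG paths
#' @param gray_threshold threshold for [white_fraction()]
#' @return data.frame of patch records
#' @export
scan_patches <- function(paths, gray_threshold = 224L) {
  recs <- lapply(paths, function(p) {
    img <- read_image_patch(p)
    m <- apply(img, 3L, mean)
    data.frame(path = p, white_fraction = white_fraction(img, gray_threshold),
               mean_r = m[1], mean_g = m[2], mean_b = m[3],
               n_pixels = prod(dim(img)[1:2]), stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Remove blank patches
#'
#' Keeps records with `white_fraction <= white_fraction_max` ("more than
#' 60 percent white" is removed, so exactly 60 percent is kept); input
#' order preserved.
#' @param records data.frame from [scan_patches()]
#' @param config a [bcsr_config()]
#' @export
filter_blank <- function(records, config = bcsr_config()) {
  records[records$white_fraction <= config$white_fraction_max, , drop = FALSE]
}

#' Rank by RGB-mean distance and keep the top k
#'
#' The global mean R_all is the pixel-weighted RGB mean over all surviving
#' patches; each record's distance is the Euclidean norm of (R_i - R_all).
#' Records are sorted by descending distance (ties broken by path) and the
#' top `keep_top_k` are returned with their distances.
#' @param records filtered records
#' @param config a [bcsr_config()]
#' @export
rank_and_select <- function(records, config = bcsr_config()) {
  n <- nrow(records)
  if (n < config$keep_top_k)
    stop_validation("only %d records survive filtering but keep_top_k = %d",
                    n, config$keep_top_k)
  w <- records$n_pixels / sum(records$n_pixels)
  r_all <- c(sum(w * records$mean_r), sum(w * records$mean_g),
             sum(w * records$mean_b))
  records$distance <- sqrt((records$mean_r - r_all[1])^2 +
                             (records$mean_g - r_all[2])^2 +
                             (records$mean_b - r_all[3])^2)
  ord <- order(-records$distance, records$path, method = "radix")
  out <- records[ord[seq_len(config$keep_top_k)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "r_all") <- r_all
  out
}

#' Assign train/test split labels
#'
#' Deterministic seeded shuffle; the first `train_count` shuffled records
#' become "train", the next `test_count` "test".
#' @param selected output of [rank_and_select()]
#' @param config a [bcsr_config()]
#' @param seed integer split seed
#' @export
split_records <- function(selected, config = bcsr_config(), seed = 1L) {
  n <- nrow(selected)
  stopifnot(n == config$train_count + config$test_count)
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(config$train_count)]] <- "train"
  split[perm[config$train_count + seq_len(config$test_count)]] <- "test"
  selected$split <- split
  selected
}

manifest_columns <- c("path", "split", "white_fraction", "mean_r", "mean_g",
                      "mean_b", "distance")

#' Write a dataset manifest
#'
#' Tab-separated with fixed 8-digit numeric formatting so that rebuilding
#' from identical inputs is byte-identical.
#' @param manifest data.frame with the manifest columns
#' @param path output TSV path
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest[, manifest_columns]
  for (col in c("white_fraction", "mean_r", "mean_g", "mean_b", "distance"))
    out[[col]] <- sprintf("%.8f", out[[col]])
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a dataset manifest
#' @param path manifest TSV
#' @export
read_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Build a curated super-resolution dataset from a patch directory
#'
#' Runs the full curation pipeline (scan, blank filter, distance ranking,
#' split) over all PNGs in `input_dir` and writes `manifest.tsv` plus a
#' `provenance.json` header (config, seed, tool version) into `output_dir`.
#' @param input_dir directory of RGB PNG patches
#' @param output_dir output directory (created if missing)
#' @param config a [bcsr_config()]
#' @param seed split seed
#' @return the manifest data.frame, invisibly
#' @export
bcsr_build <- function(input_dir, output_dir, config = bcsr_config(),
                       seed = 1L) {
  paths <- sort(list.files(input_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0) stop_validation("no PNG files in %s", input_dir)
  records <- scan_patches(paths, config$gray_threshold)
  kept <- filter_blank(records, config)
  selected <- rank_and_select(kept, config)
  manifest <- split_records(selected, config, seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(manifest, file.path(output_dir, "manifest.tsv"))
  prov <- list(tool = "carnsr",
               version = as.character(utils::packageVersion("carnsr")),
               seed = seed, config = unclass(config),
               n_input = length(paths), n_after_filter = nrow(kept),
               r_all = as.numeric(attr(selected, "r_all")))
  jsonlite::write_json(prov, file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
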