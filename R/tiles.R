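#' Tile an RGB image into 224x224 patches and filter background
#'
#' Non-overlapping grid tiling from the top-left corner; partial tiles at
#' the right/bottom edges are discarded. A pixel counts as background when
#' all three channels are at least 220 (near-white, the standard H&E
#' background rule), and a tile is discarded when its background-pixel
#' fraction reaches `background_threshold`.
#'
#' @param image H x W x 3 numeric array with values in \[0, 255\].
#' @param tile_size tile edge in pixels (default 224).
#' @param background_threshold fraction in \[0, 1\]; tiles whose background
#'   fraction is `>=` this are dropped.
#' @param source_magnification free-text provenance tag stored with the
#'   tile set.
#' @return list of class `cms_tileset`: `tiles` (list of
#'   `tile_size x tile_size x 3` arrays), `coords` (matrix of grid row/col
#'   indices), `n_grid` (total grid positions) and `n_discarded`.
#' @export
tile_and_filter <- function(image, tile_size = 224, background_threshold = 0.5,
                            source_magnification = "20x") {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_cms("image must be an H x W x 3 array")
  if (min(image) < 0 || max(image) > 255)
    stop_cms("pixel values must lie in [0, 255]")
  tile_size <- check_count(tile_size, "tile_size")
  check_prob(background_threshold, "background_threshold", open = FALSE)
  H <- dim(image)[1]; W <- dim(image)[2]
  nr <- H %/% tile_size; nc <- W %/% tile_size
  if (nr == 0 || nc == 0) {
    warning("image smaller than one tile; empty tile set", call. = FALSE)
    return(structure(list(tiles = list(), coords = matrix(0L, 0, 2),
                          n_grid = 0L, n_discarded = 0L,
                          source_magnification = source_magnification),
                     class = "cms_tileset"))
  }
  tiles <- list(); coords <- NULL; discarded <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rs <- (i - 1L) * tile_size + seq_len(tile_size)
      cs <- (j - 1L) * tile_size + seq_len(tile_size)
      tile <- image[rs, cs, , drop = FALSE]
      bg <- pmin(tile[, , 1], tile[, , 2], tile[, , 3]) >= 220
      if (mean(bg) >= background_threshold) {
        discarded <- discarded + 1L
      } else {
        tiles[[length(tiles) + 1L]] <- tile
        coords <- rbind(coords, c(i, j))
      }
    }
  }
  structure(list(tiles = tiles,
                 coords = if (is.null(coords)) matrix(0L, 0, 2) else coords,
                 n_grid = nr * nc, n_discarded = discarded,
                 source_magnification = source_magnification),
            class = "cms_tileset")
}

# mean-pool an image tile down to a grid x grid x 3 block summary
downsample_tile <- function(tile, grid = 16L) {
  d <- dim(tile)[1]
  cut_idx <- ceiling(seq_len(d) / (d / grid))
  out <- array(0, c(grid, grid, 3))
  for (ch in 1:3)
    out[, , ch] <- rowsum(t(rowsum(tile[, , ch], cut_idx)), cut_idx) /
      (d / grid)^2
  out
}

#' Deterministic stub tile encoder
#'
#' A desk-scale stand-in for a pretrained pathology encoder: each tile is
#' mean-pooled to a 16x16x3 block summary, flattened, scaled to \[0, 1\],
#' passed through a seeded Gaussian random linear projection to `dim`
#' dimensions, and squashed elementwise by `tanh` to (-1, 1). A pure
#' function of (pixels, seed, dim): identical tiles map to identical
#' embeddings.
#'
#' @param tileset a `cms_tileset` from [tile_and_filter()].
#' @param dim embedding dimension.
#' @param seed integer seed fixing the projection.
#' @return list of class `cms_tile_embeddings`: `embeddings` (tiles x dim
#'   matrix) and `tile_coords`.
#' @export
stub_encode_tiles <- function(tileset, dim = 32, seed = 0L) {
  dim <- check_count(dim, "dim")
  if (!length(tileset$tiles)) stop_cms("tile set is empty")
  grid <- 16L
  P <- with_seed(derive_seed(seed, "stub_proj"),
                 matrix(rnorm(grid * grid * 3 * dim) / sqrt(grid * grid * 3),
                        grid * grid * 3, dim))
  emb <- t(vapply(tileset$tiles, function(tile) {
    v <- as.vector(downsample_tile(tile, grid)) / 255
    tanh(as.vector(v %*% P))
  }, numeric(dim)))
  structure(list(embeddings = emb, tile_coords = tileset$coords,
                 dim = dim, seed = as.integer(seed)),
            class = "cms_tile_embeddings")
}

#' Write per-patient tile embeddings to a plain-text store
#'
#' Long-format CSV with columns `patient_id`, `tile`, `e1..eD`; one row per
#' tile. The store is self-describing (the embedding dimension is the
#' number of `e*` columns) and diff-friendly.
#'
#' @param embeddings named list of tiles x dim matrices (names = patient
#'   ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tile_embeddings <- function(embeddings, path) {
  if (is.null(names(embeddings)) || anyDuplicated(names(embeddings)))
    stop_cms("embeddings must be a named list with unique patient ids")
  dims <- vapply(embeddings, ncol, 1L)
  if (length(unique(dims)) != 1L)
    stop_cms("mixed embedding dimensions: ",
             paste(unique(dims), collapse = ", "))
  d <- dims[[1]]
  blocks <- lapply(names(embeddings), function(id) {
    M <- embeddings[[id]]
    data.frame(patient_id = id, tile = seq_len(nrow(M)),
               M, check.names = FALSE)
  })
  long <- do.call(rbind, blocks)
  names(long) <- c("patient_id", "tile", paste0("e", seq_len(d)))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Load per-patient tile embeddings from the plain-text store
#'
#' @param path CSV written by [write_tile_embeddings()].
#' @param manifest_ids optional character vector of required patient ids;
#'   missing patients raise an error listing them.
#' @return named list of tiles x dim matrices.
#' @export
load_tile_embeddings <- function(path, manifest_ids = NULL) {
  long <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ecols <- grep("^e[0-9]+$", names(long), value = TRUE)
  if (!length(ecols) || !all(c("patient_id", "tile") %in% names(long)))
    stop_cms("not a tile-embedding store: expected patient_id, tile, e1..eD")
  vals <- as.matrix(long[, ecols, drop = FALSE])
  if (any(!is.finite(vals))) stop_cms("non-finite embedding values in store")
  out <- lapply(split(seq_len(nrow(long)), long$patient_id), function(rows) {
    rows <- rows[order(long$tile[rows])]
    unname(vals[rows, , drop = FALSE])
  })
  if (!is.null(manifest_ids)) {
    missing <- setdiff(manifest_ids, names(out))
    if (length(missing))
      stop_cms("patients missing from embedding store: ",
               paste(missing, collapse = ", "))
    out <- out[manifest_ids]
  }
  out
}
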