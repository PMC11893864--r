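# Tabular-to-image conversion: correlation-clustered feature ordering,
# row-major square grid embedding with zero padding, and nearest-neighbor
# upscaling with channel replication. The embedding is lossless: the grid,
# the order and the padding mask recover the scaled record exactly.

#' Compute the correlation-clustering feature order
#'
#' Computes the Pearson correlation matrix of the (scaled) training
#' features, transforms it to a distance matrix (`1 - r` by default, the
#' signed form; `1 - |r|` optionally), applies agglomerative hierarchical
#' clustering, and reads the feature permutation off the dendrogram leaf
#' order. Correlated features thus end up spatially adjacent in the grid.
#' Constant features get zero correlation to everything (distance 1) with a
#' warning. The result is invariant to row permutations of the fitting data.
#'
#' @param train_scaled Numeric matrix (rows = records), typically the
#'   [apply_minmax()] output; at least 2 rows.
#' @param schema Optional [feature_schema()] used to label the order.
#' @param distance `"signed"` (d = 1 - r) or `"absolute"` (d = 1 - |r|).
#' @param linkage Agglomeration method: `"average"` (default), `"single"`
#'   or `"complete"`.
#' @return An object of class `feature_order`: list with `order` (integer
#'   permutation of 1..d), `features`, `distance`, `linkage` and a fitting
#'   fingerprint.
#' @export
compute_feature_order <- function(train_scaled, schema = NULL,
                                  distance = c("signed", "absolute"),
                                  linkage = c("average", "single", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- as.matrix(train_scaled)
  if (nrow(x) < 2L) tf_schema_error("feature ordering needs at least 2 rows")
  d <- ncol(x)
  if (d < 1L) tf_schema_error("feature ordering needs at least 1 feature")
  features <- colnames(x) %||% paste0("f", seq_len(d))
  if (!is.null(schema)) features <- schema_names(schema)
  if (d == 1L) {
    ord <- 1L
  } else {
    R <- safe_cor(x)
    D <- if (distance == "signed") 1 - R else 1 - abs(R)
    diag(D) <- 0
    hc <- stats::hclust(stats::as.dist(D), method = linkage)
    ord <- hc$order
  }
  structure(list(order = as.integer(ord), features = features,
                 distance = distance, linkage = linkage,
                 fingerprint = list(n = nrow(x), d = d,
                                    checksum = signif(sum(x), 12))),
            class = "feature_order")
}

#' @export
print.feature_order <- function(x, ...) {
  cat(sprintf("<feature_order> %s\n",
              paste(x$features[x$order], collapse = " > ")))
  invisible(x)
}

grid_side <- function(d) as.integer(ceiling(sqrt(d)))

#' Embed a scaled record into a square intensity grid
#'
#' Reorders the record by the clustering permutation and fills an s x s
#' grid row-major (top-left first), where `s = ceiling(sqrt(d))` (s = 4 for
#' the 13-feature schema). The trailing `s^2 - d` cells are set to exactly
#' 0 and masked as padding; for 13 features those are the last three cells
#' of the fourth row.
#'
#' @param record_scaled Length-d numeric vector with values in \[0, 1\].
#' @param order A [compute_feature_order()] result (or an integer
#'   permutation of 1..d).
#' @return An object of class `grid_image`: list with `grid` (s x s
#'   matrix), `mask` (s x s logical, TRUE on padded cells), `side`, `order`.
#' @export
embed_grid <- function(record_scaled, order) {
  perm <- if (inherits(order, "feature_order")) order$order else as.integer(order)
  d <- length(record_scaled)
  if (length(perm) != d || !setequal(perm, seq_len(d))) {
    tf_schema_error("order must be a permutation of 1..%d", d)
  }
  if (anyNA(record_scaled) || any(record_scaled < 0 | record_scaled > 1)) {
    tf_schema_error("record values must lie in [0, 1]; normalize before embedding")
  }
  s <- grid_side(d)
  padded <- c(as.numeric(record_scaled)[perm], rep(0, s * s - d))
  grid <- matrix(padded, nrow = s, byrow = TRUE)
  mask <- matrix(c(rep(FALSE, d), rep(TRUE, s * s - d)), nrow = s, byrow = TRUE)
  structure(list(grid = grid, mask = mask, side = s, order = perm),
            class = "grid_image")
}

#' Recover the scaled record from a grid image
#'
#' Inverts [embed_grid()]: reads the non-padded cells row-major and undoes
#' the feature permutation. Exact by construction.
#'
#' @param gi A `grid_image`.
#' @return Numeric vector in original feature order.
#' @export
unembed_grid <- function(gi) {
  vals_rowmajor <- as.numeric(t(gi$grid))[!as.logical(t(gi$mask))]
  out <- numeric(length(vals_rowmajor))
  out[gi$order] <- vals_rowmajor
  out
}

#' Upscale a grid to a 3-channel image
#'
#' Nearest-neighbor upscaling: when the grid side divides the target side
#' each source cell becomes a constant (S/s) x (S/s) pixel block (56 x 56
#' for the 4 -> 224 case), so the set of distinct pixel intensities equals
#' the set of distinct cell values. The grayscale plane is replicated into
#' 3 identical channels.
#'
#' @param gi A `grid_image` (or a bare numeric matrix).
#' @param target_side Output side in pixels (default 224); must be >= the
#'   grid side.
#' @return Numeric array `target_side x target_side x 3` with values in
#'   \[0, 1\].
#' @export
upscale <- function(gi, target_side = 224L) {
  grid <- if (inherits(gi, "grid_image")) gi$grid else as.matrix(gi)
  s <- nrow(grid)
  S <- as.integer(target_side)
  if (S < s) tf_schema_error("target_side (%d) must be at least the grid side (%d)", S, s)
  idx <- pmin.int(s, floor((seq_len(S) - 1L) * s / S) + 1L)
  plane <- grid[idx, idx, drop = FALSE]
  array(plane, dim = c(S, S, 3L))
}

#' Convert a scaled dataset into an image stack
#'
#' Applies [embed_grid()] and [upscale()] row by row, preserving row order.
#'
#' @param ds_scaled Numeric matrix of scaled records (rows) in \[0, 1\].
#' @param order A [compute_feature_order()] result.
#' @param target_side Output image side in pixels (default 224).
#' @return Numeric array `n x S x S x 3`.
#' @export
convert_dataset <- function(ds_scaled, order, target_side = 224L) {
  x <- as.matrix(ds_scaled)
  n <- nrow(x)
  S <- as.integer(target_side)
  stack <- array(0, dim = c(n, S, S, 3L))
  for (i in seq_len(n)) {
    stack[i, , , ] <- upscale(embed_grid(x[i, ], order), S)
  }
  stack
}

#' Export a grid image as an 8-bit grayscale PNG
#'
#' Inspection helper only; the pipeline itself passes float arrays. Pixel
#' value = round(255 * intensity).
#'
#' @param gi A `grid_image`.
#' @param path Output PNG path.
#' @param target_side Upscaled side in pixels (default 224).
#' @return `path`, invisibly.
#' @export
export_grid_png <- function(gi, path, target_side = 224L) {
  if (!requireNamespace("png", quietly = TRUE)) {
    tf_capability_error("the 'png' package is required for PNG export")
  }
  img <- upscale(gi, target_side)[, , 1L]
  png::writePNG(round(255 * img) / 255, path)
  invisible(path)
}
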