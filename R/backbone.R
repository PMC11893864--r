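# Frozen convolutional backbones for deep feature extraction. The default
# "toy" backbone is a small seeded stack of bias-free 3x3 convolutions,
# ReLU, global average pooling and a seeded linear projection: frozen at
# creation, bit-reproducible, and self-contained in the pipeline bundle.
# The "vgg16" adapter describes the pretrained-network route; it raises a
# capability error when the pretrained weights are not installed.

#' Create a frozen toy convolutional backbone
#'
#' Weights (3x3 convolution filters and the pooled-to-output projection)
#' are drawn once from a seeded normal distribution and never updated.
#' Convolutions are bias-free and the activation is ReLU, so an all-zero
#' image maps to the zero feature vector.
#'
#' @param seed Integer seed for the weights.
#' @param output_dim Length of the emitted feature vector (default 32).
#' @param input_side Expected image side in pixels (default 32).
#' @param n_filters Number of convolution filters (default 8).
#' @return An object of class `c("toy_backbone", "backbone_spec")`.
#' @export
make_toy_backbone <- function(seed = 1L, output_dim = 32L, input_side = 32L,
                              n_filters = 8L) {
  if (output_dim < 1L) tf_schema_error("output_dim must be at least 1")
  weights <- with_seed(seed, list(
    filters = array(stats::rnorm(3 * 3 * n_filters, sd = 0.5),
                    dim = c(3L, 3L, n_filters)),
    projection = matrix(stats::rnorm(n_filters * output_dim, sd = 1 / sqrt(n_filters)),
                        n_filters, output_dim)
  ))
  structure(list(backend = "toy", input_side = as.integer(input_side),
                 output_dim = as.integer(output_dim),
                 n_filters = as.integer(n_filters),
                 pooling = "average", seed = as.integer(seed),
                 frozen = TRUE, weights = weights),
            class = c("toy_backbone", "backbone_spec"))
}

#' Describe the VGG16 backbone
#'
#' Specifies the pretrained VGG16 route: 224-pixel input, the final
#' convolutional block's output reduced by global average pooling to a
#' 512-vector (or flattened to 25088 with `pooling = "flatten"`). The
#' adapter applies that network's standard input preprocessing internally.
#' Extraction requires the pretrained weights and a deep-learning runtime;
#' when they are not installed, [extract_features()] raises a capability
#' error suggesting the toy backbone.
#'
#' @param pooling `"average"` (512 features) or `"flatten"` (25088).
#' @return An object of class `c("vgg16_backbone", "backbone_spec")`.
#' @export
make_vgg16_backbone <- function(pooling = c("average", "flatten")) {
  pooling <- match.arg(pooling)
  structure(list(backend = "vgg16", input_side = 224L,
                 output_dim = if (pooling == "average") 512L else 25088L,
                 pooling = pooling, frozen = TRUE),
            class = c("vgg16_backbone", "backbone_spec"))
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone:%s> input %dpx, %d features, %s pooling, frozen\n",
              x$backend, x$input_side, x$output_dim, x$pooling))
  invisible(x)
}

#' Backbones are frozen: training always errors
#'
#' The transfer-learning design uses the backbone purely as a fixed feature
#' transform; no update path exists.
#'
#' @param backbone A `backbone_spec`.
#' @param ... Ignored.
#' @export
train_backbone <- function(backbone, ...) {
  tf_capability_error("backbones are frozen feature extractors; no training path exists")
}

#' Extract deep features from an image stack
#'
#' Applies the frozen backbone to each image and returns one fixed-length
#' feature row per image. Deterministic: the output depends only on the
#' backbone weights and the images.
#'
#' @param images Numeric array `n x S x S x 3` (from [convert_dataset()]),
#'   or a single `S x S x 3` image.
#' @param backbone A `backbone_spec`.
#' @return Numeric matrix `n x output_dim`.
#' @export
extract_features <- function(images, backbone) {
  if (length(dim(images)) == 3L) {
    images <- array(images, dim = c(1L, dim(images)))
  }
  dm <- dim(images)
  if (length(dm) != 4L || dm[4] != 3L) {
    tf_schema_error("images must be an n x S x S x 3 array")
  }
  if (dm[2] != dm[3] || dm[2] != backbone$input_side) {
    tf_schema_error("image side %d does not match the backbone's expected side %d",
                    dm[2], backbone$input_side)
  }
  if (backbone$backend == "vgg16") {
    tf_capability_error(paste0(
      "VGG16 pretrained weights are not installed in this environment; ",
      "use make_toy_backbone() for a self-contained frozen backbone"))
  }
  toy_extract(images, backbone)
}

# Vectorized toy forward pass, chunked to bound memory: grayscale ->
# zero-padded 'same' 3x3 convolutions -> ReLU -> global average pooling ->
# linear projection.
toy_extract <- function(images, backbone) {
  n <- dim(images)[1]
  S <- dim(images)[2]
  chunk <- max(1L, as.integer(2e7 / (S * S)))
  out <- matrix(0, n, backbone$output_dim)
  filters <- backbone$weights$filters
  nf <- dim(filters)[3]
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    m <- length(idx)
    gray <- (images[idx, , , 1L, drop = FALSE] +
             images[idx, , , 2L, drop = FALSE] +
             images[idx, , , 3L, drop = FALSE]) / 3
    gray <- array(gray, dim = c(m, S, S))
    padded <- array(0, dim = c(m, S + 2L, S + 2L))
    padded[, 2:(S + 1), 2:(S + 1)] <- gray
    pooled <- matrix(0, m, nf)
    for (f in seq_len(nf)) {
      conv <- array(0, dim = c(m, S, S))
      for (di in 0:2) for (dj in 0:2) {
        w <- filters[di + 1L, dj + 1L, f]
        if (w != 0) {
          conv <- conv + w * padded[, di + seq_len(S), dj + seq_len(S), drop = FALSE]
        }
      }
      conv[conv < 0] <- 0  # ReLU
      pooled[, f] <- rowMeans(matrix(conv, m, S * S))
    }
    out[idx, ] <- pooled %*% backbone$weights$projection
  }
  out
}
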