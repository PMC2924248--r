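#' Plan the tiling geometry of one hierarchy layer
#'
#' Nodes tile the previous layer's (square) feature map with receptive
#' fields of side \code{field_side} and an overlap of \code{overlap} units
#' per direction, i.e. a stride of \code{field_side - overlap}. The tiling
#' must cover the previous side exactly:
#' \code{(grid_side - 1) * stride + field_side == prev_side}.
#'
#' @param prev_side side length of the previous layer (pixels or nodes).
#' @param field_side receptive-field side length.
#' @param overlap overlap per direction, \code{0 <= overlap < field_side}.
#' @return an object of class \code{"layer_geometry"} with \code{grid_side}
#'   and \code{stride}.
#' @examples
#' plan_geometry(155, 10, 5)$grid_side  # 30
#' plan_geometry(30, 4, 2)$grid_side    # 14
#' @export
plan_geometry <- function(prev_side, field_side, overlap) {
  stopifnot(prev_side >= 1, field_side >= 1)
  if (overlap < 0 || overlap >= field_side || field_side > prev_side) {
    stop("need 0 <= overlap < field_side <= prev_side (got ",
         overlap, ", ", field_side, ", ", prev_side, ")")
  }
  stride <- field_side - overlap
  if ((prev_side - field_side) %% stride != 0L) {
    stop("receptive fields of side ", field_side, " with stride ", stride,
         " do not tile a side of ", prev_side, " exactly")
  }
  grid_side <- (prev_side - field_side) %/% stride + 1L
  structure(list(prev_side = as.integer(prev_side),
                 field_side = as.integer(field_side),
                 overlap = as.integer(overlap),
                 stride = as.integer(stride),
                 grid_side = as.integer(grid_side)),
            class = "layer_geometry")
}

#' @export
print.layer_geometry <- function(x, ...) {
  cat(sprintf("layer geometry: %d -> %d x %d grid (field %d, overlap %d)\n",
              x$prev_side, x$grid_side, x$grid_side, x$field_side, x$overlap))
  invisible(x)
}

## Index matrix for patch extraction. A feature map with `side` positions
## per side and `channels` channels is stored as a vector with the pixel
## index (row-major: (r-1)*side + c) fastest and the channel slowest.
## Patches are flattened the same way: pixels row-major within a channel,
## channels outermost. Columns of the result are grid locations in
## row-major order.
patch_index <- function(geom, channels) {
  s <- geom$prev_side
  f <- geom$field_side
  g <- geom$grid_side
  one <- matrix(0L, nrow = f * f, ncol = g * g)
  loc <- 0L
  for (gr in seq_len(g)) {
    rows <- (gr - 1L) * geom$stride + seq_len(f)
    for (gc in seq_len(g)) {
      cols <- (gc - 1L) * geom$stride + seq_len(f)
      loc <- loc + 1L
      one[, loc] <- as.integer(outer(cols, (rows - 1L) * s, `+`))
    }
  }
  if (channels == 1L) return(one)
  do.call(rbind, lapply(seq_len(channels) - 1L,
                        function(ch) one + ch * s * s))
}

#' Gather weight-sharing training patches from a feature-map sequence
#'
#' Under weight sharing a single node is trained with stimuli from every
#' grid location of its layer, so each frame contributes one sample per
#' location. Samples are returned time-major (all locations of frame 1,
#' then frame 2, ...); within a sample, pixels are row-major within a
#' channel with channels outermost.
#'
#' @param maps numeric matrix, T frames x (side^2 * channels), in the map
#'   layout described above.
#' @param geometry a [plan_geometry()] result for this layer.
#' @param channels number of channels per map position.
#' @return numeric matrix with \code{T * grid_side^2} rows and
#'   \code{field_side^2 * channels} columns.
#' @export
gather_patches <- function(maps, geometry, channels = 1L) {
  maps <- as_timeseries(maps)
  s <- geometry$prev_side
  if (ncol(maps) != s * s * channels) {
    stop("map has ", ncol(maps), " values per frame; geometry expects ",
         s * s * channels)
  }
  idx <- patch_index(geometry, channels)
  out <- matrix(0, nrow = nrow(maps) * ncol(idx), ncol = nrow(idx))
  for (t in seq_len(nrow(maps))) {
    out[(t - 1L) * ncol(idx) + seq_len(ncol(idx)), ] <-
      t(matrix(maps[t, ][idx], nrow = nrow(idx)))
  }
  out
}

#' Configure a hierarchical SFA network
#'
#' Defaults reproduce the full-scale architecture: 155 x 155 input; four
#' layers with receptive fields 10 px / 4 / 4 / 6 nodes, overlaps 5 / 2 /
#' 2 / 0 (grids 30, 14, 6, 1); first-stage dimensions 32, 32, 42, 52 and
#' node outputs 32, 32, 32, 64; 50,000 training frames for the two lower
#' layers and 200,000 for the upper layers.
#'
#' @param image_side input image side in pixels.
#' @param layers list with one entry per layer, each a list with
#'   \code{field_side}, \code{overlap} and \code{spec} (a [node_spec()]).
#' @param n_frames_lower training frames for the lower half of the layers.
#' @param n_frames_upper training frames for the upper half.
#' @return an object of class \code{"hierarchy_config"} with validated
#'   per-layer geometries.
#' @export
hierarchy_config <- function(image_side = 155,
                             layers = NULL,
                             n_frames_lower = 50000,
                             n_frames_upper = 200000) {
  if (is.null(layers)) {
    layers <- list(
      list(field_side = 10, overlap = 5, spec = node_spec(32, 32)),
      list(field_side = 4, overlap = 2, spec = node_spec(32, 32)),
      list(field_side = 4, overlap = 2, spec = node_spec(42, 32)),
      list(field_side = 6, overlap = 0, spec = node_spec(52, 64))
    )
  }
  geoms <- vector("list", length(layers))
  side <- image_side
  channels <- 1L
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    geoms[[l]] <- tryCatch(
      plan_geometry(side, ly$field_side, ly$overlap),
      error = function(e) stop("layer ", l, ": ", conditionMessage(e)))
    patch_dim <- geoms[[l]]$field_side^2 * channels
    if (ly$spec$sfa1_dim > patch_dim) {
      stop("layer ", l, ": sfa1_dim ", ly$spec$sfa1_dim,
           " exceeds patch dimensionality ", patch_dim)
    }
    side <- geoms[[l]]$grid_side
    channels <- ly$spec$sfa2_dim
  }
  if (side != 1L) {
    stop("top layer has grid side ", side, "; must converge to a single node")
  }
  structure(list(image_side = as.integer(image_side), layers = layers,
                 geoms = geoms,
                 n_frames_lower = n_frames_lower,
                 n_frames_upper = n_frames_upper,
                 top_output_dim = layers[[length(layers)]]$spec$sfa2_dim),
            class = "hierarchy_config")
}

#' Reduced-scale hierarchy configurations
#'
#' Profiles that preserve the architectural ratios (converging overlapping
#' receptive fields, weight sharing, per-node quadratic expansion) at sizes
#' suited to interactive runs. \code{"smoke"}: 40 px input, three layers
#' with grids 9 / 4 / 1. \code{"desk"}: 63 px input, three layers with
#' grids 10 / 4 / 1 and a 32-dimensional top output.
#'
#' @param profile \code{"smoke"} or \code{"desk"}.
#' @param n_frames_lower,n_frames_upper training frames per layer group.
#' @export
scaled_hierarchy_config <- function(profile = c("desk", "smoke"),
                                    n_frames_lower = NULL,
                                    n_frames_upper = NULL) {
  profile <- match.arg(profile)
  if (profile == "smoke") {
    cfg <- hierarchy_config(
      image_side = 40,
      layers = list(
        list(field_side = 8, overlap = 4, spec = node_spec(12, 12)),
        list(field_side = 3, overlap = 1, spec = node_spec(12, 12)),
        list(field_side = 4, overlap = 0, spec = node_spec(16, 24))
      ),
      n_frames_lower = n_frames_lower %||% 2000,
      n_frames_upper = n_frames_upper %||% 3000)
  } else {
    cfg <- hierarchy_config(
      image_side = 63,
      layers = list(
        list(field_side = 9, overlap = 3, spec = node_spec(16, 16)),
        list(field_side = 4, overlap = 2, spec = node_spec(16, 16)),
        list(field_side = 4, overlap = 0, spec = node_spec(24, 32))
      ),
      n_frames_lower = n_frames_lower %||% 10000,
      n_frames_upper = n_frames_upper %||% 10000)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a hierarchical SFA (or PCA) network
#'
#' Layers are trained sequentially from bottom to top with weight sharing:
#' one node per layer is fitted on patches from every grid location and
#' replicated across the layer. The lower half of the layers is trained on
#' \code{n_frames_lower} frames and the upper half on
#' \code{n_frames_upper}; each layer group gets a freshly generated stream
#' with identical random-walk parameters.
#'
#' @param stream_fn function \code{(n, seed)} returning an \code{n} x
#'   \code{image_side^2} matrix of frames (row-major pixels in [0, 1]),
#'   e.g. a closure over [generate_training_stream()].
#' @param config a [hierarchy_config()].
#' @param variant \code{"sfa"} (rank by slowness) or \code{"pca"} (rank by
#'   explained variance; identical tiling, training protocol, expansion and
#'   dimensions).
#' @param seed integer seed from which per-layer-group stream seeds and the
#'   training noise are derived.
#' @param verbose print per-layer progress.
#' @return an object of class \code{"sfa_hierarchy"}.
#' @export
sfa_hierarchy <- function(stream_fn, config, variant = c("sfa", "pca"),
                          seed = 1L, verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "hierarchy_config"))
  n_layers <- length(config$layers)
  lower <- seq_len(ceiling(n_layers / 2))
  seeds <- derive_seeds(seed, 2L + 1L)
  nodes <- vector("list", n_layers)

  groups <- list(lower = lower, upper = setdiff(seq_len(n_layers), lower))
  maps <- NULL
  set.seed(seeds[3L])  # training-noise stream
  for (g in seq_along(groups)) {
    idx_layers <- groups[[g]]
    if (length(idx_layers) == 0L) next
    n_frames <- if (g == 1L) config$n_frames_lower else config$n_frames_upper
    if (verbose) message("rendering ", n_frames, " frames (group ", g, ")")
    maps <- stream_fn(n_frames, seeds[g])
    channels <- 1L
    ## replay already-trained layers on this group's stream
    for (l in seq_len(min(idx_layers) - 1L)) {
      maps <- apply_layer(nodes[[l]], maps, config$geoms[[l]], channels)
      channels <- nodes[[l]]$out_dim
    }
    for (l in idx_layers) {
      geom <- config$geoms[[l]]
      idx <- patch_index(geom, channels)
      get_block <- function(t) {
        t(matrix(maps[t, ][idx], nrow = nrow(idx)))
      }
      if (verbose) message("fitting layer ", l, " (", nrow(idx),
                           "-dim patches, ", ncol(idx), " locations)")
      nodes[[l]] <- tryCatch(
        fit_node_stream(get_block, nrow(maps), nrow(idx),
                        config$layers[[l]]$spec, variant),
        error = function(e) stop("layer ", l, ": ", conditionMessage(e)))
      if (l < max(idx_layers)) {
        maps <- apply_layer(nodes[[l]], maps, geom, channels)
      }
      channels <- nodes[[l]]$out_dim
    }
  }
  model <- structure(list(nodes = nodes, config = config, variant = variant,
                          top_output_dim = nodes[[n_layers]]$out_dim,
                          seed = seed),
                     class = "sfa_hierarchy")
  model$idx <- hierarchy_indices(model)
  model
}

hierarchy_indices <- function(model) {
  channels <- 1L
  idx <- vector("list", length(model$nodes))
  for (l in seq_along(model$nodes)) {
    idx[[l]] <- patch_index(model$config$geoms[[l]], channels)
    channels <- model$nodes[[l]]$out_dim
  }
  idx
}

## Apply a fitted node across a whole map sequence, returning the next
## layer's map sequence (T x grid_side^2 * out_dim). Output layout matches
## patch_index(): position row-major fastest, channel slowest.
apply_layer <- function(node, maps, geom, channels) {
  idx <- patch_index(geom, channels)
  n_loc <- ncol(idx)
  out <- matrix(0, nrow = nrow(maps), ncol = n_loc * node$out_dim)
  for (t in seq_len(nrow(maps))) {
    p <- t(matrix(maps[t, ][idx], nrow = nrow(idx)))
    out[t, ] <- as.vector(predict(node, p))  # column-major: pos fast, ch slow
  }
  out
}

#' Project images through a trained hierarchy
#'
#' Deterministic forward pass: per-layer patch extraction, shared-node
#' application and feature-map reassembly. Because the top outputs are
#' ordered by slowness, selecting the \code{n_features} slowest outputs is
#' a prefix of the full output vector.
#'
#' @param object trained \code{"sfa_hierarchy"}.
#' @param newdata one image (side x side matrix or length side^2 row-major
#'   vector) or a T x side^2 matrix of frames.
#' @param n_features keep only the \code{n_features} slowest outputs
#'   (default: all).
#' @param ... unused.
#' @return feature vector (single image) or T x n_features matrix.
#' @export
predict.sfa_hierarchy <- function(object, newdata, n_features = NULL, ...) {
  side <- object$config$image_side
  single <- FALSE
  if (is.matrix(newdata) && nrow(newdata) == side && ncol(newdata) == side) {
    newdata <- matrix(as.vector(t(newdata)), nrow = 1L)
    single <- TRUE
  } else if (is.vector(newdata) && is.numeric(newdata)) {
    if (length(newdata) != side * side) {
      stop("image has ", length(newdata), " pixels; model expects ",
           side * side)
    }
    newdata <- matrix(newdata, nrow = 1L)
    single <- TRUE
  }
  newdata <- as_timeseries(newdata)
  if (ncol(newdata) != side * side) {
    stop("frames have ", ncol(newdata), " pixels; model expects ", side * side)
  }
  maps <- newdata
  channels <- 1L
  for (l in seq_along(object$nodes)) {
    maps <- apply_layer(object$nodes[[l]], maps, object$config$geoms[[l]],
                        channels)
    channels <- object$nodes[[l]]$out_dim
  }
  if (!is.null(n_features)) {
    if (n_features > ncol(maps)) {
      stop("requested ", n_features, " features but the model provides ",
           ncol(maps))
    }
    maps <- maps[, seq_len(n_features), drop = FALSE]
  }
  if (single) drop(maps) else maps
}

#' @export
print.sfa_hierarchy <- function(x, ...) {
  cat(sprintf("Hierarchical %s network: %d x %d input -> %d features\n",
              toupper(x$variant), x$config$image_side, x$config$image_side,
              x$top_output_dim))
  for (l in seq_along(x$nodes)) {
    g <- x$config$geoms[[l]]
    cat(sprintf("  layer %d: %d x %d grid, field %d, overlap %d, node %d -> %d\n",
                l, g$grid_side, g$grid_side, g$field_side, g$overlap,
                x$nodes[[l]]$d, x$nodes[[l]]$out_dim))
  }
  invisible(x)
}

#' @export
summary.sfa_hierarchy <- function(object, ...) {
  top <- object$nodes[[length(object$nodes)]]
  out <- list(variant = object$variant,
              image_side = object$config$image_side,
              top_output_dim = object$top_output_dim,
              top_values = top$sfa2$values)
  class(out) <- "summary.sfa_hierarchy"
  out
}

#' @export
print.summary.sfa_hierarchy <- function(x, ...) {
  cat(sprintf("%s hierarchy on %d x %d input, %d top outputs\n",
              toupper(x$variant), x$image_side, x$image_side,
              x$top_output_dim))
  lab <- if (x$variant == "sfa") "top delta values" else "top variances"
  cat(lab, "(first 8):", format(signif(utils::head(x$top_values, 8), 3)), "\n")
  invisible(x)
}
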