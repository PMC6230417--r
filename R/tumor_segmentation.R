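#' Train the backpropagation voxel classifier
#'
#' A four-layer feed-forward network (input, two hidden layers, one output
#' unit) with logistic sigmoid activations throughout, trained by full-batch
#' gradient descent on the cross-entropy loss. Features are standardized
#' with the training mean and standard deviation; the normalization is
#' stored in the model and re-applied at prediction time. Training is
#' deterministic for a fixed seed.
#'
#' @param features numeric matrix or data.frame of feature rows (the 10
#'   columns of [feature_map()]; index columns `z,y,x` are dropped if
#'   present).
#' @param labels 0/1 (or logical) tumor labels, one per row; both classes
#'   must be present.
#' @param hidden sizes of the two hidden layers, default `c(16, 8)`.
#' @param learning_rate gradient step size, default 0.5.
#' @param epochs full-batch epochs, default 1500.
#' @param seed RNG seed for the weight initialization, default 1.
#' @return Object of class `tumor_classifier` with layer sizes, weights,
#'   biases, feature normalization and training metadata (including the
#'   final training loss).
#' @export
train_classifier <- function(features, labels, hidden = c(16L, 8L),
                             learning_rate = 0.5, epochs = 1500L, seed = 1L) {
  X <- .feature_matrix(features)
  y <- as.numeric(as.logical(labels))
  if (length(y) != nrow(X)) {
    stop_ctb("train_classifier: labels length does not match feature rows",
             class = "ctb_contract_error")
  }
  bad <- which(!apply(X, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop_ctb("train_classifier: non-finite features in row(s) ",
             paste(head(bad, 5L), collapse = ", "),
             class = "ctb_validation_error")
  }
  if (length(unique(y)) < 2L) {
    stop_ctb("train_classifier: need examples of both classes",
             class = "ctb_training_error")
  }
  if (length(hidden) != 2L || any(hidden < 1L)) {
    stop_ctb("train_classifier: `hidden` must give two positive layer sizes",
             class = "ctb_contract_error")
  }

  center <- colMeans(X)
  scale <- apply(X, 2L, function(c_) sqrt(mean((c_ - mean(c_))^2)))
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  sizes <- c(ncol(X), as.integer(hidden), 1L)
  W <- vector("list", 3L)
  b <- vector("list", 3L)
  with_seed(seed, {
    for (l in 1:3) {
      # small uniform init scaled by fan-in keeps sigmoids unsaturated
      r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -r, r),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })

  sig <- function(z) 1 / (1 + exp(-z))
  n <- nrow(Xs)
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    a1 <- sig(sweep(Xs %*% W[[1]], 2L, b[[1]], "+"))
    a2 <- sig(sweep(a1 %*% W[[2]], 2L, b[[2]], "+"))
    p <- sig(sweep(a2 %*% W[[3]], 2L, b[[3]], "+"))[, 1L]
    # cross-entropy gradient at the logistic output simplifies to (p - y)
    d3 <- matrix(p - y, ncol = 1L) / n
    d2 <- (d3 %*% t(W[[3]])) * a2 * (1 - a2)
    d1 <- (d2 %*% t(W[[2]])) * a1 * (1 - a1)
    W[[3]] <- W[[3]] - learning_rate * t(a2) %*% d3
    b[[3]] <- b[[3]] - learning_rate * colSums(d3)
    W[[2]] <- W[[2]] - learning_rate * t(a1) %*% d2
    b[[2]] <- b[[2]] - learning_rate * colSums(d2)
    W[[1]] <- W[[1]] - learning_rate * t(Xs) %*% d1
    b[[1]] <- b[[1]] - learning_rate * colSums(d1)
  }
  a1 <- sig(sweep(Xs %*% W[[1]], 2L, b[[1]], "+"))
  a2 <- sig(sweep(a1 %*% W[[2]], 2L, b[[2]], "+"))
  p <- sig(sweep(a2 %*% W[[3]], 2L, b[[3]], "+"))[, 1L]
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))

  W <- lapply(W, function(w) { dimnames(w) <- NULL; w })
  structure(list(layer_sizes = sizes, weights = W, biases = b,
                 activation = "logistic",
                 center = center, scale = scale,
                 feature_names = colnames(X),
                 training = list(seed = seed, epochs = as.integer(epochs),
                                 learning_rate = learning_rate,
                                 final_loss = loss)),
            class = "tumor_classifier")
}

.feature_matrix <- function(features) {
  X <- as.data.frame(features)
  X <- X[setdiff(names(X), c("z", "y", "x"))]
  as.matrix(X)
}

#' @export
print.tumor_classifier <- function(x, ...) {
  cat(sprintf("<tumor_classifier> layers %s, logistic, final loss %.4g\n",
              paste(x$layer_sizes, collapse = "-"),
              x$training$final_loss))
  invisible(x)
}

#' Tumor probability of feature rows
#'
#' Forward pass of the trained network; output is strictly inside (0, 1).
#'
#' @param object a [train_classifier()] model.
#' @param newdata feature rows in the training column order.
#' @param ... unused.
#' @return Numeric vector of tumor probabilities.
#' @export
predict.tumor_classifier <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata)
  if (ncol(X) != object$layer_sizes[1]) {
    stop_ctb("predict: feature dimension ", ncol(X), " does not match the ",
             "trained input size ", object$layer_sizes[1],
             class = "ctb_contract_error")
  }
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  sig <- function(z) 1 / (1 + exp(-z))
  a <- Xs
  for (l in 1:3) {
    a <- sig(sweep(a %*% object$weights[[l]], 2L, object$biases[[l]], "+"))
  }
  as.numeric(a)
}

#' Classify ROI voxels as tumor
#'
#' Applies the voxel classifier to a feature table and assembles the binary
#' tumor mask over the ROI: a voxel is tumor iff its forward-pass
#' probability is `>= threshold`. Raising the threshold can only remove
#' voxels.
#'
#' @param model a [train_classifier()] model.
#' @param features a [feature_map()] table (must carry `z, y, x` columns).
#' @param roi the [ct_mask()] the features were computed over; supplies the
#'   output grid.
#' @param threshold probability cut, default 0.5.
#' @return A [ct_mask()] of tumor voxels (subset of the ROI).
#' @export
classify_voxels <- function(model, features, roi, threshold = 0.5) {
  stopifnot(inherits(roi, "ct_mask"))
  p <- predict(model, features)
  tumor <- p >= threshold
  out <- array(FALSE, dim = dim(roi$data))
  idx <- cbind(features$z, features$y, features$x)
  if (any(idx < 1L) || any(sweep(idx, 2L, dim(out), ">") )) {
    stop_ctb("classify_voxels: feature voxel indices outside the grid",
             class = "ctb_contract_error")
  }
  out[idx] <- tumor
  ct_mask(out, spacing = roi$spacing)
}

#' Morphological clean-up of a tumor mask
#'
#' Closing (fills small interior holes) followed by opening (removes
#' isolated noise voxels), each with a ball structuring element. Radii of 0
#' disable the corresponding step, so `postprocess_mask(m, 0, 0)` is the
#' identity.
#'
#' @param mask a [ct_mask()] or logical array.
#' @param closing_radius_vox,opening_radius_vox ball radii in voxels
#'   (default 1 each).
#' @return Mask of the same type as the input.
#' @export
postprocess_mask <- function(mask, closing_radius_vox = 1L,
                             opening_radius_vox = 1L) {
  if (closing_radius_vox < 0L || opening_radius_vox < 0L) {
    stop_ctb("postprocess_mask: radii must be >= 0",
             class = "ctb_contract_error")
  }
  out <- binary_close(mask, closing_radius_vox)
  binary_open(out, opening_radius_vox)
}

#' Apply batch radiologist edits to a mask
#'
#' Stand-in for interactive refinement: a list of voxel-level `add` /
#' `remove` actions applied in one pass. Applying the same edit list twice
#' gives the same mask (idempotent).
#'
#' @param mask a [ct_mask()].
#' @param edits data.frame with columns `z, y, x, action`
#'   (`action` in `add`, `remove`), e.g. from [read_edits()].
#' @return The edited [ct_mask()].
#' @export
apply_refinement <- function(mask, edits) {
  stopifnot(inherits(mask, "ct_mask"))
  edits <- as.data.frame(edits)
  if (nrow(edits) == 0L) return(mask)
  required <- c("z", "y", "x", "action")
  if (!all(required %in% names(edits))) {
    stop_ctb("apply_refinement: edits need columns z, y, x, action",
             class = "ctb_validation_error")
  }
  if (!all(edits$action %in% c("add", "remove"))) {
    stop_ctb("apply_refinement: actions must be 'add' or 'remove'",
             class = "ctb_validation_error")
  }
  d <- dim(mask$data)
  idx <- as.matrix(edits[c("z", "y", "x")])
  storage.mode(idx) <- "integer"
  if (any(idx < 1L) || any(sweep(idx, 2L, d, ">"))) {
    stop_ctb("apply_refinement: edit voxel outside the grid",
             class = "ctb_validation_error")
  }
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  conflict <- tapply(edits$action, key, function(a) length(unique(a)) > 1L)
  if (any(conflict)) {
    stop_ctb("apply_refinement: conflicting add/remove for voxel(s) ",
             paste(names(conflict)[conflict], collapse = "; "),
             class = "ctb_validation_error")
  }
  out <- mask$data
  out[idx[edits$action == "add", , drop = FALSE]] <- TRUE
  out[idx[edits$action == "remove", , drop = FALSE]] <- FALSE
  ct_mask(out, spacing = mask$spacing)
}

#' Read a refinement edit list from CSV
#'
#' @param path CSV with header `z,y,x,action`.
#' @return A data.frame accepted by [apply_refinement()].
#' @export
read_edits <- function(path) {
  if (!file.exists(path)) {
    stop_ctb("file not found: ", path, class = "ctb_io_error")
  }
  read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load a voxel classifier as JSON
#'
#' The model file stores layer sizes, feature normalization, weights and
#' biases as nested lists at full numeric precision, so that
#' save -> load -> classify reproduces masks exactly.
#'
#' @param model a [train_classifier()] model.
#' @param path JSON file path.
#' @return `save_classifier`: `path`, invisibly. `load_classifier`: the
#'   model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "tumor_classifier"))
  obj <- unclass(model)
  obj$weights <- lapply(obj$weights, function(w) {
    list(dim = dim(w), values = as.numeric(w))
  })
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) {
    stop_ctb("file not found: ", path, class = "ctb_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  structure(list(
    layer_sizes = as.integer(num(obj$layer_sizes)),
    weights = lapply(obj$weights, function(w) {
      d <- as.integer(num(w$dim))
      matrix(num(w$values), d[1], d[2])
    }),
    biases = lapply(obj$biases, num),
    activation = obj$activation,
    center = num(obj$center),
    scale = num(obj$scale),
    feature_names = vapply(obj$feature_names, as.character, character(1)),
    training = list(seed = obj$training$seed,
                    epochs = as.integer(obj$training$epochs),
                    learning_rate = as.numeric(obj$training$learning_rate),
                    final_loss = as.numeric(obj$training$final_loss))),
    class = "tumor_classifier")
}

#' Segment tumors inside a liver mask
#'
#' Convenience wrapper chaining [feature_map()], [classify_voxels()] and
#' [postprocess_mask()].
#'
#' @param volume a [ct_volume()].
#' @param liver_mask the liver ROI [ct_mask()].
#' @param model a trained [train_classifier()].
#' @param window,levels,hu_window feature parameters, see [feature_map()].
#' @param threshold probability cut (default 0.5).
#' @param closing_radius_vox,opening_radius_vox clean-up radii (default 1).
#' @return The post-processed tumor [ct_mask()].
#' @export
segment_tumors <- function(volume, liver_mask, model, window = 11L,
                           levels = 32L, hu_window = c(-100, 300),
                           threshold = 0.5, closing_radius_vox = 1L,
                           opening_radius_vox = 1L) {
  feats <- feature_map(volume, liver_mask, window = window, levels = levels,
                       hu_window = hu_window)
  raw <- classify_voxels(model, feats, liver_mask, threshold = threshold)
  postprocess_mask(raw, closing_radius_vox, opening_radius_vox)
}
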