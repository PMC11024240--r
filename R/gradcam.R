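#' Grad-CAM heatmap for the scalar survival output
#'
#' Gradient-weighted class activation mapping adapted to a survival network:
#' channel weights are the spatially averaged gradients of the scalar
#' log-hazard output with respect to a convolutional layer's activations; the
#' weighted activation sum is passed through `max(., 0)`, normalized to
#' `[0, 1]`, and bilinearly upsampled to the input resolution.
#'
#' The model outputs conception hazard, while the clinical reading highlights
#' risk factors for subfertility; under the default
#' `sign = "risk-of-subfertility"` the output is negated before
#' differentiation, so hot regions are those pushing the conception hazard
#' down. Use `sign = "hazard"` for the raw direction. The heatmap is
#' invariant to adding a constant to the model output.
#'
#' @param model a trained image `deepsurv_model` (tiny_test backbone).
#' @param image one preprocessed image array (`H x W x 3`).
#' @param target_layer index of a convolutional layer in `model$layers`
#'   (default: the last conv layer of the backbone).
#' @param sign `"risk-of-subfertility"` (default) or `"hazard"`.
#' @return object of class `heatmap`: `values` (matrix in `[0, 1]` at input
#'   resolution), `source_layer`, `sign`.
#' @export
grad_cam <- function(model, image, target_layer = NULL,
                     sign = c("risk-of-subfertility", "hazard")) {
  sign <- match.arg(sign)
  conv_idx <- which(vapply(model$layers, function(l) l$type == "conv", logical(1)))
  if (length(conv_idx) == 0) hs_error("no-conv-layer", "model has no convolutional layer")
  if (is.null(target_layer)) target_layer <- max(conv_idx)
  if (!(target_layer %in% conv_idx))
    hs_error("not-a-conv-layer", paste0("layer ", target_layer, " is not convolutional"))
  x <- array(image, c(dim(image), 1))
  fw <- net_forward(model, x, training = FALSE, keep_outputs = TRUE)
  dout <- matrix(if (sign == "risk-of-subfertility") -1 else 1, 1, 1)
  bw <- net_backward(model, fw$caches, dout, stop_after = target_layer)
  acts <- fw$outputs[[target_layer]]            # H x W x C x 1
  grads <- bw$dx_in[[target_layer + 1]]         # gradient w.r.t. that output
  w <- apply(grads[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (ch in seq_along(w)) cam <- cam + w[ch] * acts[, , ch, 1]
  cam <- pmax(cam, 0)
  mx <- max(cam)
  if (mx == 0) {
    warning("zero gradient everywhere; returning all-zero heatmap")
  } else {
    cam <- cam / mx
  }
  up <- bilinear_resize(cam, dim(image)[1], dim(image)[2])
  up <- pmin(pmax(up, 0), 1)
  structure(list(values = up, source_layer = target_layer, sign = sign),
            class = "heatmap")
}

#' Overlay a Grad-CAM heatmap on an image
#'
#' Alpha-blends a red-hot colormapped heatmap over the (preprocessed or raw)
#' RGB image: `alpha = 0` returns the image, `alpha = 1` the pure colormap.
#' Deterministic.
#'
#' @param heatmap a `heatmap` object (or a matrix in `[0, 1]`).
#' @param image RGB array with matching spatial dimensions, values in
#'   `[0, 1]`.
#' @param alpha blend weight in `[0, 1]`.
#' @return RGB array `H x W x 3`.
#' @export
overlay_heatmap <- function(heatmap, image, alpha = 0.4) {
  v <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!all(dim(v) == dim(image)[1:2]))
    hs_error("dimension-mismatch", "heatmap and image dimensions differ")
  stopifnot(alpha >= 0, alpha <= 1)
  ramp <- grDevices::colorRamp(c("#00008B", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF0000"))
  cols <- ramp(as.vector(v)) / 255
  cmap <- array(cols, c(dim(v), 3))
  (1 - alpha) * image[, , 1:3] + alpha * cmap
}
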