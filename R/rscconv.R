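# Self-calibrated convolution block (RSCconv).
#
# The input feature map is duplicated into three branches:
#   branch 1 -- identity: no treatment, preserves small-object detail;
#   branch 2 -- refinement: a plain 3x3 convolution at the original scale;
#   branch 3 -- calibration: bilinear 2x upscale, 3x3 convolution in the
#               upscaled space, bilinear map back to the output grid.
# The three branches are fused by elementwise multiplication, so positions
# that any branch scores near zero are suppressed in the output.

#' Construct parameters for a self-calibrated convolution block
#'
#' @param refine_kernel `(C, C, 3, 3)` kernel of the original-scale branch.
#' @param calib_kernel `(C, C, 3, 3)` kernel of the upscaled-space branch.
#' @param refine_bias,calib_bias Bias vectors of length `C`; `NULL` means zero.
#' @param stride Convolution stride, 1 or 2. For stride 2 the identity and
#'   calibration branches are bilinearly resized to the strided grid before
#'   fusion.
#' @param padding Non-negative symmetric zero padding (default 1 keeps the
#'   stride-1 output the same size as the input).
#' @param gate_calibration If `TRUE`, squash the calibration branch through a
#'   logistic before fusion so it acts as a soft (0,1) gate rather than an
#'   unbounded factor. Off by default: the plain three-factor product is the
#'   reference behaviour.
#' @return An object of class `rscconv_params`.
#' @export
rscconv_params <- function(refine_kernel, calib_kernel,
                           refine_bias = NULL, calib_bias = NULL,
                           stride = 1L, padding = 1L,
                           gate_calibration = FALSE) {
  for (nm in c("refine_kernel", "calib_kernel")) {
    k <- get(nm)
    d <- dim(k)
    if (is.null(d) || length(d) != 4L || d[3] != 3L || d[4] != 3L) {
      stop(nm, " must be a (C, C, 3, 3) array")
    }
    if (d[1] != d[2]) {
      stop(nm, " must have equal input/output channels (got ", d[1], "x",
           d[2], "): the identity branch is fused elementwise")
    }
  }
  if (!identical(dim(refine_kernel), dim(calib_kernel))) {
    stop("refine_kernel and calib_kernel must have identical shapes")
  }
  ch <- dim(refine_kernel)[1]
  if (is.null(refine_bias)) refine_bias <- numeric(ch)
  if (is.null(calib_bias)) calib_bias <- numeric(ch)
  stride <- as.integer(stride)
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  padding <- as.integer(padding)
  if (padding < 0L) stop("padding must be non-negative")
  structure(list(refine_kernel = refine_kernel, refine_bias = refine_bias,
                 calib_kernel = calib_kernel, calib_bias = calib_bias,
                 stride = stride, padding = padding,
                 gate_calibration = isTRUE(gate_calibration)),
            class = "rscconv_params")
}

#' Self-calibrated convolution forward pass
#'
#' @param x `(batch, C, H, W)` feature map; `C` must match the kernels.
#' @param p [rscconv_params()] object.
#' @param keep_cache Keep intermediates for [rscconv_backward()].
#' @return Output feature map with the spatial size of a standard 3x3
#'   convolution at the same stride/padding; or `list(out, cache)` when
#'   `keep_cache = TRUE`.
#' @export
rscconv_forward <- function(x, p, keep_cache = FALSE) {
  check_featuremap(x)
  d <- dim(x)
  if (d[2] != dim(p$refine_kernel)[2]) {
    stop("channel mismatch: input has ", d[2], " channels, block expects ",
         dim(p$refine_kernel)[2])
  }
  f2 <- conv2d(x, p$refine_kernel, p$refine_bias, stride = p$stride,
               padding = p$padding, keep_cache = keep_cache)
  b2 <- if (keep_cache) f2$out else f2
  oh <- dim(b2)[3]; ow <- dim(b2)[4]

  up <- resize_bilinear(x, 2L * d[3], 2L * d[4])
  f3 <- conv2d(up, p$calib_kernel, p$calib_bias, stride = 1L,
               padding = p$padding, keep_cache = keep_cache)
  c3 <- if (keep_cache) f3$out else f3
  b3 <- resize_bilinear(c3, oh, ow)
  gate <- NULL
  if (p$gate_calibration) {
    gate <- sigmoid(b3)
    b3 <- gate
  }
  b1 <- if (oh == d[3] && ow == d[4]) x else resize_bilinear(x, oh, ow)
  out <- b1 * b2 * b3
  if (!keep_cache) return(out)
  list(out = out,
       cache = list(dim_x = d, b1 = b1, b2 = b2, b3 = b3, gate = gate,
                    c3_dim = dim(c3), conv2 = f2$cache, conv3 = f3$cache,
                    oh = oh, ow = ow))
}

#' Self-calibrated convolution backward pass
#'
#' @param grad Gradient w.r.t. the block output.
#' @param cache Cache from `rscconv_forward(..., keep_cache = TRUE)`.
#' @param p The same [rscconv_params()] used in the forward pass.
#' @return `list(dx, drefine_kernel, drefine_bias, dcalib_kernel, dcalib_bias)`.
#' @export
rscconv_backward <- function(grad, cache, p) {
  d <- cache$dim_x
  g1 <- grad * cache$b2 * cache$b3
  g2 <- grad * cache$b1 * cache$b3
  g3 <- grad * cache$b1 * cache$b2
  if (p$gate_calibration) g3 <- sigmoid_backward(g3, cache$gate)

  bw2 <- conv2d_backward(g2, cache$conv2)
  dx <- bw2$dx

  g_c3 <- resize_bilinear_backward(g3, cache$c3_dim[3], cache$c3_dim[4])
  bw3 <- conv2d_backward(g_c3, cache$conv3)
  dx <- dx + resize_bilinear_backward(bw3$dx, d[3], d[4])

  dx <- dx + if (cache$oh == d[3] && cache$ow == d[4]) g1 else
    resize_bilinear_backward(g1, d[3], d[4])

  list(dx = dx,
       drefine_kernel = bw2$dw, drefine_bias = bw2$db,
       dcalib_kernel = bw3$dw, dcalib_bias = bw3$db)
}

#' Build a self-calibrated convolution from pretrained 3x3 weights
#'
#' Both the refinement and the calibration kernel start as independent value
#' copies of the donor weights, so the pretrained filters act in both scale
#' spaces at step 0 and then diverge during fine-tuning.
#'
#' @param w Donor `(C, C, 3, 3)` kernel.
#' @param b Donor bias (length `C`) or `NULL` for zero bias.
#' @param stride,padding Copied from the donor layer.
#' @param gate_calibration Passed through to [rscconv_params()].
#' @return [rscconv_params()] object.
#' @export
inherit_pretrained <- function(w, b = NULL, stride = 1L, padding = 1L,
                               gate_calibration = FALSE) {
  d <- dim(w)
  if (is.null(d) || length(d) != 4L || d[3] != 3L || d[4] != 3L) {
    stop("donor kernel must be spatially 3x3")
  }
  if (d[1] != d[2]) {
    stop("donor kernel must have equal input/output channel counts")
  }
  rscconv_params(refine_kernel = w + 0, calib_kernel = w + 0,
                 refine_bias = if (is.null(b)) NULL else b + 0,
                 calib_bias = if (is.null(b)) NULL else b + 0,
                 stride = stride, padding = padding,
                 gate_calibration = gate_calibration)
}

#' Number of trainable parameters in a self-calibrated convolution
#'
#' @param p [rscconv_params()] object.
#' @return Integer count (two 3x3 kernels plus two biases).
#' @export
rscconv_n_params <- function(p) {
  length(p$refine_kernel) + length(p$refine_bias) +
    length(p$calib_kernel) + length(p$calib_bias)
}
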