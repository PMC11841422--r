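make_params <- function(ch, stride = 1L, padding = 1L, gate = FALSE) {
  rscconv_params(refine_kernel = rand_array(c(ch, ch, 3, 3)),
                 calib_kernel = rand_array(c(ch, ch, 3, 3)),
                 refine_bias = rnorm(ch), calib_bias = rnorm(ch),
                 stride = stride, padding = padding, gate_calibration = gate)
}

delta_kernel <- function(ch) {
  w <- array(0, dim = c(ch, ch, 3, 3))
  for (c in seq_len(ch)) w[c, c, 2, 2] <- 1
  w
}

test_that("zero input annihilates the output for any parameters", {
  set.seed(21)
  for (gate in c(FALSE, TRUE)) for (stride in c(1L, 2L)) {
    p <- make_params(4, stride = stride, gate = gate)
    out <- rscconv_forward(array(0, dim = c(1, 4, 8, 8)), p)
    expect_true(all(out == 0))
  }
})

test_that("delta kernels on a constant map act as the identity", {
  p <- rscconv_params(delta_kernel(1), delta_kernel(1))
  x <- array(1, dim = c(1, 1, 4, 4))
  expect_equal(rscconv_forward(x, p), x)
})

test_that("forward pass matches the loop-based branch oracle", {
  set.seed(22)
  for (trial in 1:20) {
    stride <- sample(c(1L, 2L), 1)
    gate <- sample(c(TRUE, FALSE), 1)
    ch <- sample(1:3, 1)
    p <- make_params(ch, stride = stride, gate = gate)
    x <- rand_array(c(1, ch, sample(4:8, 1), sample(4:8, 1)))
    got <- rscconv_forward(x, p)
    want <- oracle_rscconv(x, p)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("output spatial size equals a plain 3x3 convolution at same stride/padding", {
  set.seed(23)
  for (stride in c(1L, 2L)) for (hw in list(c(8, 8), c(7, 9))) {
    p <- make_params(2, stride = stride)
    x <- rand_array(c(1, 2, hw[1], hw[2]))
    ref <- conv2d(x, rand_array(c(2, 2, 3, 3)), stride = stride, padding = 1)
    expect_equal(dim(rscconv_forward(x, p)), dim(ref))
  }
})

test_that("channel mismatch and non-finite input are rejected", {
  p <- make_params(3)
  expect_error(rscconv_forward(rand_array(c(1, 2, 4, 4)), p), "channel mismatch")
  bad <- array(Inf, dim = c(1, 3, 4, 4))
  expect_error(rscconv_forward(bad, p), "non-finite")
  expect_error(rscconv_params(rand_array(c(2, 3, 3, 3)),
                              rand_array(c(2, 3, 3, 3))), "equal input/output")
  expect_error(rscconv_params(rand_array(c(2, 2, 5, 5)),
                              rand_array(c(2, 2, 5, 5))), "3, 3")
})

test_that("analytic gradients match finite differences (kernels and input)", {
  set.seed(24)
  x <- rand_array(c(1, 1, 4, 4))
  for (gate in c(FALSE, TRUE)) {
    p <- make_params(1, gate = gate)
    fw <- rscconv_forward(x, p, keep_cache = TRUE)
    gr <- rscconv_backward(2 * fw$out, fw$cache, p)
    loss_x <- function(z) sum(rscconv_forward(z, p)^2)
    expect_equal(gr$dx, fd_grad(loss_x, x), tolerance = 1e-4)
    loss_w <- function(z) {
      p2 <- p; p2$refine_kernel <- z
      sum(rscconv_forward(x, p2)^2)
    }
    expect_equal(gr$drefine_kernel, fd_grad(loss_w, p$refine_kernel),
                 tolerance = 1e-4)
    loss_c <- function(z) {
      p2 <- p; p2$calib_kernel <- z
      sum(rscconv_forward(x, p2)^2)
    }
    expect_equal(gr$dcalib_kernel, fd_grad(loss_c, p$calib_kernel),
                 tolerance = 1e-4)
    expect_gt(sum(abs(gr$dx)), 0)
    expect_gt(sum(abs(gr$drefine_kernel)), 0)
    expect_gt(sum(abs(gr$dcalib_kernel)), 0)
  }
})

test_that("inherit_pretrained copies weights by value and propagates geometry", {
  set.seed(25)
  w <- rand_array(c(3, 3, 3, 3)); b <- rnorm(3)
  p <- inherit_pretrained(w, b, stride = 2, padding = 1)
  expect_equal(p$refine_kernel, w)
  expect_equal(p$calib_kernel, w)
  expect_equal(p$refine_bias, b)
  expect_equal(p$stride, 2L)
  expect_equal(p$padding, 1L)
  p$calib_kernel[1, 1, 1, 1] <- 99
  expect_equal(p$refine_kernel, w)   # copies are independent

  z <- array(0, dim = c(2, 2, 3, 3))
  pz <- inherit_pretrained(z)
  expect_true(all(pz$refine_kernel == 0) && all(pz$calib_kernel == 0))
  expect_true(all(pz$refine_bias == 0))

  expect_error(inherit_pretrained(rand_array(c(2, 3, 3, 3))), "equal")
  expect_error(inherit_pretrained(rand_array(c(2, 2, 5, 5))), "3x3")
})

test_that("patch_backbone replaces every residual-block conv exactly once", {
  set.seed(26)
  bb <- build_backbone(widths = c(4, 6, 8, 10), n_blocks = 2)
  n0 <- backbone_n_params(bb)
  res <- patch_backbone(bb, use_rscconv = TRUE)
  expect_equal(nrow(res$report), 4 * 2)
  # parameter count delta: one extra 3x3 kernel + bias per replaced layer
  expect_equal(backbone_n_params(res$backbone),
               n0 + sum(res$report$added_params))
  expect_equal(sum(res$report$added_params),
               sum(res$report$channels^2 * 9 + res$report$channels))
  # weights inherited by value
  expect_equal(res$backbone$stages[[1]]$blocks[[1]]$conv$refine_kernel,
               bb$stages[[1]]$blocks[[1]]$conv$w)

  # flag off: unchanged spec, empty report
  off <- patch_backbone(bb, use_rscconv = FALSE)
  expect_identical(off$backbone, bb)
  expect_equal(nrow(off$report), 0)

  # idempotence: second application changes nothing
  twice <- patch_backbone(res$backbone, use_rscconv = TRUE)
  expect_identical(twice$backbone, res$backbone)
  expect_equal(nrow(twice$report), 0)
})

test_that("patched and plain backbones produce identically-shaped pyramids", {
  set.seed(27)
  bb <- build_backbone(widths = c(4, 6, 8, 10), n_blocks = 1)
  x <- rand_array(c(1, 3, 64, 64))
  plain <- backbone_forward(bb, x)
  patched <- backbone_forward(patch_backbone(bb)$backbone, x)
  for (i in 1:3) {
    expect_equal(dim(plain$pyramid[[i]]), dim(patched$pyramid[[i]]))
  }
  expect_equal(dim(plain$pyramid[[1]])[3:4], c(8, 8))    # stride 8
  expect_equal(dim(plain$pyramid[[3]])[3:4], c(2, 2))    # stride 32
})

test_that("backbone backward gradients match finite differences", {
  set.seed(28)
  bb <- build_backbone(widths = c(3, 4, 4, 4), n_blocks = 1)
  bb <- patch_backbone(bb)$backbone
  x <- rand_array(c(1, 3, 32, 32))
  loss <- function(b2) {
    b <- bb; b$stages[[2]]$blocks[[1]]$conv$refine_kernel <- b2
    fw <- backbone_forward(b, x)
    sum(fw$pyramid[[2]]^2)
  }
  fw <- backbone_forward(bb, x, keep_cache = TRUE)
  gs <- list(NULL, NULL, 2 * fw$stage_outputs[[3]], NULL)
  bw <- backbone_backward(bb, fw$cache, gs)
  got <- bw$grads$stages[[2]]$blocks[[1]]$conv$refine_kernel
  want <- fd_grad(loss, bb$stages[[2]]$blocks[[1]]$conv$refine_kernel, eps = 1e-4)
  expect_gt(sum(abs(want)), 0)
  expect_equal(got, want, tolerance = 1e-3)
})
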