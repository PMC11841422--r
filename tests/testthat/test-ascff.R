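make_pyramid <- function(channels = c(6, 8, 10), hw = 16, batch = 1) {
  list(rand_array(c(batch, channels[1], hw, hw)),
       rand_array(c(batch, channels[2], hw / 2, hw / 2)),
       rand_array(c(batch, channels[3], hw / 4, hw / 4)))
}

test_that("attention weights lie strictly inside (0, 1) and zeros map to zeros", {
  set.seed(31)
  ap <- attention_params(8, reduction = 4, spatial_kernel = 7)
  x <- rand_array(c(2, 8, 6, 6))
  res <- spatial_channel_attention(x, ap)
  expect_true(all(res$weights$channel_weights > 0 &
                    res$weights$channel_weights < 1))
  expect_true(all(res$weights$spatial_map > 0 & res$weights$spatial_map < 1))
  z <- spatial_channel_attention(array(0, dim = c(1, 8, 6, 6)), ap)
  expect_true(all(z$out == 0))
  expect_error(spatial_channel_attention(array(NaN, c(1, 8, 2, 2)), ap),
               "non-finite")
})

test_that("attention matches the scalar-loop oracle", {
  set.seed(32)
  for (trial in 1:10) {
    ch <- sample(c(4, 8), 1)
    ap <- attention_params(ch, reduction = sample(c(2, 4, 16), 1),
                           spatial_kernel = sample(c(3, 7), 1))
    x <- rand_array(c(1, ch, 6, 6))
    got <- spatial_channel_attention(x, ap)
    want <- oracle_sc_attention(x, ap)
    expect_equal(got$weights$channel_weights, want$channel_weights,
                 tolerance = 1e-5)
    expect_equal(got$weights$spatial_map, want$spatial_map, tolerance = 1e-5)
    expect_equal(got$out, want$out, tolerance = 1e-5)
  }
})

test_that("attention backward matches finite differences", {
  set.seed(33)
  ap <- attention_params(4, reduction = 2, spatial_kernel = 3)
  x <- rand_array(c(1, 4, 4, 4))
  fw <- spatial_channel_attention(x, ap, keep_cache = TRUE)
  bw <- spatial_channel_attention_backward(2 * fw$out, fw$cache, ap)
  loss_x <- function(z) sum(spatial_channel_attention(z, ap)$out^2)
  expect_equal(bw$dx, fd_grad(loss_x, x), tolerance = 1e-4)
  loss_p <- function(field) function(z) {
    a2 <- ap; a2[[field]] <- z
    sum(spatial_channel_attention(x, a2)$out^2)
  }
  for (field in c("fc1_w", "fc2_w", "spatial_w")) {
    want <- fd_grad(loss_p(field), ap[[field]])
    expect_equal(bw$grads[[field]], want, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("align_levels maps all levels to the target shape and preserves constants", {
  set.seed(34)
  pyr <- make_pyramid()
  neck <- build_ascff_neck(c(6, 8, 10), out_channels = 8, reduction = 4)
  for (t in 1:3) {
    al <- align_levels(pyr, t, neck)
    td <- dim(pyr[[t]])
    for (l in 1:3) expect_equal(dim(al[[l]]), c(1, 8, td[3], td[4]))
  }
  # constant input stays constant per channel after 1x1 conv + resize
  pyr[[3]] <- array(2, dim = dim(pyr[[3]]))
  al <- align_levels(pyr, 1, neck)
  m <- al[[3]]
  for (ci in seq_len(dim(m)[2])) {
    expect_equal(max(m[1, ci, , ]) - min(m[1, ci, , ]), 0, tolerance = 1e-12)
  }
  expect_error(align_levels(pyr, 4, neck), "target_index")
})

test_that("ascff_fuse composes the oracle-verified stages end to end", {
  set.seed(35)
  neck <- build_ascff_neck(c(6, 8, 10), out_channels = 4, reduction = 4,
                           spatial_kernel = 3)
  aligned <- lapply(1:3, function(i) rand_array(c(1, 4, 8, 8)))
  got <- ascff_fuse(aligned, neck)
  # independent composition: concat -> oracle attention -> plain convs
  cc <- array(0, dim = c(1, 12, 8, 8))
  cc[, 1:4, , ] <- aligned[[1]]; cc[, 5:8, , ] <- aligned[[2]]
  cc[, 9:12, , ] <- aligned[[3]]
  att <- oracle_sc_attention(cc, neck$attention)
  red <- oracle_conv2d(att$out, neck$reduce$w, neck$reduce$b)
  want <- oracle_conv2d(red, neck$extract$w, neck$extract$b, padding = 1)
  expect_equal(got, want, tolerance = 1e-5)
  expect_equal(dim(got), c(1, 4, 8, 8))
  expect_error(ascff_fuse(list(aligned[[1]], aligned[[2]],
                               rand_array(c(1, 4, 6, 8))), neck),
               "identical shape")
})

test_that("all-zero fused inputs give the bias response of the two convolutions", {
  set.seed(36)
  neck <- build_ascff_neck(c(4, 4, 4), out_channels = 4, reduction = 2,
                           spatial_kernel = 3)
  aligned <- lapply(1:3, function(i) array(0, dim = c(1, 4, 6, 6)))
  out <- ascff_fuse(aligned, neck)
  # zeros stay zeros through attention; response = conv3x3(bias map of 1x1)
  biasmap <- array(0, dim = c(1, 4, 6, 6))
  for (ci in 1:4) biasmap[, ci, , ] <- neck$reduce$b[ci]
  want <- conv2d(biasmap, neck$extract$w, neck$extract$b, padding = 1)
  expect_equal(out, want, tolerance = 1e-12)
})

test_that("neck shape contract: four outputs at strides 8/16/32/64, drop-in vs baseline", {
  set.seed(37)
  pyr <- make_pyramid(c(6, 8, 10), hw = 16)
  an <- build_ascff_neck(c(6, 8, 10), out_channels = 8, reduction = 4)
  mn <- build_mapper_neck(c(6, 8, 10), out_channels = 8)
  oa <- ascff_neck(pyr, an)$outputs
  om <- mapper_neck(pyr, mn)$outputs
  want_hw <- list(c(16, 16), c(8, 8), c(4, 4), c(2, 2))
  for (i in 1:4) {
    expect_equal(dim(oa[[i]]), c(1, 8, want_hw[[i]][1], want_hw[[i]][2]))
    expect_equal(dim(oa[[i]]), dim(om[[i]]))
  }
})

test_that("fused level-1 output responds to a perturbation of level-3 only", {
  set.seed(38)
  pyr <- make_pyramid(c(6, 8, 10), hw = 16)
  neck <- build_ascff_neck(c(6, 8, 10), out_channels = 8, reduction = 4)
  base <- ascff_neck(pyr, neck)$outputs[[1]]
  pyr2 <- pyr
  pyr2[[3]] <- pyr2[[3]] + rand_array(dim(pyr2[[3]]))
  pert <- ascff_neck(pyr2, neck)$outputs[[1]]
  expect_gt(max(abs(pert - base)), 1e-6)
  # the baseline mapper, by contrast, has no cross-scale flow into level 1
  mn <- build_mapper_neck(c(6, 8, 10), out_channels = 8)
  b0 <- mapper_neck(pyr, mn)$outputs[[1]]
  b1 <- mapper_neck(pyr2, mn)$outputs[[1]]
  expect_equal(b0, b1)
})

test_that("identical seeds give bitwise-identical neck initialisation and outputs", {
  make <- function() {
    set.seed(99)
    build_ascff_neck(c(4, 6, 8), out_channels = 4, reduction = 4)
  }
  n1 <- make(); n2 <- make()
  expect_identical(n1, n2)
  set.seed(5); pyr <- make_pyramid(c(4, 6, 8), hw = 8)
  expect_identical(ascff_neck(pyr, n1)$outputs, ascff_neck(pyr, n2)$outputs)
})

test_that("neck backward gradients match finite differences", {
  set.seed(40)
  pyr <- make_pyramid(c(3, 4, 5), hw = 8)
  neck <- build_ascff_neck(c(3, 4, 5), out_channels = 3, reduction = 2,
                           spatial_kernel = 3)
  fw <- ascff_neck(pyr, neck, keep_cache = TRUE)
  grads <- list(2 * fw$outputs[[1]], NULL, NULL, 2 * fw$outputs[[4]])
  bw <- ascff_neck_backward(grads, fw$cache, neck)
  loss_pyr <- function(z) {
    p2 <- pyr; p2[[2]] <- z
    o <- ascff_neck(p2, neck)$outputs
    sum(o[[1]]^2) + sum(o[[4]]^2)
  }
  expect_equal(bw$d_pyramid[[2]], fd_grad(loss_pyr, pyr[[2]], eps = 1e-4),
               tolerance = 1e-3)
  loss_w <- function(z) {
    n2 <- neck; n2$reduce$w <- z
    o <- ascff_neck(pyr, n2)$outputs
    sum(o[[1]]^2) + sum(o[[4]]^2)
  }
  expect_equal(bw$grads$reduce$w, fd_grad(loss_w, neck$reduce$w, eps = 1e-4),
               tolerance = 1e-3)
  loss_extra <- function(z) {
    n2 <- neck; n2$extra$w <- z
    o <- ascff_neck(pyr, n2)$outputs
    sum(o[[1]]^2) + sum(o[[4]]^2)
  }
  expect_equal(bw$grads$extra$w, fd_grad(loss_extra, neck$extra$w, eps = 1e-4),
               tolerance = 1e-3)
})
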