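# Layer and block constructors. Each constructor allocates parameters in the
# model's store, registers the layer's geometry for the profiler, and returns
# a closure `function(tp, xs) -> node id`, where xs is a vector of input node
# ids. Convolutions accept multiple inputs directly (sum of per-source
# convolutions), which is mathematically identical to convolving the channel
# concatenation but never materializes it.

new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$layers <- list()
  reg
}

reg_add <- function(reg, type, size, k = NA, cin = NA, cout = NA, dil = NA) {
  reg$layers[[length(reg$layers) + 1L]] <-
    list(type = type, size = size, k = k, cin = cin, cout = cout, dil = dil)
  invisible(reg)
}

# conv (Kaiming-uniform init over the total fan-in) + batchnorm + ReLU
conv_bn_relu <- function(ps, reg, size, cins, cout, k = 3L, dil = 1L,
                         relu = TRUE, bn = TRUE) {
  bound <- sqrt(6 / (k * k * sum(cins)))
  wids <- vapply(cins, function(ci) {
    ps_add(ps, array(runif(k * k * ci * cout, -bound, bound), c(k, k, ci, cout)))
  }, 0L)
  bid <- ps_add(ps, numeric(cout))
  reg_add(reg, "conv", size, k, sum(cins), cout, dil)
  if (bn) {
    gid <- ps_add(ps, rep(1, cout))
    bbid <- ps_add(ps, numeric(cout))
    rmid <- ps_add(ps, numeric(cout), trainable = FALSE)
    rvid <- ps_add(ps, rep(1, cout), trainable = FALSE)
    reg_add(reg, "bn", size, cout = cout)
  }
  function(tp, xs) {
    h <- tp_conv_multi(tp, xs, wids, bid, dil)
    if (bn) tp_bn(tp, h, gid, bbid, rmid, rvid, relu = relu)
    else if (relu) tp_relu(tp, h)
    else h
  }
}

# plain double 3x3 conv block (the U-Net baseline's feature extractor)
double_conv <- function(ps, reg, size, cins, cout) {
  c1 <- conv_bn_relu(ps, reg, size, cins, cout)
  c2 <- conv_bn_relu(ps, reg, size, cout, cout)
  function(tp, xs) c2(tp, c1(tp, xs))
}

# Nested "tiny U-Net" feature extractor (UIU block). The number of internal
# down/up levels is log2(size / 8) with a floor of 1, so the deepest internal
# map is 8 x 8 for every backbone stage of 16 x 16 or larger. An entry conv
# lifts the input to `cout` channels; the internal encoder/decoder works at
# `mid` channels with concatenating skips, and the block output is the
# residual sum of the entry features and the decoded features.
uiu_block <- function(ps, reg, size, cins, cout, mid) {
  stop_if(bitwAnd(size, size - 1L) != 0L, "UIU block needs a power-of-two size")
  levels <- max(1L, as.integer(log2(size / 8)))
  entry <- conv_bn_relu(ps, reg, size, cins, cout)
  enc <- vector("list", levels)
  enc[[1]] <- conv_bn_relu(ps, reg, size, cout, mid)
  s <- size
  if (levels > 1) for (l in 2:levels) {
    s <- s / 2
    enc[[l]] <- conv_bn_relu(ps, reg, s, mid, mid)
  }
  bottom <- conv_bn_relu(ps, reg, s / 2, mid, mid)
  dec <- vector("list", levels)
  s <- size / 2^(levels - 1)
  if (levels > 1) for (l in levels:2) {
    dec[[l]] <- conv_bn_relu(ps, reg, s, c(mid, mid), mid)
    s <- s * 2
  }
  dec[[1]] <- conv_bn_relu(ps, reg, size, c(mid, mid), cout)
  structure(function(tp, xs) {
    hin <- entry(tp, xs)
    skips <- vector("integer", levels)
    h <- hin
    for (l in seq_len(levels)) {
      skips[l] <- enc[[l]](tp, h)
      h <- tp_maxpool(tp, skips[l])
    }
    h <- bottom(tp, h)
    for (l in seq(levels, 1L)) {
      h <- tp_upsample(tp, h)
      h <- dec[[l]](tp, c(h, skips[l]))
    }
    tp_add(tp, h, hin)
  }, levels = levels)
}

# Dilated dense decoder block: two 3x3 conv layers per dilation rate (1, 2, 3
# by default, i.e. effective receptive fields 3x3, 5x5 and 7x7), each layer
# receiving the block inputs plus all previous layer outputs (dense
# connectivity), BN + ReLU after every convolution, and a 1x1 fusion conv to
# the output width.
dense_block <- function(ps, reg, size, cins, cout, growth,
                        dilations = c(1L, 2L, 3L)) {
  stop_if(length(dilations) == 0, "dense block needs at least one dilation rate")
  layers <- list()
  srcs <- cins
  for (d in dilations) for (rep in 1:2) {
    layers[[length(layers) + 1L]] <- conv_bn_relu(ps, reg, size, srcs, growth, dil = d)
    srcs <- c(srcs, growth)
  }
  fuse <- conv_bn_relu(ps, reg, size, srcs, cout, k = 1L)
  function(tp, xs) {
    feats <- xs
    for (ly in layers) feats <- c(feats, ly(tp, feats))
    fuse(tp, feats)
  }
}

# Residual bridge block: two 3x3 convs with an identity shortcut (1x1
# projection when the widths differ).
residual_block <- function(ps, reg, size, cins, cout) {
  c1 <- conv_bn_relu(ps, reg, size, cins, cout)
  c2 <- conv_bn_relu(ps, reg, size, cout, cout, relu = FALSE)
  identity_ok <- length(cins) == 1 && cins == cout
  proj <- if (!identity_ok)
    conv_bn_relu(ps, reg, size, cins, cout, k = 1L, relu = FALSE)
  function(tp, xs) {
    h <- c2(tp, c1(tp, xs))
    s <- if (is.null(proj)) xs[[1]] else proj(tp, xs)
    tp_relu(tp, tp_add(tp, h, s))
  }
}
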