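#' Network configuration
#'
#' Architecture hyperparameters for the multi-scale dense U-Net and its
#' ablation stages. The default widths were calibrated so the full stage-3
#' network profiles at about 16 million trainable parameters and 29.5
#' GFLOPs (two FLOPs per multiply-accumulate) for one 128 x 128 x 1 forward
#' pass; see [msdnet_config_small()] for narrower desk-scale variants.
#'
#' @param widths Encoder stage widths (4 stages, full resolution first).
#' @param bridge Bridge width at the 8 x 8 bottleneck.
#' @param mid_frac,mid_floor Internal width of each UIU block as a fraction
#'   of its stage width, floored.
#' @param growth_frac,growth_floor Dense-block growth rate as a fraction of
#'   the block's output width, floored.
#' @param head_channels Channels per multi-scale head branch; the
#'   concatenated head carries `5 * head_channels` channels.
#' @param dilations Dilation rates of the dense decoder blocks.
#' @param stage Ablation stage: `"baseline_unet"` (plain U-Net),
#'   `"stage1_uiu"` (+ UIU encoder), `"stage2_uiu_dense"` (+ dense decoder),
#'   `"stage3_full"` (+ multi-scale head).
#' @param input_size,input_channels Input geometry.
#' @param seed Seed for weight initialization.
#' @return A `msdnet_config` list.
#' @export
msdnet_config <- function(widths = c(40, 80, 160, 320), bridge = 160,
                          mid_frac = 0.5, mid_floor = 16,
                          growth_frac = 0.5, growth_floor = 8,
                          head_channels = 32, dilations = c(1L, 2L, 3L),
                          stage = c("stage3_full", "stage2_uiu_dense",
                                    "stage1_uiu", "baseline_unet"),
                          input_size = 128L, input_channels = 1L, seed = 1L) {
  stage <- match.arg(stage)
  stop_if(length(widths) != 4, "four encoder stage widths are required")
  structure(list(widths = as.integer(widths), bridge = as.integer(bridge),
                 mid_frac = mid_frac, mid_floor = as.integer(mid_floor),
                 growth_frac = growth_frac, growth_floor = as.integer(growth_floor),
                 head_channels = as.integer(head_channels),
                 dilations = as.integer(dilations), stage = stage,
                 input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 seed = as.integer(seed)),
            class = "msdnet_config")
}

#' Reduced-width configuration for CPU-scale experiments
#'
#' Same architecture as [msdnet_config()] with every width divided by
#' `factor` (floors keep the tiny blocks functional).
#'
#' @param factor Width reduction factor.
#' @param ... Overrides passed to [msdnet_config()].
#' @export
msdnet_config_small <- function(factor = 10, ...) {
  base <- msdnet_config()
  msdnet_config(widths = pmax(4L, as.integer(base$widths / factor)),
                bridge = max(8L, as.integer(base$bridge / factor)),
                mid_floor = 4L, growth_floor = 4L,
                head_channels = max(4L, as.integer(base$head_channels / factor)),
                ...)
}

mid_width <- function(cfg, w) max(cfg$mid_floor, as.integer(round(w * cfg$mid_frac)))
growth_width <- function(cfg, w) max(cfg$growth_floor, as.integer(round(w * cfg$growth_frac)))

#' Build the multi-scale dense U-Net (or an ablation stage)
#'
#' The backbone is a 4-level U-Net over 128 x 128 inputs. Depending on the
#' stage, the encoder uses plain double-conv blocks or nested-U (UIU)
#' blocks, the decoder uses double-conv or dilated dense blocks, and the
#' output head is a single 1 x 1 convolution or the full-scale multi-scale
#' head: every decoder stage is reduced to `head_channels` channels by a
#' 3 x 3 convolution, bilinearly upsampled to full resolution, concatenated
#' together with a projection of the full-resolution encoder features into a
#' `5 * head_channels`-channel map, and fused by a 1 x 1 convolution with a
#' sigmoid, so outputs lie in (0, 1).
#'
#' @param cfg A `msdnet_config`.
#' @return An object of class `msdnet` with the parameter store, the layer
#'   registry and a forward closure.
#' @export
build_msdnet <- function(cfg = msdnet_config()) {
  stop_if(!inherits(cfg, "msdnet_config"), "cfg must be a msdnet_config")
  ps <- new_param_store()
  reg <- new_registry()
  S <- cfg$input_size
  w <- cfg$widths
  uiu <- cfg$stage != "baseline_unet"
  dense <- cfg$stage %in% c("stage2_uiu_dense", "stage3_full")
  head <- cfg$stage == "stage3_full"

  with_seed(cfg$seed, {
    sizes <- S / c(1, 2, 4, 8)
    cins <- c(cfg$input_channels, w[-4])
    enc <- lapply(1:4, function(i) {
      if (uiu) uiu_block(ps, reg, sizes[i], cins[i], w[i], mid_width(cfg, w[i]))
      else double_conv(ps, reg, sizes[i], cins[i], w[i])
    })
    bridge <- residual_block(ps, reg, S / 16, w[4], cfg$bridge)
    dec <- lapply(4:1, function(i) {
      cin <- c(if (i == 4) cfg$bridge else w[i + 1], w[i]) # upsampled + skip
      if (dense) dense_block(ps, reg, sizes[i], cin, w[i], growth_width(cfg, w[i]),
                             cfg$dilations)
      else double_conv(ps, reg, sizes[i], cin, w[i])
    })
    dec <- rev(dec) # dec[[i]] now decodes at stage i's resolution
    if (head) {
      hc <- cfg$head_channels
      branches <- lapply(1:4, function(i) conv_bn_relu(ps, reg, sizes[i], w[i], hc))
      enc_branch <- conv_bn_relu(ps, reg, S, w[1], hc)
      out_conv <- conv_bn_relu(ps, reg, S, rep(hc, 5), 1L, k = 1L,
                               relu = FALSE, bn = FALSE)
    } else {
      out_conv <- conv_bn_relu(ps, reg, S, w[1], 1L, k = 1L, relu = FALSE, bn = FALSE)
    }
  })

  fwd <- function(tp, x, collect = NULL) {
    skips <- integer(4)
    h <- x
    for (i in 1:4) {
      skips[i] <- enc[[i]](tp, h)
      h <- tp_maxpool(tp, skips[i])
    }
    h <- bridge(tp, h)
    decs <- integer(4)
    for (i in 4:1) {
      h <- tp_upsample(tp, h)
      h <- dec[[i]](tp, c(h, skips[i]))
      decs[i] <- h
    }
    if (head) {
      up_to_full <- function(id, i) {
        b <- branches[[i]](tp, id)
        for (r in seq_len(i - 1)) b <- tp_upsample(tp, b)
        b
      }
      parts <- c(vapply(1:4, function(i) up_to_full(decs[i], i), 0L),
                 enc_branch(tp, skips[1]))
      if (!is.null(collect)) {
        # materialize the concatenated multi-scale map for inspection; the
        # fused 1x1 convolution below consumes the five branches directly
        collect$head_concat <- concat_fwd(lapply(parts, tp_value, tp = tp))
      }
      y <- tp_sigmoid(tp, out_conv(tp, parts))
    } else {
      y <- tp_sigmoid(tp, out_conv(tp, h))
    }
    y
  }

  structure(list(ps = ps, reg = reg, config = cfg, fwd = fwd,
                 stage = cfg$stage),
            class = "msdnet")
}

#' Build a specific ablation stage
#'
#' @param cfg A `msdnet_config` (its `stage` field is overridden).
#' @param stage One of `baseline_unet`, `stage1_uiu`, `stage2_uiu_dense`,
#'   `stage3_full`.
#' @export
build_stage <- function(cfg = msdnet_config(), stage) {
  cfg$stage <- match.arg(stage, c("baseline_unet", "stage1_uiu",
                                  "stage2_uiu_dense", "stage3_full"))
  build_msdnet(cfg)
}

#' Build one UIU block as a standalone model (mainly for inspection/tests)
#'
#' @param level_input_size Stage resolution (128, 64, 32, 16 or 8).
#' @param in_ch,out_ch Input/output channels.
#' @param mid Internal width (default: half of `out_ch`, floor 16).
#' @param seed Seed for initialization.
#' @return List with the forward closure, the parameter store, the registry
#'   and `levels` (number of internal down/up levels).
#' @export
build_uiu_block <- function(level_input_size, in_ch, out_ch,
                            mid = max(16L, out_ch %/% 2L), seed = 1L) {
  stop_if(!level_input_size %in% c(128L, 64L, 32L, 16L, 8L),
          "level_input_size must be one of 128, 64, 32, 16, 8")
  ps <- new_param_store()
  reg <- new_registry()
  blk <- with_seed(seed, uiu_block(ps, reg, level_input_size, in_ch, out_ch, mid))
  list(fwd = blk, ps = ps, reg = reg, levels = attr(blk, "levels"))
}

#' Build one dilated dense block as a standalone model
#'
#' @param in_ch,out_ch Input/output channels.
#' @param dilations Dilation rates (3x3 kernels; rates 2 and 3 give 5x5 and
#'   7x7 effective receptive fields).
#' @param size Spatial size the block operates at.
#' @param growth Growth rate (default quarter of `out_ch`, floor 8).
#' @param seed Seed for initialization.
#' @export
build_dense_block <- function(in_ch, out_ch, dilations = c(1L, 2L, 3L),
                              size = 128L, growth = max(8L, out_ch %/% 4L),
                              seed = 1L) {
  ps <- new_param_store()
  reg <- new_registry()
  blk <- with_seed(seed, dense_block(ps, reg, size, in_ch, out_ch, growth,
                                     as.integer(dilations)))
  list(fwd = blk, ps = ps, reg = reg)
}

#' @export
print.msdnet <- function(x, ...) {
  pr <- profile_network(x)
  cat(sprintf("<msdnet> stage %s, widths %s | %.2fM params, %.2f GFLOPs\n",
              x$stage, paste(x$config$widths, collapse = "/"),
              pr$n_params / 1e6, pr$flops / 1e9))
  invisible(x)
}

#' Run the network on images
#'
#' @param object A `msdnet`.
#' @param x Input images: matrix, or H x W x N array, with values in \[0,1\].
#' @param batch_size Mini-batch size used during inference.
#' @param ... Unused.
#' @return Array of the same shape with values in (0, 1).
#' @export
predict.msdnet <- function(object, x, batch_size = 8L, ...) {
  single <- is.matrix(x)
  if (single) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  out <- array(0, d)
  for (at in seq(1, d[3], by = batch_size)) {
    sel <- at:min(d[3], at + batch_size - 1L)
    xb <- x[, , sel, drop = FALSE]
    dim(xb) <- c(d[1], d[2], 1L, length(sel))
    tp <- new_tape(object$ps, training = FALSE, grad = FALSE)
    y <- tp_value(tp, object$fwd(tp, tp_input(tp, xb)))
    out[, , sel] <- y
  }
  if (single) out[, , 1] else out
}

#' Profile a network: trainable parameters and forward FLOPs
#'
#' Counts exact trainable parameters (convolution weights/biases and
#' batchnorm scale/shift) and convolution compute for one forward pass at
#' the build resolution. The default FLOP convention counts the multiply and
#' the add of each multiply-accumulate separately (2 FLOPs per MAC, the
#' convention behind many published "GFLOPs" figures); set
#' `flops_per_mac = 1` for the fused-MAC convention. Pooling, upsampling,
#' batchnorm and activations contribute negligibly and are excluded.
#'
#' @param model A `msdnet` (or any object with `ps`/`reg` fields).
#' @param flops_per_mac 2 (default) or 1 (fused multiply-add).
#' @return A `network_profile` list with `n_params` and `flops`.
#' @export
profile_network <- function(model, flops_per_mac = 2) {
  macs <- 0
  for (ly in model$reg$layers) {
    if (ly$type == "conv") {
      macs <- macs + ly$size^2 * ly$k^2 * ly$cin * ly$cout
    }
  }
  structure(list(n_params = ps_n_params(model$ps),
                 flops = macs * flops_per_mac, macs = macs),
            class = "network_profile")
}

#' @export
print.network_profile <- function(x, ...) {
  cat(sprintf("%.2f M parameters, %.2f GFLOPs (%.2f GMACs)\n",
              x$n_params / 1e6, x$flops / 1e9, x$macs / 1e9))
  invisible(x)
}
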