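# Declarative network specs and builders: 3-D U-Net generator, patch
# discriminator, and dual-branch residual fusion classifier. All three are
# parameterized by a width scale so tiny CPU-sized instances exist alongside
# the full-width configuration (generator encoder 64..1024, decoder 1024..1;
# discriminator 32..1024; both kernel 3, stride 2).

.GEN_ENC <- c(64L, 128L, 256L, 512L, 1024L, 1024L)
.GEN_DEC <- c(1024L, 512L, 256L, 128L, 64L, 1L)
.DIS_CH  <- c(32L, 64L, 128L, 256L, 512L, 1024L)

scale_ch <- function(ch, ws) pmax(1L, as.integer(round(ch * ws)))

#' Generator architecture specification
#'
#' Describes a 3-D U-Net: a strided convolutional encoder, a transposed
#' convolutional decoder, and skip connections concatenated along the channel
#' axis. At full width the encoder has channels 64, 128, 256, 512, 1024, 1024
#' and the decoder 1024, 512, 256, 128, 64, 1; `width_scale` shrinks every
#' channel count for desk-scale instances.
#'
#' @param depth number of encode/decode levels; the input edge must be
#'   divisible by `2^depth`.
#' @param width_scale multiplier applied to all channel counts.
#' @param output_activation activation of the last decoder layer; `"sigmoid"`
#'   keeps synthesized intensities in `[0, 1]`.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 2L, width_scale = 1, output_activation = "sigmoid") {
  depth <- as.integer(depth)
  stopifnot(depth >= 1L, depth <= 6L, width_scale > 0)
  enc <- scale_ch(.GEN_ENC[seq_len(depth)], width_scale)
  dec <- scale_ch(.GEN_DEC[seq.int(6L - depth + 1L, 6L)], width_scale)
  dec[depth] <- 1L
  structure(list(encoder_channels = enc, decoder_channels = dec,
                 kernel = 3L, stride = 2L, skip = "concat",
                 output_activation = output_activation,
                 width_scale = width_scale, depth = depth),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Strided convolutions (kernel 3, stride 2) with leaky-rectifier activations
#' followed by a flatten + single-output affine head squashed to (0, 1).
#' Full-width channels are 32, 64, 128, 256, 512, 1024.
#'
#' @param depth number of convolution layers.
#' @param width_scale channel multiplier.
#' @param lrelu_slope negative slope of the leaky rectifier.
#' @return an object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(depth = 2L, width_scale = 1, lrelu_slope = 0.2) {
  depth <- as.integer(depth)
  stopifnot(depth >= 1L, depth <= 6L, width_scale > 0)
  structure(list(channels = scale_ch(.DIS_CH[seq_len(depth)], width_scale),
                 kernel = 3L, stride = 2L, lrelu_slope = lrelu_slope,
                 width_scale = width_scale, depth = depth),
            class = "discriminator_spec")
}

#' Fusion classifier architecture specification
#'
#' A dual-branch residual network: each modality passes through its own stack
#' of `branch_blocks` Resblocks, branch outputs are concatenated along the
#' channel axis, fused by `trunk_blocks` further Resblocks, flattened and fed
#' to an affine two-class head. Each Resblock is 4 convolutions (the first
#' with stride 2) and 2 shortcut connections with batch normalization and
#' rectifier activations; dropout follows each block. The feature extractor
#' `F` is the whole network minus the final affine head.
#'
#' @param branch_blocks Resblocks per single-modality branch.
#' @param trunk_blocks Resblocks after channel concatenation.
#' @param base_channels channels of the first branch block; doubled each block.
#' @param dropout_rate dropout probability after each Resblock.
#' @return an object of class `fusion_spec`.
#' @export
fusion_spec <- function(branch_blocks = 2L, trunk_blocks = 1L,
                        base_channels = 4L, dropout_rate = 0.5) {
  branch_blocks <- as.integer(branch_blocks); trunk_blocks <- as.integer(trunk_blocks)
  stopifnot(branch_blocks >= 1L, trunk_blocks >= 1L, base_channels >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  branch_ch <- as.integer(base_channels * 2L^(seq_len(branch_blocks) - 1L))
  trunk_ch <- as.integer(base_channels * 2L^(branch_blocks + seq_len(trunk_blocks) - 1L))
  structure(list(branch_blocks = branch_blocks, trunk_blocks = trunk_blocks,
                 base_channels = as.integer(base_channels),
                 branch_channels = branch_ch, trunk_channels = trunk_ch,
                 dropout_rate = dropout_rate),
            class = "fusion_spec")
}

# ---- initialization --------------------------------------------------------

init_conv <- function(cin, cout, k = 3L) {
  k3 <- k^3L
  list(W = matrix(stats::rnorm(k3 * cin * cout, sd = sqrt(2 / (k3 * cin))),
                  nrow = k3 * cin, ncol = cout),
       b = numeric(cout))
}

init_convt <- function(cin, cout, k = 3L) {
  k3 <- k^3L
  list(W = matrix(stats::rnorm(k3 * cout * cin, sd = sqrt(2 / (k3 * cin))),
                  nrow = k3 * cout, ncol = cin),
       b = numeric(cout))
}

init_dense <- function(fin, fout) {
  list(W = matrix(stats::rnorm(fin * fout, sd = sqrt(1 / fin)), fin, fout),
       b = numeric(fout))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), rmean = numeric(c), rvar = rep(1, c))
}

init_resblock <- function(cin, cout) {
  list(conv1 = init_conv(cin, cout), bn1 = init_bn(cout),
       conv2 = init_conv(cout, cout), bn2 = init_bn(cout),
       proj = init_conv(cin, cout, k = 1L),
       conv3 = init_conv(cout, cout), bn3 = init_bn(cout),
       conv4 = init_conv(cout, cout), bn4 = init_bn(cout))
}

#' Initialize generator parameters
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for the weight draw.
#' @return nested list of weight matrices/biases, class `generator_params`.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(seed, {
    L <- spec$depth
    enc_in <- c(1L, spec$encoder_channels[-L])
    enc <- lapply(seq_len(L), function(i) init_conv(enc_in[i], spec$encoder_channels[i]))
    dec_in <- integer(L)
    dec_in[1L] <- spec$encoder_channels[L]
    if (L > 1L) for (j in 2:L) {
      dec_in[j] <- spec$decoder_channels[j - 1L] + spec$encoder_channels[L - j + 1L]
    }
    dec <- lapply(seq_len(L), function(j) init_convt(dec_in[j], spec$decoder_channels[j]))
    structure(list(enc = enc, dec = dec, spec = spec), class = "generator_params")
  })
}

#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  with_seed(seed, {
    cin <- c(1L, spec$channels[-spec$depth])
    convs <- lapply(seq_len(spec$depth), function(i) init_conv(cin[i], spec$channels[i]))
    structure(list(convs = convs, head = NULL, spec = spec),
              class = "discriminator_params")
  })
}

#' @export
build_fusion_classifier <- function(spec, input_edge, seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"))
  halvings <- spec$branch_blocks + spec$trunk_blocks
  if (input_edge %% 2L^halvings != 0L) {
    stop("input edge must be divisible by 2^(branch_blocks + trunk_blocks)")
  }
  with_seed(seed, {
    branch_in <- c(1L, spec$branch_channels[-spec$branch_blocks])
    make_branch <- function() {
      lapply(seq_len(spec$branch_blocks), function(i) {
        init_resblock(branch_in[i], spec$branch_channels[i])
      })
    }
    bm <- make_branch(); bp <- make_branch()
    trunk_in <- c(2L * spec$branch_channels[spec$branch_blocks],
                  spec$trunk_channels[-spec$trunk_blocks])
    tr <- lapply(seq_len(spec$trunk_blocks), function(j) {
      init_resblock(trunk_in[j], spec$trunk_channels[j])
    })
    fedge <- input_edge %/% 2L^halvings
    flen <- fedge^3L * spec$trunk_channels[spec$trunk_blocks]
    head <- init_dense(flen, 2L)
    structure(list(branch_mri = bm, branch_pet = bp, trunk = tr, head = head,
                   spec = spec, input_edge = as.integer(input_edge),
                   feature_length = flen),
              class = "fusion_params")
  })
}

# ---- forward passes --------------------------------------------------------

#' Generator forward pass
#'
#' @param params `generator_params` (possibly tape-wrapped for training).
#' @param x 5-D array `(edge, edge, edge, 1, N)` or a tape node.
#' @param spec generator spec; defaults to the one stored in `params`.
#' @return same-shape output with values in `[0, 1]` (sigmoid output).
#' @export
generator_forward <- function(params, x, spec = NULL) {
  if (is.null(spec)) spec <- params$spec
  L <- spec$depth
  e <- dim(vof(x))[1L]
  if (e %% 2L^L != 0L) stop("input edge not divisible by 2^depth")
  xs <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    h <- tp_lrelu(conv3d(h, params$enc[[i]]$W, params$enc[[i]]$b, stride = 2L), 0.2)
    xs[[i]] <- h
  }
  h <- xs[[L]]
  for (j in seq_len(L)) {
    if (j > 1L) h <- concat_ch(h, xs[[L - j + 1L]])
    h <- convt3d(h, params$dec[[j]]$W, params$dec[[j]]$b)
    h <- if (j < L) tp_relu(h) else switch(spec$output_activation,
                                           sigmoid = tp_sigmoid(h),
                                           identity = h,
                                           stop("unknown output activation"))
  }
  h
}

#' Discriminator forward pass: probability per input patch, strictly in (0,1).
#' @export
discriminator_forward <- function(params, x, spec = NULL) {
  if (is.null(spec)) spec <- params$spec
  h <- x
  for (i in seq_along(params$convs)) {
    h <- tp_lrelu(conv3d(h, params$convs[[i]]$W, params$convs[[i]]$b, stride = 2L),
                  spec$lrelu_slope)
  }
  flat <- flatten5d(h)
  if (is.null(params$head)) stop("discriminator head not initialized; use disc_ensure_head()")
  logit <- dense(flat, params$head$W, params$head$b)
  tp_sigmoid(logit)
}

# The head's input size depends on the patch edge; initialize lazily for the
# training geometry so one spec serves multiple scales.
disc_ensure_head <- function(params, patch_edge, seed = 1L) {
  if (!is.null(params$head)) return(params)
  d <- spec_disc_feat(params$spec, patch_edge)
  params$head <- with_seed(seed + 977L, init_dense(d, 1L))
  params
}

spec_disc_feat <- function(spec, edge) {
  e <- edge
  for (i in seq_len(spec$depth)) e <- (e + 2L - 3L) %/% 2L + 1L
  e^3L * spec$channels[spec$depth]
}

resblock_forward <- function(p, x, training, collect, key) {
  h <- conv3d(x, p$conv1$W, p$conv1$b, stride = 2L)
  h <- tp_relu(batchnorm3d(h, p$bn1$gamma, p$bn1$beta, p$bn1$rmean, p$bn1$rvar,
                           training, collect = collect, key = paste0(key, ".bn1")))
  h <- conv3d(h, p$conv2$W, p$conv2$b, stride = 1L)
  h <- batchnorm3d(h, p$bn2$gamma, p$bn2$beta, p$bn2$rmean, p$bn2$rvar,
                   training, collect = collect, key = paste0(key, ".bn2"))
  sc <- conv3d(x, p$proj$W, p$proj$b, stride = 2L, pad = 0L, k = 1L)
  h <- tp_relu(tp_add(h, sc))
  h2 <- conv3d(h, p$conv3$W, p$conv3$b, stride = 1L)
  h2 <- tp_relu(batchnorm3d(h2, p$bn3$gamma, p$bn3$beta, p$bn3$rmean, p$bn3$rvar,
                            training, collect = collect, key = paste0(key, ".bn3")))
  h2 <- conv3d(h2, p$conv4$W, p$conv4$b, stride = 1L)
  h2 <- batchnorm3d(h2, p$bn4$gamma, p$bn4$beta, p$bn4$rmean, p$bn4$rvar,
                    training, collect = collect, key = paste0(key, ".bn4"))
  tp_relu(tp_add(h2, h))
}

#' Fusion network forward pass
#'
#' Runs MRI and PET through their own Resblock branches, concatenates along
#' the channel axis, applies the trunk, and returns both the fused feature
#' vector (the output of the feature extractor `F`) and the two-class scores
#' from the affine head.
#'
#' @param params `fusion_params`.
#' @param mri,pet 5-D arrays `(edge, edge, edge, 1, N)`.
#' @param training use batch statistics and dropout.
#' @param collect environment receiving updated batch-norm running statistics.
#' @param capture also return the last branch convolution activations
#'   (needed for Grad-CAM).
#' @return list with `features` (N x F), `scores` (N x 2) and optionally
#'   `branch_acts`.
#' @export
fusion_forward <- function(params, mri, pet, training = FALSE,
                           collect = NULL, capture = FALSE, with_head = TRUE) {
  dm <- dim(vof(mri)); dp <- dim(vof(pet))
  if (!all(dm == dp)) stop("MRI and PET inputs must have identical shapes")
  run_branch <- function(bp, x, key) {
    h <- x
    for (i in seq_along(bp)) {
      h <- resblock_forward(bp[[i]], h, training, collect, paste0(key, ".b", i))
      h <- dropout3d(h, params$spec$dropout_rate, training)
    }
    h
  }
  hm <- run_branch(params$branch_mri, mri, "branch_mri")
  hp <- run_branch(params$branch_pet, pet, "branch_pet")
  h <- concat_ch(hm, hp)
  for (j in seq_along(params$trunk)) {
    h <- resblock_forward(params$trunk[[j]], h, training, collect, paste0("trunk.b", j))
    h <- dropout3d(h, params$spec$dropout_rate, training)
  }
  features <- flatten5d(h)
  scores <- if (with_head) dense(features, params$head$W, params$head$b) else NULL
  out <- list(features = features, scores = scores)
  if (capture) out$branch_acts <- list(mri = hm, pet = hp)
  out
}

#' Fused feature extractor F (the fusion network minus its affine head).
#' @export
fusion_features <- function(params, mri, pet, training = FALSE) {
  fusion_forward(params, mri, pet, training = training, with_head = FALSE)$features
}

# ---- parameter plumbing ----------------------------------------------------

.non_trainable <- c("rmean", "rvar", "spec", "input_edge", "feature_length")

# Recursively wrap trainable arrays as tape leaves; running stats and spec
# metadata stay plain.
wrap_params <- function(tape, params) {
  wrap <- function(x, name) {
    if (name %in% .non_trainable) return(x)
    if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) x[[i]] <- wrap(x[[i]], if (is.null(nm)) "" else nm[i])
      return(x)
    }
    if (is.numeric(x)) return(tp_leaf(tape, x)) else return(x)
  }
  out <- wrap(unclass(params), "")
  class(out) <- class(params)
  out
}

# Extract plain values / gradients from a wrapped structure.
unwrap_params <- function(params) {
  un <- function(x) {
    if (is_tp(x)) return(vof(x))
    if (is.list(x)) return(lapply(x, un))
    x
  }
  out <- un(unclass(params))
  class(out) <- class(params)
  out
}

grads_of <- function(params) {
  gr <- function(x) {
    if (is_tp(x)) return(tp_grad(x))
    if (is.list(x)) return(lapply(x, gr))
    NULL
  }
  gr(unclass(params))
}

# Flat list of trainable arrays, for parameter counts and L2 penalties.
param_arrays <- function(params, wrapped = FALSE) {
  out <- list()
  walk <- function(x, name) {
    if (name %in% .non_trainable) return(invisible())
    if (is_tp(x) || is.numeric(x)) { out[[length(out) + 1L]] <<- x; return(invisible()) }
    if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) walk(x[[i]], if (is.null(nm)) "" else nm[i])
    }
    invisible()
  }
  walk(unclass(params), "")
  out
}

#' Number of trainable parameters in a network.
#' @export
param_count <- function(params) {
  sum(vapply(param_arrays(params), function(a) length(vof(a)), numeric(1)))
}

# Stable fingerprint of the trainable parameters (freeze contracts).
param_checksum <- function(params) {
  arrs <- param_arrays(params)
  v <- unlist(lapply(arrs, function(a) as.numeric(vof(a))))
  c(n = length(v), sum = sum(v), asum = sum(abs(v)), ssum = sum(v * v))
}

# Apply updated batch-norm running stats gathered during a training step.
apply_bn_updates <- function(params, collect) {
  for (key in ls(collect)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    # e.g. "branch_mri.b2.bn1" -> params$branch_mri[[2]]$bn1
    blk <- as.integer(sub("^b", "", path[2]))
    st <- collect[[key]]
    params[[path[1]]][[blk]][[path[3]]]$rmean <- st$rmean
    params[[path[1]]][[blk]][[path[3]]]$rvar <- st$rvar
  }
  params
}

# Seed helper: evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
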