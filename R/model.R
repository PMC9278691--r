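#' Architecture hyperparameters of the dose-prediction U-Net
#'
#' Five multiscale levels with feature counts doubling from 16 to 256, two
#' zero-padded 3x3x3 convolutions (each ReLU-activated) per level, dropout
#' after the second convolution of each encoder level with rates increasing
#' 10% to 30% in 5% steps, 2x2x2 max-pooling (stride 2) between encoder
#' levels, a mirrored decoder using parameter-free nearest-neighbour x2
#' upsampling, attention-gated skip concatenations, and a final 1x1x1
#' single-channel convolution with linear activation. No batch
#' normalization. The gate internals (`gate_width = "skip"`, i.e. bottleneck
#' width equal to the skip channel count, and nearest-neighbour upsampling)
#' are the configuration whose trainable-parameter total matches the
#' published network exactly (6,738,869); see the methods vignette.
#'
#' @param n_levels Number of hierarchy levels (>= 2; default 5).
#' @param base_features Feature maps at the first level (default 16).
#' @param feature_growth Multiplicative growth per level (default 2).
#' @param in_channels Input channels (default 12: CT + 11 masks).
#' @param out_channels Output channels (default 1: the dose volume).
#' @param dropout_rates Per-level encoder dropout rates, nondecreasing,
#'   in `[0, 1)`.
#' @param use_attention Gate the skip connections (`TRUE`) or plain
#'   concatenation (`FALSE`, the baseline U-Net).
#' @param gate_width Gate bottleneck width rule; only `"skip"` (bottleneck
#'   width = skip channel count) is supported — it is the rule that
#'   reproduces the published parameter count.
#' @param upsample_mode Decoder upsampling operator; only `"nearest"` is
#'   supported, for the same reason.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_levels = 5L,
                         base_features = 16L,
                         feature_growth = 2L,
                         in_channels = 12L,
                         out_channels = 1L,
                         dropout_rates = 0.10 + 0.05 * (seq_len(n_levels) - 1),
                         use_attention = TRUE,
                         gate_width = "skip",
                         upsample_mode = "nearest") {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop_kbp("n_levels must be >= 2")
  if (length(dropout_rates) != n_levels)
    stop_kbp("need one dropout rate per level")
  if (any(dropout_rates < 0 | dropout_rates >= 1))
    stop_kbp("dropout rates must lie in [0, 1)")
  if (any(diff(dropout_rates) < 0))
    stop_kbp("dropout rates must be nondecreasing with depth")
  if (!identical(gate_width, "skip"))
    stop_kbp("gate_width: only the \"skip\" rule is supported")
  if (!identical(upsample_mode, "nearest"))
    stop_kbp("upsample_mode: only \"nearest\" is supported")
  features <- as.integer(base_features * feature_growth^(seq_len(n_levels) - 1))
  structure(list(n_levels = n_levels, base_features = as.integer(base_features),
                 feature_growth = feature_growth, features = features,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 conv_kernel = 3L, gate_kernel = 1L, pool_kernel = 2L,
                 dropout_rates = dropout_rates,
                 use_attention = isTRUE(use_attention),
                 gate_width = gate_width, upsample_mode = upsample_mode),
            class = "model_config")
}

# A convolution layer: weights as a (k^3 * cin) x cout matrix (tap-major row
# blocks, channels contiguous within a block) plus a per-output-channel bias.
new_conv_layer <- function(k, cin, cout) {
  list(W = matrix(0, k^3 * cin, cout), b = numeric(cout),
       k = as.integer(k), cin = as.integer(cin), cout = as.integer(cout))
}

# Ordered layer table for a given config; order fixes the He-init RNG stream.
build_layers <- function(config) {
  L <- config$n_levels
  f <- config$features
  layers <- list()
  cin <- config$in_channels
  for (l in seq_len(L)) {
    layers[[sprintf("enc%d_conv1", l)]] <- new_conv_layer(3, cin, f[l])
    layers[[sprintf("enc%d_conv2", l)]] <- new_conv_layer(3, f[l], f[l])
    cin <- f[l]
  }
  for (l in rev(seq_len(L - 1))) {
    cs <- f[l]; cc <- f[l + 1]
    if (config$use_attention) {
      layers[[sprintf("gate%d_g", l)]]    <- new_conv_layer(1, cc, cs)
      layers[[sprintf("gate%d_theta", l)]] <- new_conv_layer(2, cs, cs)
      layers[[sprintf("gate%d_phi", l)]]  <- new_conv_layer(1, cs, cs)
      layers[[sprintf("gate%d_phi2", l)]] <- new_conv_layer(3, cs, cs)
      layers[[sprintf("gate%d_psi", l)]]  <- new_conv_layer(1, cs, 1)
      layers[[sprintf("gate%d_out", l)]]  <- new_conv_layer(1, cs, cs)
    }
    layers[[sprintf("dec%d_conv1", l)]] <- new_conv_layer(3, cc + cs, cs)
    layers[[sprintf("dec%d_conv2", l)]] <- new_conv_layer(3, cs, cs)
  }
  layers[["final"]] <- new_conv_layer(1, f[1], config$out_channels)
  layers
}

new_dose_unet <- function(config, params) {
  structure(list(config = config, params = params, curve = NULL,
                 control = NULL, best_epoch = NA_integer_,
                 trained = FALSE),
            class = "dose_unet")
}

#' Build the attention-gated 3D U-Net
#'
#' Constructs the gated network and He-initializes it. The network is fully
#' convolutional: it maps a 12-channel cubic volume to a single-channel
#' volume of the same size, for any edge length divisible by
#' `2^(n_levels - 1)`.
#'
#' @param config A [model_config()] with `use_attention = TRUE`.
#' @param seed Initialization seed (see [initialize_parameters()]).
#' @return A `dose_unet` object.
#' @export
build_attention_unet <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  if (!config$use_attention)
    stop_kbp("config has use_attention = FALSE; use build_baseline_unet()")
  net <- new_dose_unet(config, build_layers(config))
  initialize_parameters(net, seed)
}

#' Build the baseline (gate-free) 3D U-Net
#'
#' Identical topology to [build_attention_unet()] but with plain skip
#' concatenations; used as the comparison architecture.
#'
#' @param config A [model_config()]; `use_attention` is forced to `FALSE`.
#' @param seed Initialization seed.
#' @return A `dose_unet` object.
#' @export
build_baseline_unet <- function(config = model_config(use_attention = FALSE),
                                seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  config$use_attention <- FALSE
  net <- new_dose_unet(config, build_layers(config))
  initialize_parameters(net, seed)
}

#' He-initialize all network parameters
#'
#' Convolution weights are drawn from a zero-mean normal with variance
#' `2 / fan_in` (fan-in = kernel volume times input channels), the scaling
#' appropriate for ReLU networks; all biases are set to zero. Deterministic
#' given the seed.
#'
#' @param net A `dose_unet`.
#' @param seed Integer seed.
#' @return The network with freshly initialized parameters.
#' @export
initialize_parameters <- function(net, seed = 1L) {
  stopifnot(inherits(net, "dose_unet"))
  set.seed(as.integer(seed))
  for (nm in names(net$params)) {
    ly <- net$params[[nm]]
    fan_in <- nrow(ly$W)
    ly$W[] <- stats::rnorm(length(ly$W), 0, sqrt(2 / fan_in))
    ly$b[] <- 0
    net$params[[nm]] <- ly
  }
  net$init_seed <- as.integer(seed)
  net
}

#' Count trainable parameters
#'
#' Sum of the element counts of every trainable weight matrix and bias
#' vector. The default attention configuration totals 6,738,869.
#'
#' @param net A `dose_unet`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(net) {
  stopifnot(inherits(net, "dose_unet"))
  sum(vapply(net$params, function(ly) length(ly$W) + length(ly$b), numeric(1)))
}

#' Create a standalone attention gate
#'
#' Builds the parameter set of one attention-gated skip connection outside a
#' full network, for inspection and testing: a 1x1x1 gating-signal projection
#' (ReLU) from the coarser decoder features, a 2x2x2 stride-2 projection of
#' the skip signal down to the gating resolution, 1x1x1 and 3x3x3
#' convolutions on the gating branch, and a single-channel 1x1x1 convolution
#' whose sigmoid output forms the attention coefficients.
#'
#' @param channels Skip-path channel count (z1).
#' @param gating_channels Channel count of the coarser decoder feature (z2);
#'   twice `channels` in the full network.
#' @param seed He-init seed.
#' @return A named list of gate layers usable with [attention_gate()].
#' @export
make_attention_gate <- function(channels, gating_channels = 2 * channels,
                                seed = 1L) {
  layers <- list(g = new_conv_layer(1, gating_channels, channels),
                 theta = new_conv_layer(2, channels, channels),
                 phi = new_conv_layer(1, channels, channels),
                 phi2 = new_conv_layer(3, channels, channels),
                 psi = new_conv_layer(1, channels, 1))
  set.seed(as.integer(seed))
  for (nm in names(layers)) {
    fan_in <- nrow(layers[[nm]]$W)
    layers[[nm]]$W[] <- stats::rnorm(length(layers[[nm]]$W), 0,
                                     sqrt(2 / fan_in))
  }
  layers
}

#' Apply an attention gate to a skip connection
#'
#' Computes additive attention between the skip-path (propagation) signal
#' `z1` and the coarser-resolution gating signal `z2`: both are projected to
#' a common bottleneck width at the gating resolution, added, ReLU-activated,
#' reduced to one channel, and squashed through a sigmoid to yield
#' coefficients strictly inside (0, 1). The coefficients are upsampled back
#' to the skip resolution and multiply `z1` elementwise (broadcast across
#' channels), so the gated output is bounded by the skip signal in magnitude.
#' Inside the full network an additional 1x1x1 output projection follows the
#' product; it is not part of this function's contract.
#'
#' @param z1 Skip feature volume: `n x C` matrix with a `dims` attribute
#'   (fine grid, each axis even).
#' @param z2 Gating feature volume: `m x Cg` matrix with a `dims` attribute
#'   equal to half the `z1` grid.
#' @param gate Gate parameters from [make_attention_gate()] (or extracted
#'   from a network's `gate<l>_*` layers).
#' @param coefficients Optional override: a vector of length `n` used in
#'   place of the computed coefficients (e.g. all ones or all zeros to probe
#'   the multiplicative limit cases).
#' @return List with `gated` (`n x C`, the product `z1 * coefficients`) and
#'   `coefficients` (length `n`).
#' @export
attention_gate <- function(z1, z2, gate, coefficients = NULL) {
  d1 <- attr(z1, "dims")
  d2 <- attr(z2, "dims")
  if (is.null(d1) || is.null(d2))
    stop_kbp("z1 and z2 need a 'dims' attribute (grid dimensions)")
  if (!all(d1 == 2 * d2))
    stop_kbp("z2 must live on the half-resolution grid of z1 (got ",
             paste(d1, collapse = "x"), " vs ", paste(d2, collapse = "x"), ")")
  if (is.null(coefficients)) {
    g <- pmax(conv_fwd(z2, d2, gate$g), 0)
    tt <- conv_fwd(z1, d1, gate$theta)
    p2 <- conv_fwd(conv_fwd(g, d2, gate$phi), d2, gate$phi2)
    s <- pmax(tt + p2, 0)
    alpha <- sigmoid(conv_fwd(s, d2, gate$psi))
    coefficients <- as.numeric(cpp_upsample2_fwd(alpha, d2[1], d2[2], d2[3]))
  }
  gated <- z1 * coefficients
  attr(gated, "dims") <- d1
  list(gated = gated, coefficients = coefficients)
}
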