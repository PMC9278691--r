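# Forward and backward passes of the (attention-gated) 3D U-Net.
#
# Feature maps are n x C matrices (rows = voxels in column-major x/y/z
# order); grid dimensions travel alongside as a length-3 integer vector.
# The backward pass is hand-derived layer by layer and verified against
# finite differences in the test suite.

# The 3x3x3 kernels compute in float32 by default (the precision deep nets
# are ordinarily trained in); options(kbpdose.double_precision = TRUE)
# switches them to double, which the gradient-verification tests use.
use_double_conv <- function() isTRUE(getOption("kbpdose.double_precision"))

conv_fwd <- function(X, dims, ly) {
  if (ly$k == 3L) {
    cpp_conv3_fwd(X, dims[1], dims[2], dims[3], ly$W, ly$b, use_double_conv())
  } else if (ly$k == 1L) {
    Y <- X %*% ly$W
    Y + rep(ly$b, each = nrow(Y))
  } else if (ly$k == 2L) {
    cpp_conv2s2_fwd(X, dims[1], dims[2], dims[3], ly$W, ly$b)
  } else stop_kbp("unsupported kernel size ", ly$k)
}

conv_bwd <- function(X, dims, ly, gY) {
  if (ly$k == 3L) {
    cpp_conv3_bwd(X, dims[1], dims[2], dims[3], ly$W, gY, use_double_conv())
  } else if (ly$k == 1L) {
    list(gX = gY %*% t(ly$W), gW = crossprod(X, gY), gb = colSums(gY))
  } else if (ly$k == 2L) {
    cpp_conv2s2_bwd(X, dims[1], dims[2], dims[3], ly$W, gY)
  } else stop_kbp("unsupported kernel size ", ly$k)
}

check_input_size <- function(config, dims) {
  div <- 2^(config$n_levels - 1)
  if (any(dims %% div != 0))
    stop_kbp("input size ", paste(dims, collapse = "x"),
             " is not divisible by 2^(n_levels-1) = ", div)
}

# Forward pass. x: n x in_channels matrix; dims: grid dimensions.
# training = TRUE activates (inverted) dropout, drawing masks from the
# current RNG stream. keep_cache retains every intermediate needed by
# unet_backward.
unet_forward <- function(net, x, dims, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  P <- net$params
  L <- cfg$n_levels
  check_input_size(cfg, dims)
  if (ncol(x) != cfg$in_channels)
    stop_kbp("expected ", cfg$in_channels, " input channels, got ", ncol(x))

  enc <- vector("list", L)
  skip <- vector("list", L)
  skip_dims <- vector("list", L)
  cur <- x
  curd <- dims
  for (l in seq_len(L)) {
    z1 <- conv_fwd(cur, curd, P[[sprintf("enc%d_conv1", l)]])
    m1 <- z1 > 0
    a1 <- z1 * m1
    z2 <- conv_fwd(a1, curd, P[[sprintf("enc%d_conv2", l)]])
    m2 <- z2 > 0
    f <- z2 * m2
    dmask <- NULL
    rate <- cfg$dropout_rates[l]
    if (training && rate > 0) {
      keep <- 1 - rate
      dmask <- matrix((stats::runif(length(f)) < keep) / keep,
                      nrow(f), ncol(f))
      f <- f * dmask
    }
    skip[[l]] <- f
    skip_dims[[l]] <- curd
    if (keep_cache)
      enc[[l]] <- list(input = cur, m1 = m1, a1 = a1, m2 = m2,
                       dmask = dmask, dims = curd)
    if (l < L) {
      pl <- cpp_maxpool2_fwd(f, curd[1], curd[2], curd[3])
      if (keep_cache) enc[[l]]$pool_idx <- pl$idx
      cur <- pl$Y
      curd <- curd %/% 2L
    }
  }

  dec <- skip[[L]]
  decd <- skip_dims[[L]]
  dcache <- vector("list", L - 1)
  for (l in rev(seq_len(L - 1))) {
    fd <- skip_dims[[l]]
    sk <- skip[[l]]
    up <- cpp_upsample2_fwd(dec, decd[1], decd[2], decd[3])
    if (cfg$use_attention) {
      g0 <- conv_fwd(dec, decd, P[[sprintf("gate%d_g", l)]])
      mg <- g0 > 0
      g <- g0 * mg
      tt <- conv_fwd(sk, fd, P[[sprintf("gate%d_theta", l)]])
      p <- conv_fwd(g, decd, P[[sprintf("gate%d_phi", l)]])
      p2 <- conv_fwd(p, decd, P[[sprintf("gate%d_phi2", l)]])
      s0 <- tt + p2
      ms <- s0 > 0
      s <- s0 * ms
      alpha <- sigmoid(conv_fwd(s, decd, P[[sprintf("gate%d_psi", l)]]))
      A <- cpp_upsample2_fwd(alpha, decd[1], decd[2], decd[3])
      zg <- sk * A[, 1]
      go <- conv_fwd(zg, fd, P[[sprintf("gate%d_out", l)]])
      sk_used <- go
    } else {
      sk_used <- sk
    }
    cc <- cbind(up, sk_used)
    c0 <- conv_fwd(cc, fd, P[[sprintf("dec%d_conv1", l)]])
    mc0 <- c0 > 0
    c1 <- c0 * mc0
    c2 <- conv_fwd(c1, fd, P[[sprintf("dec%d_conv2", l)]])
    mc2 <- c2 > 0
    dec_out <- c2 * mc2
    if (keep_cache) {
      dcache[[l]] <- list(dec_in = dec, dec_in_dims = decd, sk = sk,
                          fd = fd, cc = cc, mc0 = mc0, c1 = c1, mc2 = mc2)
      if (cfg$use_attention)
        dcache[[l]] <- c(dcache[[l]],
                         list(mg = mg, g = g, p = p, s0 = s0, ms = ms, s = s,
                              alpha = alpha, A = A, zg = zg))
    }
    dec <- dec_out
    decd <- fd
  }

  out <- conv_fwd(dec, decd, P[["final"]])
  cache <- if (keep_cache) list(enc = enc, dec = dcache, skip = skip,
                                skip_dims = skip_dims, last = dec,
                                dims = dims)
           else NULL
  list(out = out, cache = cache)
}

# Backward pass: gout is dLoss/d(out) (n x out_channels). Returns a list of
# gradients with the same names/shapes as net$params.
unet_backward <- function(net, cache, gout) {
  cfg <- net$config
  P <- net$params
  L <- cfg$n_levels
  G <- list()

  r <- conv_bwd(cache$last, cache$dims, P[["final"]], gout)
  G[["final"]] <- list(gW = r$gW, gb = r$gb)
  gdec <- r$gX

  gskip <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dc <- cache$dec[[l]]
    fd <- dc$fd
    cs <- cfg$features[l]
    cc_ch <- cfg$features[l + 1]

    gc2 <- gdec * dc$mc2
    r <- conv_bwd(dc$c1, fd, P[[sprintf("dec%d_conv2", l)]], gc2)
    G[[sprintf("dec%d_conv2", l)]] <- list(gW = r$gW, gb = r$gb)
    gc0 <- r$gX * dc$mc0
    r <- conv_bwd(dc$cc, fd, P[[sprintf("dec%d_conv1", l)]], gc0)
    G[[sprintf("dec%d_conv1", l)]] <- list(gW = r$gW, gb = r$gb)
    gcc <- r$gX
    gup <- gcc[, seq_len(cc_ch), drop = FALSE]
    gsk_used <- gcc[, cc_ch + seq_len(cs), drop = FALSE]

    cd <- dc$dec_in_dims
    gdec_in <- cpp_upsample2_bwd(gup, cd[1], cd[2], cd[3])

    if (cfg$use_attention) {
      r <- conv_bwd(dc$zg, fd, P[[sprintf("gate%d_out", l)]], gsk_used)
      G[[sprintf("gate%d_out", l)]] <- list(gW = r$gW, gb = r$gb)
      gzg <- r$gX
      gsk <- gzg * dc$A[, 1]
      gA <- matrix(rowSums(gzg * dc$sk), ncol = 1)
      galpha <- cpp_upsample2_bwd(gA, cd[1], cd[2], cd[3])
      gq <- galpha * dc$alpha * (1 - dc$alpha)
      r <- conv_bwd(dc$s, cd, P[[sprintf("gate%d_psi", l)]], gq)
      G[[sprintf("gate%d_psi", l)]] <- list(gW = r$gW, gb = r$gb)
      gs0 <- r$gX * dc$ms
      r <- conv_bwd(dc$p, cd, P[[sprintf("gate%d_phi2", l)]], gs0)
      G[[sprintf("gate%d_phi2", l)]] <- list(gW = r$gW, gb = r$gb)
      r <- conv_bwd(dc$g, cd, P[[sprintf("gate%d_phi", l)]], r$gX)
      G[[sprintf("gate%d_phi", l)]] <- list(gW = r$gW, gb = r$gb)
      gg0 <- r$gX * dc$mg
      r <- conv_bwd(dc$dec_in, cd, P[[sprintf("gate%d_g", l)]], gg0)
      G[[sprintf("gate%d_g", l)]] <- list(gW = r$gW, gb = r$gb)
      gdec_in <- gdec_in + r$gX
      r <- conv_bwd(dc$sk, fd, P[[sprintf("gate%d_theta", l)]], gs0)
      G[[sprintf("gate%d_theta", l)]] <- list(gW = r$gW, gb = r$gb)
      gsk <- gsk + r$gX
    } else {
      gsk <- gsk_used
    }
    gskip[[l]] <- gsk
    gdec <- gdec_in
  }

  # gdec now holds the gradient w.r.t. the bottleneck (encoder level L
  # output); walk the encoder from the deepest level back to the input.
  gnext_in <- NULL
  for (l in rev(seq_len(L))) {
    ec <- cache$enc[[l]]
    gf <- if (l == L) gdec
          else gskip[[l]] +
               cpp_maxpool2_bwd(gnext_in, ec$pool_idx, nrow(ec$a1))
    if (!is.null(ec$dmask)) gf <- gf * ec$dmask
    gz2 <- gf * ec$m2
    r <- conv_bwd(ec$a1, ec$dims, P[[sprintf("enc%d_conv2", l)]], gz2)
    G[[sprintf("enc%d_conv2", l)]] <- list(gW = r$gW, gb = r$gb)
    gz1 <- r$gX * ec$m1
    r <- conv_bwd(ec$input, ec$dims, P[[sprintf("enc%d_conv1", l)]], gz1)
    G[[sprintf("enc%d_conv1", l)]] <- list(gW = r$gW, gb = r$gb)
    gnext_in <- r$gX
  }
  G
}
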