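# closed-form parameter accounting, independent of the builder
count_oracle <- function(n_levels = 5, base = 16, in_ch = 12,
                         attention = TRUE) {
  conv <- function(cin, cout, k) cin * cout * k^3 + cout
  f <- base * 2^(seq_len(n_levels) - 1)
  total <- conv(in_ch, f[1], 3) + conv(f[1], f[1], 3)
  for (l in 2:n_levels)
    total <- total + conv(f[l - 1], f[l], 3) + conv(f[l], f[l], 3)
  for (l in seq_len(n_levels - 1)) {
    cs <- f[l]; cc <- f[l + 1]
    total <- total + conv(cc + cs, cs, 3) + conv(cs, cs, 3)
    if (attention)
      total <- total + conv(cc, cs, 1) + conv(cs, cs, 2) + conv(cs, cs, 1) +
        conv(cs, cs, 3) + conv(cs, 1, 1) + conv(cs, cs, 1)
  }
  total + conv(f[1], 1, 1)
}

gate_cost_oracle <- function(n_levels = 5, base = 16) {
  count_oracle(n_levels, base, attention = TRUE) -
    count_oracle(n_levels, base, attention = FALSE)
}

test_that("parameter counts match layer-by-layer closed-form accounting", {
  for (L in c(3, 4, 5)) {
    for (base in c(8, 16)) {
      cfg_a <- model_config(n_levels = L, base_features = base)
      cfg_b <- model_config(n_levels = L, base_features = base,
                            use_attention = FALSE)
      a <- build_attention_unet(cfg_a, seed = 1)
      b <- build_baseline_unet(cfg_b, seed = 1)
      expect_equal(count_trainable_parameters(a), count_oracle(L, base))
      expect_equal(count_trainable_parameters(b),
                   count_oracle(L, base, attention = FALSE))
      expect_lt(count_trainable_parameters(b), count_trainable_parameters(a))
      expect_equal(count_trainable_parameters(a) -
                     count_trainable_parameters(b),
                   gate_cost_oracle(L, base))
    }
  }
  # single-layer sanity: 1x1x1 16->1 with bias; 3x3x3 12->16 with bias
  net <- build_attention_unet(model_config(), seed = 1)
  fin <- net$params$final
  expect_equal(length(fin$W) + length(fin$b), 17)
  e1 <- net$params$enc1_conv1
  expect_equal(length(e1$W) + length(e1$b), 12 * 16 * 27 + 16)
})

test_that("parameter count is invariant to the initialization seed", {
  a <- build_attention_unet(model_config(), seed = 1)
  b <- initialize_parameters(a, seed = 999)
  expect_equal(count_trainable_parameters(a), count_trainable_parameters(b))
  expect_false(identical(a$params$enc1_conv1$W, b$params$enc1_conv1$W))
})

test_that("forward pass honours the shape contract at any divisible size", {
  net <- build_attention_unet(model_config(), seed = 2)
  for (n in c(16, 32)) {
    x <- matrix(0, n^3, 12)
    fw <- kbpdose:::unet_forward(net, x, c(n, n, n))
    expect_equal(dim(fw$out), c(n^3, 1))
    expect_true(all(is.finite(fw$out)))
  }
  expect_error(kbpdose:::unet_forward(net, matrix(0, 24^3, 12), c(24, 24, 24)),
               "divisible")
  expect_error(kbpdose:::unet_forward(net, matrix(0, 16^3, 11), c(16, 16, 16)),
               "channels")
  bl <- build_baseline_unet(seed = 2)
  fw <- kbpdose:::unet_forward(bl, matrix(0, 16^3, 12), c(16, 16, 16))
  expect_equal(dim(fw$out), c(16^3, 1))
})

test_that("He initialization is seeded, fan-in scaled, with zero biases", {
  net1 <- build_attention_unet(model_config(), seed = 42)
  net2 <- build_attention_unet(model_config(), seed = 42)
  expect_identical(net1$params, net2$params)
  for (nm in names(net1$params)) {
    expect_true(all(net1$params[[nm]]$b == 0))
  }
  # deepest encoder entry: 3x3x3 kernel with 128 input channels
  w <- net1$params$enc5_conv1$W
  expect_equal(nrow(w), 27 * 128)
  expect_equal(stats::var(as.numeric(w)), 2 / (27 * 128), tolerance = 0.1)
})

test_that("attention gating is bounded by the skip signal", {
  set.seed(12)
  C <- 16
  gate <- make_attention_gate(C, 2 * C, seed = 12)
  d1 <- c(8, 8, 8); d2 <- c(4, 4, 4)
  z1 <- matrix(rnorm(prod(d1) * C), prod(d1), C)
  z2 <- matrix(rnorm(prod(d2) * 2 * C), prod(d2), 2 * C)
  attr(z1, "dims") <- d1; attr(z2, "dims") <- d2
  out <- attention_gate(z1, z2, gate)
  expect_true(all(out$coefficients > 0 & out$coefficients < 1))
  expect_true(all(abs(out$gated) <= abs(z1) + 1e-12))
  # multiplicative limit cases
  ones <- attention_gate(z1, z2, gate, coefficients = rep(1, prod(d1)))
  expect_equal(ones$gated, z1)
  zero <- attention_gate(z1, z2, gate, coefficients = rep(0, prod(d1)))
  expect_true(all(zero$gated == 0))
  # resolution contract
  attr(z2, "dims") <- c(8, 8, 8)
  expect_error(attention_gate(z1, z2, gate), "half-resolution")
})

test_that("analytic gradients match finite differences in double precision", {
  withr::local_options(kbpdose.double_precision = TRUE)
  set.seed(77)
  net <- build_attention_unet(model_config(n_levels = 3), seed = 3)
  d <- c(8, 8, 8); n <- prod(d)
  x <- matrix(runif(n * 12), n, 12)
  y <- runif(n)
  loss_fn <- function(params) {
    net2 <- net; net2$params <- params
    mean((kbpdose:::unet_forward(net2, x, d)$out[, 1] - y)^2)
  }
  fw <- kbpdose:::unet_forward(net, x, d, keep_cache = TRUE)
  G <- kbpdose:::unet_backward(net, fw$cache,
                               matrix(2 * (fw$out[, 1] - y) / n, ncol = 1))
  h <- 1e-5
  for (nm in names(net$params)) {
    for (i in sample(length(net$params[[nm]]$W), 2)) {
      pp <- net$params; pp[[nm]]$W[i] <- pp[[nm]]$W[i] + h
      pm <- net$params; pm[[nm]]$W[i] <- pm[[nm]]$W[i] - h
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      expect_equal(G[[nm]]$gW[i], num, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})
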