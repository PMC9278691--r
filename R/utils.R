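# Internal helpers shared across modules.

# Canonical structure names, in the fixed channel order used by the network
# input tensor (channel 1 is the CT; channels 2-12 are these masks in order).
CANONICAL_STRUCTURES <- c(
  "PTV_70", "PTV_63", "PTV_56",
  "brainstem", "left_parotid", "right_parotid",
  "spinal_cord", "mandible", "esophagus", "larynx", "body"
)

PTV_NAMES <- c("PTV_70", "PTV_63", "PTV_56")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kbp <- function(...) stop(..., call. = FALSE)

assert_volume3d <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_kbp(name, " must be a 3D array")
  invisible(x)
}

assert_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop_kbp("shape mismatch between ", what, ": ",
             paste(dim(a), collapse = "x"), " vs ",
             paste(dim(b), collapse = "x"))
  invisible(NULL)
}

is_binary_mask <- function(m) {
  is.array(m) && all(m %in% c(0, 1))
}

# Flatten a 3D array into the n x 1 voxel-major layout used by the network
# kernels (column-major in x, y, z), and back.
flatten_volume <- function(vol) {
  assert_volume3d(vol)
  d <- dim(vol)
  m <- matrix(as.numeric(vol), ncol = 1L)
  attr(m, "dims") <- d
  m
}

unflatten_volume <- function(x, dims) {
  array(as.numeric(x), dim = dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Deterministic per-item seed derivation that stays inside 32-bit range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 9973) %% 2147483647)
}
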