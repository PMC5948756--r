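# Internal helpers: validation, unit conversion, small numerics.
# Unit policy: lengths in micrometres, times in seconds (minutes only at the
# reporting boundary), volumes in nanolitres, concentrations in cells/uL.

abort_validation <- function(msg, field = NULL) {
  abort(msg, class = "csfcount_validation_error", field = field)
}

abort_input <- function(msg) {
  abort(msg, class = "csfcount_input_error")
}

check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort_validation(sprintf("`%s` must be supplied", field), field)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", field), field)
  }
  if (strict_min && x <= min) {
    abort_validation(sprintf("`%s` must be > %g (got %g)", field, min, x), field)
  }
  if (!strict_min && x < min) {
    abort_validation(sprintf("`%s` must be >= %g (got %g)", field, min, x), field)
  }
  if (x > max) {
    abort_validation(sprintf("`%s` must be <= %g (got %g)", field, max, x), field)
  }
  invisible(x)
}

# Pixel-centre convention: the top-left pixel centre is the origin, x runs
# along columns (rightward), y along rows (downward).  A point at x um sits
# at continuous column x / pixel_size + 1 in R's 1-based indexing.
um_to_col <- function(x_um, pixel_size) x_um / pixel_size + 1
um_to_row <- function(y_um, pixel_size) y_um / pixel_size + 1
col_to_um <- function(col, pixel_size) (col - 1) * pixel_size
row_to_um <- function(row, pixel_size) (row - 1) * pixel_size

# Evaluate expr under a fixed RNG state when seed is given, leaving the
# caller's RNG untouched; with seed = NULL use (and advance) the current RNG.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one base seed, kept within 32-bit
# integer range so they remain valid R seeds.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Separable 3x3 binomial smoothing ([1 2 1]/4 in each direction).
smooth3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad_r <- rbind(m[1, , drop = FALSE], m, m[H, , drop = FALSE])
  v <- (pad_r[1:H, , drop = FALSE] + 2 * pad_r[2:(H + 1), , drop = FALSE] +
          pad_r[3:(H + 2), , drop = FALSE]) / 4
  pad_c <- cbind(v[, 1, drop = FALSE], v, v[, W, drop = FALSE])
  (pad_c[, 1:W, drop = FALSE] + 2 * pad_c[, 2:(W + 1), drop = FALSE] +
      pad_c[, 3:(W + 2), drop = FALSE]) / 4
}
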