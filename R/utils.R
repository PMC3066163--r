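# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "tfm3d_parameter_error")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Index permutation that moves zero lag (linear index 1 of an FFT output of
# length n) to position floor(n/2) + 1, i.e. the centre of a -L..L-1 lattice.
fftshift_index <- function(n) {
  half <- floor(n / 2)
  c(seq.int(half + 1L, n), seq_len(half))
}

# Lag values after fftshift: -floor(n/2) .. ceiling(n/2) - 1, zero at centre.
lag_values <- function(n) {
  seq.int(-floor(n / 2), length.out = n)
}

check_positive3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be 3 positive finite numbers.", name),
          class = "tfm3d_parameter_error")
  }
  as.numeric(x)
}

# Recover the regular lattice behind a field tibble (x, y, z in micrometers).
# Returns sorted unique axis coordinates and per-row integer indices.
field_lattice <- function(field) {
  ax <- lapply(c("x", "y", "z"), function(a) sort(unique(field[[a]])))
  names(ax) <- c("x", "y", "z")
  idx <- lapply(c("x", "y", "z"), function(a) match(field[[a]], ax[[a]]))
  names(idx) <- c("i", "j", "k")
  list(axes = ax, index = idx,
       dims = vapply(ax, length, integer(1)))
}

rms <- function(x) sqrt(mean(x^2))
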