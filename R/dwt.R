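# Periodized orthogonal discrete wavelet transform.
#
# Only the pieces the motion-artifact corrector needs: a multi-level
# analysis/synthesis pair with perfect reconstruction. The analysis operator
# for a periodized orthogonal wavelet is an orthogonal matrix, so synthesis
# is its transpose; no boundary filters are required beyond periodization.

# Daubechies extremal-phase 10-tap scaling filter ("db5"), standard
# published tabulation, normalized to sum sqrt(2).
DB5_LO <- c(
  0.0033357252854738, -0.0125807519990820, -0.0062414902127983,
  0.0775714938400457, -0.0322448695846384, -0.2422948870663820,
  0.1384281459013207, 0.7243085284377729, 0.6038292697971896,
  0.1601023979741929
)

wavelet_filters <- function(family = "db5") {
  if (!identical(family, "db5")) {
    abort(paste0("unsupported wavelet family: ", family))
  }
  h <- rev(DB5_LO) # analysis low-pass (decomposition order)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * h[L:1L] # quadrature mirror high-pass
  list(h = h, g = g, L = L)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  n2 <- n %/% 2L
  idx <- outer(2L * (seq_len(n2) - 1L), seq_len(filt$L) - 1L, "+") %% n + 1L
  X <- matrix(x[idx], nrow = n2)
  list(a = drop(X %*% filt$h), d = drop(X %*% filt$g))
}

idwt_step <- function(a, d, filt) {
  n2 <- length(a)
  n <- 2L * n2
  idx <- outer(2L * (seq_len(n2) - 1L), seq_len(filt$L) - 1L, "+") %% n + 1L
  y <- numeric(n)
  for (k in seq_len(filt$L)) {
    y[idx[, k]] <- y[idx[, k]] + filt$h[k] * a + filt$g[k] * d
  }
  y
}

#' Multi-level periodized discrete wavelet transform
#'
#' Decomposes a series into `levels` detail bands plus a final approximation
#' using the Daubechies-5 orthogonal wavelet with periodic boundary
#' handling. The series is reflection-padded to a multiple of `2^levels`;
#' [idwt()] undoes the padding, so `idwt(dwt(x))` reproduces `x` to
#' round-off.
#'
#' @param x numeric series, length >= `2^levels`.
#' @param levels decomposition depth (default 5).
#' @param family wavelet family (only `"db5"`).
#' @return a list with elements `details` (list of detail coefficient
#'   vectors, level 1 = finest), `approx`, and bookkeeping for inversion.
#' @export
dwt <- function(x, levels = 5L, family = "db5") {
  filt <- wavelet_filters(family)
  n0 <- length(x)
  if (n0 < 2^levels) {
    abort(sprintf(
      "series of length %d is too short for a %d-level decomposition (need >= %d)",
      n0, levels, 2^levels
    ))
  }
  block <- 2L^levels
  n_pad <- ceiling(n0 / block) * block
  if (n_pad > n0) {
    extra <- n_pad - n0
    # reflect the tail; a series is always long enough because n0 >= block > extra
    x <- c(x, rev(x)[seq_len(extra)])
  }
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, filt)
    details[[j]] <- st$d
    a <- st$a
  }
  structure(
    list(details = details, approx = a, levels = levels, family = family,
         n_orig = n0, n_pad = n_pad),
    class = "nirs_dwt"
  )
}

#' @rdname dwt
#' @param w an `nirs_dwt` object.
#' @export
idwt <- function(w) {
  filt <- wavelet_filters(w$family)
  a <- w$approx
  for (j in rev(seq_len(w$levels))) {
    a <- idwt_step(a, w$details[[j]], filt)
  }
  a[seq_len(w$n_orig)]
}
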