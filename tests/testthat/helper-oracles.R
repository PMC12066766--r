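# Independent brute-force oracles for the weighted graph metrics and the
# modularity optimum. These share no code with the package implementation:
# shortest paths are computed by Floyd-Warshall here (the package uses
# igraph's Dijkstra), and the modularity optimum by exhaustive enumeration
# of set partitions.

random_weighted_graph <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) {
        w[i, j] <- w[j, i] <- runif(1, 0.05, 1)
      }
    }
  }
  w
}

floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

lengths_from_weights <- function(w, expo = 1) {
  len <- matrix(Inf, nrow(w), ncol(w))
  len[w > 0] <- (1 / w[w > 0])^expo
  diag(len) <- 0
  len
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  d <- floyd_warshall(lengths_from_weights(w))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(u) {
    V <- which(w[u, ] > 0)
    k <- length(V)
    if (k < 2) return(0)
    sw <- w[u, V]^(1 / 3)
    d <- floyd_warshall(lengths_from_weights(w[V, V, drop = FALSE], 1 / 3))
    tot <- 0
    for (j in seq_len(k)) {
      for (h in seq_len(k)) {
        if (j != h && is.finite(d[j, h]) && d[j, h] > 0) {
          tot <- tot + sw[j] * sw[h] / d[j, h]
        }
      }
    }
    tot / (k * (k - 1))
  }, numeric(1))
  mean(vals)
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  c_i <- vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
        }
      }
    }
    t_i <- t_i / 2
    2 * t_i / (k * (k - 1))
  }, numeric(1))
  mean(c_i)
}

oracle_modularity <- function(w, membership, gamma = 1) {
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + w[i, j] - gamma * k[i] * k[j] / two_m
      }
    }
  }
  q / two_m
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(memb, mx) {
    if (length(memb) == n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) grow(c(memb, v), max(mx, v))
  }
  grow(integer(0), 0L)
  out
}

oracle_best_partition <- function(w, gamma = 1) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) oracle_modularity(w, p, gamma), numeric(1))
  list(membership = parts[[which.max(qs)]], q = max(qs))
}

# spec for noise-free / artifact-free cohorts used by inversion tests
quiet_cohort_spec <- function(...) {
  cohort_spec(
    noise = list(cardiac = c(1.1, 0), resp = c(0.25, 0), mayer = c(0.1, 0),
                 drift_um = 0, idio_um = 0, latent_roi_um = 0,
                 latent_global_um = 0, latent_tau_s = 3),
    artifacts = list(spikes_per_min = 0, shifts_per_min = 0,
                     spike_amp_sd = c(5, 15), shift_amp_sd = c(3, 8),
                     spike_width_s = 0.2),
    activation_effects = NULL, coupling_effects = NULL,
    ...
  )
}

# deterministic inversion chain: optical density -> band-pass -> MBLL
inversion_config <- function(...) {
  preprocess_config(correct_wavelet = FALSE, correct_spline_sg = FALSE, ...)
}

fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  2 * abs(stats::fft(x))[round(freq * n / fs) + 1L] / n
}
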