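# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles follow the textbook definitions with explicit loops over
# template pairs, deliberately sharing no code with the package implementations.

apen_oracle <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nt <- N - mm + 1L
    tmpl <- lapply(seq_len(nt), function(i) x[i:(i + mm - 1L)])
    cnt <- vapply(seq_len(nt), function(i)
      sum(vapply(seq_len(nt), function(j)
        max(abs(tmpl[[i]] - tmpl[[j]])) <= r, logical(1))), numeric(1))
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1L)
}

sampen_oracle <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  count <- function(mm) {
    tmpl <- lapply(seq_len(nt), function(i) x[i:(i + mm - 1L)])
    total <- 0L
    for (i in seq_len(nt - 1L))
      for (j in (i + 1L):nt)
        if (max(abs(tmpl[[i]] - tmpl[[j]])) <= r) total <- total + 1L
    total
  }
  B <- count(m); A <- count(m + 1L)
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

fuzzen_oracle <- function(x, m, r, n_grad = 2) {
  N <- length(x)
  nt <- N - m
  phi <- function(mm) {
    tmpl <- lapply(seq_len(nt), function(i) {
      v <- x[i:(i + mm - 1L)]
      v - mean(v)
    })
    total <- 0
    for (i in seq_len(nt))
      for (j in seq_len(nt))
        if (i != j)
          total <- total + exp(-(max(abs(tmpl[[i]] - tmpl[[j]])) / r)^n_grad)
    total / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1L))
}

# Periodogram band power: direct FFT integration over band bins, the
# independent check for the Morlet implementation and the epoch generator.
fft_band_power <- function(series, fs, band) {
  n <- length(series)
  sp <- Mod(stats::fft(series))^2 / n
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2]
  sum(sp[keep])
}

# Tiny hand-built state-mode dataset: values chosen per participant, one
# feature unless a matrix is given.
tiny_dataset <- function(values, participants, labels, mode = "state") {
  participant_dataset(matrix(values, ncol = 1), participants, labels, mode = mode)
}

# Standard clustered synthetic config used by several diagnostics tests.
clustered_config <- function(seed, P = 12, n_per = 20, d = 10,
                             delta = 1, sp = 3, sn = 1, mode = "state") {
  synthetic_config(P = P, n_per = n_per, d = d, delta = delta,
                   sigma_participant = sp, sigma_noise = sn,
                   mode = mode, seed = seed)
}
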