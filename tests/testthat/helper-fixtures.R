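# Shared fixtures: geometric rasters with known analytic properties, plus an
# independent brute-force Otsu used as oracle against the implementation.

disk_mask <- function(r, pad = 10L) {
  n <- 2L * (r + pad) + 1L
  cen <- r + pad + 1L
  outer(seq_len(n), seq_len(n), function(i, j) (i - cen)^2 + (j - cen)^2 <= r^2)
}

square_mask <- function(side, pad = 10L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  m
}

ellipse_mask <- function(a, b, pad = 10L) {
  n <- 2L * (max(a, b) + pad) + 1L
  cen <- max(a, b) + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - cen) / b)^2 + ((j - cen) / a)^2 <= 1)
}

# brute-force Otsu: explicit scan of all 256 thresholds
otsu_bruteforce <- function(values8) {
  best_t <- NA_integer_; best_v <- -Inf
  n <- length(values8)
  for (t in 0:255) {
    g0 <- values8[values8 <= t]; g1 <- values8[values8 > t]
    if (!length(g0) || !length(g1)) next
    v <- (length(g0) / n) * (length(g1) / n) * (mean(g0) - mean(g1))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# independent log-rank chi-square from the 2x2 contingency construction
logrank_chisq_hand <- function(time, event, g) {
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n <- sum(time >= t); n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1); d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# tiny uniform sections (constant colour + class blob) for split arithmetic
fake_section <- function(n = 32L, id = "s") {
  list(image = array(runif(n * n * 3), c(n, n, 3)),
       mask = matrix(0, n, n), id = id)
}
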