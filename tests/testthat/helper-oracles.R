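# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force summation, scalar BFS flood fill,
# normal equations, textbook formulas.

random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# scalar BFS flood fill (queue-based), independent of the package's
# min-label propagation labeler
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  cur <- 0L
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      if (!mask[r0, c0] || lab[r0, c0] > 0L) next
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (o in offs) {
          r <- p[1] + o[1]
          c <- p[2] + o[2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# canonical form of a labeling: list of sorted pixel-index sets, sorted
partition_of <- function(lab) {
  sets <- split(which(lab > 0), lab[lab > 0])
  sets <- lapply(sets, function(s) sort(unname(s)))
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

# double-loop raw moment
moment_oracle <- function(mask, i, j) {
  s <- 0
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) s <- s + (c - 1)^i * (r - 1)^j
    }
  }
  s
}

rasterize_disk <- function(n, radius, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  m <- matrix(FALSE, n, n)
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      m[r, c] <- (r - cy)^2 + (c - cx)^2 < radius^2
    }
  }
  m
}

rasterize_ellipse <- function(a, b, pad = 5) {
  nr <- 2 * b + 2 * pad
  nc <- 2 * a + 2 * pad
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  m <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      m[r, c] <- ((c - cx) / a)^2 + ((r - cy) / b)^2 < 1
    }
  }
  m
}

# least squares via normal equations
normal_eq_beta <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# partial correlation via the inverse correlation matrix
pcor_matrix_oracle <- function(y, x, Z) {
  m <- cbind(y = y, x = x, as.matrix(Z))
  p <- solve(stats::cor(m))
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# textbook Welch statistic
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# shared fixtures (built once per test run)
shared_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) map <<- build_axon_map(n_bundles = 150)
    map
  }
})

# small per-drawing descriptor table with known structure (no rendering)
toy_drawing_table <- function() {
  grid <- expand.grid(
    participant = c("P1", "P2"),
    electrode1 = c("C4", "D6"),
    amplitude_x_th = c(1.5, 2),
    frequency_hz = c(20, 40),
    trial = 1:3,
    stringsAsFactors = FALSE
  )
  grid$electrode2 <- NA_character_
  base <- ifelse(grid$participant == "P1", 100, 200)
  fac <- grid$amplitude_x_th / 2 * sqrt(grid$frequency_hz / 20)
  tibble::tibble(
    participant = grid$participant,
    electrode1 = grid$electrode1,
    electrode2 = grid$electrode2,
    electrodes = grid$electrode1,
    amplitude_x_th = grid$amplitude_x_th,
    frequency_hz = grid$frequency_hz,
    trial = grid$trial,
    area = base * fac,
    perimeter = base / 10 * fac,
    major = base / 20 * fac,
    minor = base / 40 * fac,
    n_phosphenes = 1
  )
}
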