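# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain double loops / explicit algebra, sharing no
# code with the package internals they check.

oracle_rollsum <- function(x, t) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (m in seq_len(n)) {
    if (m >= t) {
      s <- 0
      for (q in (m - t + 1):m) s <- s + x[q]
      out[m] <- s
    }
  }
  out
}

oracle_gringorten <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.44) / (n + 0.12))
}

# plain-R IRLS with bisquare weights, mirroring the documented algorithm
oracle_irls <- function(X, y, c = 4.685, tol = 1e-8, maxit = 50) {
  colnames(X) <- NULL
  beta <- unname(qr.solve(X, y))
  ols <- beta
  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    s <- median(abs(r)) / 0.6745
    if (s < 1e-12 * (1 + median(abs(y)))) return(drop(beta))
    u <- r / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) < 1e-12) return(drop(ols))
    sw <- sqrt(w)
    bnew <- unname(qr.solve(X * drop(sw), y * drop(sw)))
    if (sqrt(sum((bnew - beta)^2)) < tol * (1 + sqrt(sum(bnew^2))))
      return(drop(bnew))
    beta <- bnew
  }
  drop(ols)
}

# one explicit LOOCV fold: detrend/standardize on training years, robust
# regression, prediction of the held-out standardized value
oracle_loocv_fold <- function(ba, x, hold) {
  n <- length(ba)
  tr <- setdiff(seq_len(n), hold)
  Xt <- cbind(1, tr)
  cb <- oracle_irls(Xt, ba[tr])
  rb <- ba[tr] - (cb[1] + cb[2] * tr)
  zb <- (rb - mean(rb)) / sd(rb)
  cx <- oracle_irls(Xt, x[tr])
  rx <- x[tr] - (cx[1] + cx[2] * tr)
  zx <- (rx - mean(rx)) / sd(rx)
  cr <- oracle_irls(cbind(1, zx), zb)
  xh <- (x[hold] - (cx[1] + cx[2] * hold) - mean(rx)) / sd(rx)
  list(pred = unname(cr[1] + cr[2] * xh), beta = unname(cr[2]),
       obs_std = unname((ba[hold] - (cb[1] + cb[2] * hold) -
                           mean(rb)) / sd(rb)))
}

oracle_blocksum <- function(fine, factor) {
  d <- dim(fine)
  out <- matrix(0, d[1] / factor, d[2] / factor)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    s <- 0
    for (a in ((i - 1) * factor + 1):(i * factor))
      for (b in ((j - 1) * factor + 1):(j * factor))
        s <- s + fine[a, b]
    out[i, j] <- s
  }
  out
}

# scalar Thornthwaite PET for one month, written from the textbook formulas
oracle_thornthwaite_month <- function(Tm, Tclim12, lat_deg, month) {
  if (Tm <= 0) return(0)
  pos <- pmax(Tclim12, 0)
  I <- sum((pos[pos > 0] / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  mid <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  delta <- 0.409 * sin(2 * pi * mid[month] / 365 - 1.39)
  phi <- lat_deg * pi / 180
  ws <- acos(min(max(-tan(phi) * tan(delta), -1), 1))
  L <- 24 / pi * ws
  nd <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month]
  16 * (10 * Tm / I)^a * (L / 12) * (nd / 30)
}

# a single-cell monthly grid from a numeric series
grid1 <- function(x, units = "mm/month", start = c(1L, 1L)) {
  monthly_grid(array(x, dim = c(1, 1, length(x))), lat = 0, lon = 0,
               start = start, units = units)
}

# tiny fitted-map stub for verification-summary tests
toy_fit_map <- function(r, significant, beta = NULL, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(r), ncol(r))
  structure(list(r = r, significant = significant,
                 beta = if (is.null(beta)) r else beta,
                 mask = mask, season = season_spec("JJA")),
            class = "fire_fit_map")
}
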