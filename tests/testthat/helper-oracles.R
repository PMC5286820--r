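# Independent brute-force oracles, kept free of the package's own code
# paths: explicit model-matrix regression for Type-II ANOVA, the direct
# Scheffe bound per contrast, hand step-up BH, and a numeric solver for
# the variance-prior moment equations.

# residual sum of squares of y on a design matrix via QR projection
.rssOn <- function(y, X) {
  fit <- qr(X)
  sum((y - X %*% qr.coef(fit, y))^2)
}

# Type-II two-way ANOVA from adjusted sums of squares
oracleTypeII <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  mm <- function(f) model.matrix(f, data = data.frame(A = A, B = B))
  rss_full <- .rssOn(y, mm(~ A * B))
  rss_ab <- .rssOn(y, mm(~ A + B))
  rss_a <- .rssOn(y, mm(~ A))
  rss_b <- .rssOn(y, mm(~ B))
  ss <- c(A = rss_b - rss_ab, B = rss_a - rss_ab, AB = rss_ab - rss_full)
  df <- c(A = nlevels(A) - 1L, B = nlevels(B) - 1L,
          AB = (nlevels(A) - 1L) * (nlevels(B) - 1L))
  df_err <- length(y) - nlevels(A) * nlevels(B)
  mse <- rss_full / df_err
  F <- (ss / df) / mse
  list(SS = ss, df = df, F = F,
       p = pf(F, df, df_err, lower.tail = FALSE),
       rss = rss_full, df_err = df_err)
}

# Type-I (sequential) SS for the A-then-B ordering, to contrast with Type II
oracleTypeI_A <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  mm <- function(f) model.matrix(f, data = data.frame(A = A, B = B))
  .rssOn(y, mm(~ 1)) - .rssOn(y, mm(~ A))
}

# Scheffe adjusted p for every pair of groups, from first principles
oracleScheffe <- function(y, g, mse, df_err) {
  g <- factor(g)
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  out <- list()
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    Fc <- unname((means[i] - means[j])^2 / (mse * (1 / ns[i] + 1 / ns[j])))
    out[[paste(levels(g)[i], levels(g)[j], sep = "|")]] <-
      pf(Fc / (k - 1), k - 1, df_err, lower.tail = FALSE)
  }
  unlist(out)
}

# BH step-up by hand
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Numeric solve of the variance-prior moment equations on log s^2:
# Var[e] = trigamma(d/2) + trigamma(d0/2), E[e] = log s0^2 + digamma(d0/2)
# - log(d0/2), with e = log s^2 - digamma(d/2) + log(d/2).
oracleVariancePrior <- function(s2, df) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar <= 0) return(list(d0 = Inf, s0_sq = mean(s2)))
  f <- function(x) trigamma(x) - evar
  half_d0 <- uniroot(f, c(1e-8, 1e8), tol = 1e-14)$root
  list(d0 = 2 * half_d0,
       s0_sq = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}

# Pooled two-sample t per gene (rows), plain formulas
oraclePooledT <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  d <- n1 + n2 - 2
  s2 <- (rowSums((x1 - rowMeans(x1))^2) +
           rowSums((x2 - rowMeans(x2))^2)) / d
  delta <- rowMeans(x1) - rowMeans(x2)
  t <- delta / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, df = d, p = 2 * pt(abs(t), d, lower.tail = FALSE),
       s2 = s2, delta = delta)
}

# dense-sampling arc length oracle for a parametric curve
oracleCurveLength <- function(fx, fy, from, to, n = 2e5) {
  t <- seq(from, to, length.out = n)
  sum(sqrt(diff(fx(t))^2 + diff(fy(t))^2))
}

# small balanced/unbalanced random two-way dataset
randomTwoWay <- function(seed, unbalanced = FALSE) {
  set.seed(seed)
  cells <- expand.grid(ecotype = c("Col-0", "WS"), angle_gp = c(45, 90, 135),
                       stringsAsFactors = FALSE)
  n <- if (unbalanced) sample(2:6, nrow(cells), replace = TRUE)
       else rep(sample(3:5, 1), nrow(cells))
  eff_e <- rnorm(2); eff_a <- rnorm(3); eff_i <- rnorm(6, sd = 0.5)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(ecotype = cells$ecotype[i], angle_gp = cells$angle_gp[i],
               y = eff_e[match(cells$ecotype[i], c("Col-0", "WS"))] +
                 eff_a[match(cells$angle_gp[i], c(45, 90, 135))] +
                 eff_i[i] + rnorm(n[i]))
  }))
}

# straight-root trace at a given angle from vertical (toward +x)
straightTrace <- function(theta_deg, length_mm = 20, n = 50) {
  t <- seq(0, length_mm, length.out = n)
  th <- theta_deg * pi / 180
  cbind(t * sin(th), t * cos(th))
}

# sinusoidal trace: k full periods of given amplitude about a vertical chord
sineTrace <- function(k, amplitude, chord = 30, n = 1200) {
  t <- seq(0, chord, length.out = n)
  cbind(amplitude * sin(2 * pi * k * t / chord), t)
}
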