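# Independent brute-force reference implementations, written as plain
# double loops straight from the index definitions. They share no code with
# the package internals and exist solely to validate them.

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:nt) for (j in 1:nt) {
    if (i == j) next
    dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
    if (dm <= r) {
      B <- B + 1
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

oracle_fuzzyen <- function(x, m, r, nf) {
  n <- length(x)
  nt <- n - m
  phi <- function(mm) {
    acc <- 0
    for (i in 1:nt) for (j in 1:nt) {
      if (i == j) next
      u <- x[i:(i + mm - 1)]; u <- u - mean(u)
      v <- x[j:(j + mm - 1)]; v <- v - mean(v)
      acc <- acc + exp(-(max(abs(u - v)) / r)^nf)
    }
    acc / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

oracle_dispen <- function(x, m, nc) {
  z <- round(pnorm(x, mean(x), sd(x)) * nc + 0.5)
  z <- pmin(pmax(z, 1), nc)
  pats <- character(0)
  for (i in 1:(length(z) - m + 1))
    pats <- c(pats, paste(z[i:(i + m - 1)], collapse = "-"))
  p <- table(pats) / length(pats)
  -sum(p * log(p)) / log(nc^m)
}

oracle_permen <- function(x, m) {
  # tie-free input assumed; ordinal pattern by sorting order
  pats <- character(0)
  for (i in 1:(length(x) - m + 1))
    pats <- c(pats, paste(sort.list(x[i:(i + m - 1)]), collapse = ""))
  p <- table(pats) / length(pats)
  -sum(p * log(p)) / log(factorial(m))
}

oracle_maxmin <- function(x) {
  s <- floor((x - min(x)) / (max(x) - min(x)) * 6)
  s[s == 6] <- 5
  fam <- c(`Symb-0V` = 0, `Symb-1V` = 0, `Symb-2LV` = 0, `Symb-2UV` = 0)
  for (i in 1:(length(s) - 2)) {
    w <- s[i:(i + 2)]
    d1 <- w[2] - w[1]; d2 <- w[3] - w[2]
    if (d1 == 0 && d2 == 0) fam["Symb-0V"] <- fam["Symb-0V"] + 1
    else if (d1 == 0 || d2 == 0) fam["Symb-1V"] <- fam["Symb-1V"] + 1
    else if (sign(d1) == sign(d2)) fam["Symb-2LV"] <- fam["Symb-2LV"] + 1
    else fam["Symb-2UV"] <- fam["Symb-2UV"] + 1
  }
  100 * fam / sum(fam)
}

oracle_binary_symb <- function(x) {
  s <- ifelse(diff(x) > 0, 1, 0)
  fam <- c(`Bin-0V` = 0, `Bin-1V` = 0, `Bin-2V` = 0)
  for (i in 1:(length(s) - 2)) {
    w <- s[i:(i + 2)]
    nch <- (w[1] != w[2]) + (w[2] != w[3])
    fam[nch + 1] <- fam[nch + 1] + 1
  }
  100 * fam / sum(fam)
}

oracle_hrf <- function(x) {
  d <- diff(x)
  s <- ifelse(d < 0, 1, ifelse(d > 0, -1, 0))
  m <- length(s)
  infl <- 0
  for (i in 1:(m - 1)) if (s[i + 1] != s[i]) infl <- infl + 1
  w <- c(0, 0, 0, 0)
  for (i in 1:(m - 3)) {
    cnt <- 0
    for (j in 0:2) if (s[i + j] != s[i + j + 1]) cnt <- cnt + 1
    w[cnt + 1] <- w[cnt + 1] + 1
  }
  c(`HRF-PIP` = 100 * infl / (m - 1),
    setNames(100 * w / sum(w), c("HRF-W0", "HRF-W1", "HRF-W2", "HRF-W3")))
}

oracle_asymmetry <- function(x) {
  d <- diff(x)
  d <- d[d != 0]
  c(Porta = 100 * sum(d < 0) / length(d),
    Guzik = 100 * sum(d[d > 0]^2) / sum(d^2),
    Ehlers = sum(d^3) / sum(d^2)^(3 / 2))
}

oracle_prsa <- function(x, L, filter, direction) {
  n <- length(x)
  anchors <- integer(0)
  for (i in 2:n) {
    if (direction == "dc" && !(x[i] > x[i - 1])) next
    if (direction == "ac" && !(x[i] < x[i - 1])) next
    if (abs(x[i] - x[i - 1]) > filter * x[i - 1]) next
    if (i - L < 1 || i + L - 1 > n) next
    anchors <- c(anchors, i)
  }
  if (length(anchors) == 0) return(NA_real_)
  X <- numeric(2 * L)
  for (k in seq(-L, L - 1)) {
    acc <- 0
    for (a in anchors) acc <- acc + x[a + k]
    X[k + L + 1] <- acc / length(anchors)
  }
  (X[L + 1] + X[L + 2] - X[L] - X[L - 1]) / 4
}

oracle_auroc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  acc <- 0
  for (a in pos) for (b in neg)
    acc <- acc + (a > b) + 0.5 * (a == b)
  acc / (length(pos) * length(neg))
}

# DeLong variance of the AUROC difference via explicitly looped structural
# components
oracle_delong <- function(sa, sb, positive) {
  xs <- cbind(sa, sb)[positive, , drop = FALSE]
  ys <- cbind(sa, sb)[!positive, , drop = FALSE]
  m <- nrow(xs); n <- nrow(ys)
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- matrix(0, m, 2); v01 <- matrix(0, n, 2)
  for (r in 1:2) {
    for (i in 1:m) {
      acc <- 0
      for (j in 1:n) acc <- acc + psi(xs[i, r], ys[j, r])
      v10[i, r] <- acc / n
    }
    for (j in 1:n) {
      acc <- 0
      for (i in 1:m) acc <- acc + psi(xs[i, r], ys[j, r])
      v01[j, r] <- acc / m
    }
  }
  theta <- colMeans(v10)
  s10 <- cov(v10); s01 <- cov(v01)
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  list(delta = theta[1] - theta[2], var_delta = var_delta)
}

# shared battery of seeded random RRi-like test series (100-300 beats)
random_test_series <- function(n_series = 20, seed = 404) {
  set.seed(seed)
  lapply(seq_len(n_series), function(i) {
    n <- sample(100:300, 1)
    800 + 50 * rnorm(n) + 20 * sin(2 * pi * seq_len(n) / sample(20:60, 1))
  })
}
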