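# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. Deliberately naive: plain loops and
# direct definitions, no shared code with the package internals.

gfp_oracle <- function(epoch) {
  apply(epoch, 2, function(v) sqrt(mean((v - mean(v))^2)))
}

transition_count_oracle <- function(s, K) {
  N <- matrix(0, K, K)
  for (t in seq_len(length(s) - 1))
    N[s[t] + 1, s[t + 1] + 1] <- N[s[t] + 1, s[t + 1] + 1] + 1
  N
}

# full T x T recurrence matrix + exhaustive diagonal scan
rqa_oracle <- function(s, l_min = 2) {
  T <- length(s)
  R <- outer(s, s, `==`)
  rr <- sum(R) / T^2
  num <- 0; pts <- 0
  for (d in c(-(T - 1):-1, 1:(T - 1))) {
    line <- 0
    for (t in 1:T) {
      tp <- t + d
      if (tp < 1 || tp > T) next
      if (s[t] == s[tp]) {
        line <- line + 1; pts <- pts + 1
      } else {
        if (line >= l_min) num <- num + line
        line <- 0
      }
    }
    if (line >= l_min) num <- num + line
  }
  det <- if (pts > 0) num / pts else 0
  c(recurrence_rate = rr, determinism = det)
}

sampen_oracle <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

permen_oracle <- function(x, m = 3, delay = 1) {
  n <- length(x) - (m - 1) * delay
  pats <- character(n)
  for (i in 1:n) {
    w <- x[i + (0:(m - 1)) * delay]
    pats[i] <- paste(rank(w, ties.method = "first"), collapse = ".")
  }
  p <- table(pats) / n
  -sum(p * log(p))
}

# LZ76 by the substring definition: a phrase s[i..j] completes when it is
# not a substring of s[1..j-1]; final partial phrase still counts.
lz76_oracle <- function(s) {
  s <- paste0("a", as.integer(factor(s))) # tokens to avoid digit collisions
  toks <- s
  n <- length(toks)
  c_s <- 0; i <- 1
  while (i <= n) {
    j <- i
    repeat {
      phrase <- paste(toks[i:j], collapse = " ")
      history <- paste(toks[seq_len(j - 1)], collapse = " ")
      if (j == n || !grepl(phrase, history, fixed = TRUE)) break
      j <- j + 1
    }
    c_s <- c_s + 1
    i <- j + 1
  }
  c_s
}

ngram_count_oracle <- function(s, n = 3) {
  s <- match(s, sort(unique(s))) - 1
  m <- length(s) - n + 1
  pats <- sapply(1:m, function(i) paste(s[i:(i + n - 1)], collapse = "_"))
  p <- as.numeric(table(pats)) / m
  -sum(p * log(p))
}

# plain-loop DFA, same window schedule contract as the implementation
dfa_oracle <- function(x, n_sizes = 12) {
  N <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(N / 4), length.out = n_sizes))))
  Fn <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    nseg <- N %/% n
    ss <- 0; cnt <- 0
    for (j in 1:nseg) {
      seg <- y[((j - 1) * n + 1):(j * n)]
      t_ <- 1:n
      fit <- lm(seg ~ t_)
      ss <- ss + sum(residuals(fit)^2)
      cnt <- cnt + n
    }
    Fn[si] <- sqrt(ss / cnt)
  }
  ok <- Fn > 0
  unname(coef(lm(log(Fn[ok]) ~ log(sizes[ok])))[2])
}

hurst_oracle <- function(x, n_sizes = 10) {
  N <- length(x)
  sizes <- unique(round(exp(seq(log(8), log(N / 2), length.out = n_sizes))))
  rs <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    vals <- c()
    for (j in 1:(N %/% n)) {
      w <- x[((j - 1) * n + 1):(j * n)]
      s <- sd(w)
      if (s == 0) next
      y <- cumsum(w - mean(w))
      vals <- c(vals, (max(y) - min(y)) / s)
    }
    rs[si] <- mean(vals)
  }
  ok <- is.finite(rs) & rs > 0
  unname(coef(lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

# U statistic from first principles: count pairwise wins + half-ties
mwu_oracle <- function(x, y) {
  wins_x <- 0
  for (xi in x) for (yj in y)
    wins_x <- wins_x + (xi > yj) + 0.5 * (xi == yj)
  U1 <- length(x) * length(y) - wins_x # losses of x = U1 under rank formula
  U2 <- wins_x
  min(U1, U2)
}

cliffs_oracle <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) { gt <- gt + (xi > yj); lt <- lt + (xi < yj) }
  (gt - lt) / (length(x) * length(y))
}

cohens_d_oracle <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# random label sequences for property tests
random_labels <- function(n, K = 4, seed = 1) {
  set.seed(seed)
  sample(0:(K - 1), n, replace = TRUE)
}
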