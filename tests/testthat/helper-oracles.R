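# Independent oracles and small fixtures shared across tests.

# brute-force AUC by pair counting (ties count one half)
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# isotropic variogram-slope Hurst estimator for a 2D field:
# E|I(x+d) - I(x)|^2 ~ |d|^(2H) over small lags
variogram_hurst <- function(f, lags = 1:8) {
  v <- sapply(lags, function(L) {
    n <- nrow(f); m <- ncol(f)
    dx <- f[(1 + L):n, ] - f[1:(n - L), ]
    dy <- f[, (1 + L):m] - f[, 1:(m - L)]
    mean(c(dx^2, dy^2))
  })
  unname(coef(lm(log(v) ~ log(lags)))[2]) / 2
}

# all 26 neighbor offsets and the 13 unique directions
OFFS26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
OFFS26 <- OFFS26[rowSums(abs(OFFS26)) > 0, ]
OFFS13 <- OFFS26[apply(OFFS26, 1, function(o) {
  o[1] > 0 || (o[1] == 0 && o[2] > 0) || (o[1] == 0 && o[2] == 0 && o[3] > 0)
}), ]

# brute-force symmetric merged GLCM by explicit pair enumeration
brute_glcm <- function(q, Ng) {
  dm <- dim(q)
  M <- matrix(0, Ng, Ng)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- q[x, y, z]
    if (a == 0) next
    for (k in seq_len(nrow(OFFS13))) {
      p <- c(x, y, z) + OFFS13[k, ]
      if (any(p < 1) || any(p > dm)) next
      b <- q[p[1], p[2], p[3]]
      if (b == 0) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  if (sum(M) > 0) M / sum(M) else M
}

# brute-force merged run-length counts by walking every direction line
brute_glrlm <- function(q, Ng) {
  dm <- dim(q)
  maxlen <- max(dm)
  M <- matrix(0, Ng, maxlen)
  for (k in seq_len(nrow(OFFS13))) {
    d <- OFFS13[k, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      a <- q[x, y, z]
      if (a == 0) next
      prev <- c(x, y, z) - d
      if (all(prev >= 1) && all(prev <= dm) && q[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      cur <- c(x, y, z) + d
      while (all(cur >= 1) && all(cur <= dm) && q[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1
        cur <- cur + d
      }
      M[a, len] <- M[a, len] + 1
    }
  }
  M[, seq_len(max(1, max(which(colSums(M) > 0)))), drop = FALSE]
}

# brute-force 26-connected zone sizes via repeated flood fill in R
brute_glszm <- function(q, Ng) {
  dm <- dim(q)
  seen <- array(FALSE, dm)
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (seen[x, y, z] || q[x, y, z] == 0) next
    a <- q[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(OFFS26))) {
        p <- cur + OFFS26[k, ]
        if (any(p < 1) || any(p > dm)) next
        if (!seen[p[1], p[2], p[3]] && q[p[1], p[2], p[3]] == a) {
          seen[p[1], p[2], p[3]] <- TRUE
          stack[[length(stack) + 1]] <- p
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  maxsize <- max(vapply(zones, `[`, 0, 2))
  M <- matrix(0, Ng, maxsize)
  for (zn in zones) M[zn[1], zn[2]] <- M[zn[1], zn[2]] + 1
  M
}

# a small cached 64^3 phantom case reused across test files
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom_case(phantom_spec(grid_size = 64),
                                      c(IDH = "negative"), seed = 3)
    cache
  }
})

# random labeled feature table: a few informative columns + noise
toy_feature_table <- function(n = 40, p_noise = 30, n_inf = 2, effect = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("positive", "negative"), length.out = n)
    X <- matrix(rnorm(n * (p_noise + n_inf)), n)
    for (k in seq_len(n_inf))
      X[, k] <- X[, k] + effect * (y == "positive")
    colnames(X) <- c(sprintf("inf%02d", seq_len(n_inf)),
                     sprintf("noise%03d", seq_len(p_noise)))
    X <- as.data.frame(X)
    rownames(X) <- sprintf("c%03d", seq_len(n))
    list(X = X, y = y)
  })
}

fixture_table_path <- function() {
  system.file("extdata", "cohort_distribution_synthetic.csv",
              package = "gliofract")
}
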