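# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition (per-pair formulas, explicit loops) and never
# call the implementation paths they check.

pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# spatial correlation per pair: build the two reduced rows and apply Pearson
spatial_oracle <- function(M) {
  V <- nrow(M)
  S <- diag(V)
  for (i in seq_len(V - 1)) for (j in (i + 1):V) {
    keep <- setdiff(seq_len(V), c(i, j))
    a <- M[i, keep]; b <- M[j, keep]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else pearson_oracle(a, b)
    S[i, j] <- r; S[j, i] <- r
  }
  S
}

# two-step neighbour filtering, written as literal enumeration
voxel_threshold_oracle <- function(R, i, nbrs6, mean_pos) {
  r <- R[i, nbrs6[[i]]]
  r <- r[r >= 0]
  r <- r[r >= mean_pos]
  if (length(r) == 0) return(NaN)
  r2 <- r[r >= mean(r)]
  mean(r2)
}

adaptive_threshold_oracle <- function(R, geometry) {
  nbrs6 <- neighbor_list(geometry, 6L)
  ut <- R[upper.tri(R)]
  mean_pos <- mean(ut[ut > 0])
  thr <- sapply(seq_len(geometry$V), function(i)
    voxel_threshold_oracle(R, i, nbrs6, mean_pos))
  mean(thr[!is.nan(thr)])
}

# breadth-first growth keyed on the seed correlation
grow_oracle <- function(R, seed, T_a, nbrs26) {
  members <- seed
  repeat {
    cand <- setdiff(unique(unlist(nbrs26[members])), members)
    add <- cand[R[seed, cand] >= T_a]
    if (length(add) == 0) break
    members <- c(members, add)
  }
  sort(members)
}

rger_oracle <- function(clusters) {
  V <- length(clusters)
  err <- 0
  for (i in seq_len(V - 1)) for (j in (i + 1):V) {
    a <- j %in% clusters[[i]]
    b <- i %in% clusters[[j]]
    if (xor(a, b)) err <- err + 1
  }
  err / (V * (V - 1) / 2)
}

size_maps_oracle <- function(clusters) {
  V <- length(clusters)
  M <- lengths(clusters)
  N <- sapply(seq_len(V), function(i)
    sum(sapply(clusters, function(cl) i %in% cl)))
  list(M = as.numeric(M), N = as.numeric(N))
}

# traditional degree by per-pair summation
degree_oracle <- function(R, T_d, metric) {
  V <- nrow(R)
  wfun <- switch(metric, U = function(r) 1, W = identity,
                 WS = function(r) r^2, WF = function(r) 0.5 * log((1 + r) / (1 - r)))
  sapply(seq_len(V), function(i) {
    s <- 0
    for (j in seq_len(V)) {
      if (j == i) next
      if (R[i, j] >= T_d) s <- s + wfun(R[i, j])
    }
    s
  })
}

# corrected degree by the literal triple loop over (i, j, k)
rse_oracle <- function(R, T_d, clusters, metric) {
  V <- nrow(R)
  wfun <- switch(metric, U = function(r) 1, W = identity,
                 WS = function(r) r^2, WF = function(r) 0.5 * log((1 + r) / (1 - r)))
  sapply(seq_len(V), function(i) {
    s <- 0
    for (j in seq_len(V)) {
      if (j == i) next
      if (R[i, j] < T_d) next
      if (j %in% clusters[[i]]) next            # g(i,j) = 0
      sij <- 0
      for (k in setdiff(clusters[[j]], clusters[[i]]))
        if (R[i, k] >= T_d) sij <- sij + 1
      s <- s + wfun(R[i, j]) / sij
    }
    s
  })
}

# ICC(A,1) via aov() mean squares: independent of the vectorized formulas
icc_a1_aov <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# direct mask-normalized Gaussian summation over the truncated cubic support
smooth_oracle <- function(values, geometry, fwhm_mm) {
  sigma <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / geometry$voxel_size
  radius <- pmax(1, ceiling(4 * sigma))
  co <- geometry$coords
  out <- numeric(geometry$V)
  for (v in seq_len(geometry$V)) {
    d <- sweep(co, 2, co[v, ])
    inside <- abs(d[, 1]) <= radius[1] & abs(d[, 2]) <= radius[2] &
      abs(d[, 3]) <= radius[3]
    w <- exp(-d[inside, 1]^2 / (2 * sigma[1]^2) -
             d[inside, 2]^2 / (2 * sigma[2]^2) -
             d[inside, 3]^2 / (2 * sigma[3]^2))
    out[v] <- sum(w * values[inside]) / sum(w)
  }
  out
}

# random symmetric correlation-like matrix with unit diagonal
random_corr_matrix <- function(V, scale = 0.8) {
  A <- matrix(stats::rnorm(V * V), V)
  R <- stats::cov2cor(crossprod(A) + diag(V))   # PSD, entries in [-1, 1]
  R * scale + diag(V) * (1 - scale)
}

# random cluster map: each seed gets a random member set containing itself
random_cluster_map <- function(V, geometry, max_extra = 4) {
  clusters <- lapply(seq_len(V), function(i) {
    extra <- sample(setdiff(seq_len(V), i),
                    sample(0:min(max_extra, V - 1), 1))
    sort(c(i, extra))
  })
  rsedegree:::new_cluster_map(clusters, "combined", 0.5, geometry)
}

line_geometry <- function(V) mask_geometry(array(TRUE, c(V, 1, 1)))
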