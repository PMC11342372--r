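# Shared fixtures and independent oracle implementations used across the
# suite. Oracles deliberately share no code with the package internals.

# random structure with the given symbols: i.i.d. Gaussian coordinates,
# rescaled until clash-free (for fingerprint/energy invariance tests only)
random_structure <- function(symbols, spread = 2.5) {
  repeat {
    coords <- matrix(rnorm(length(symbols) * 3, sd = spread), ncol = 3)
    s <- mol_structure(symbols, coords)
    if (length(symbols) < 2 || min_pair_separation(s) > 0.9) return(s)
  }
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# straight-line reimplementation of the combined fingerprint distance:
# dense r-grid quadrature of the smoothed radial distribution, plain loops
oracle_fingerprint <- function(s, pair, delta = 0.2, bin_width = 0.5,
                               r_max = 8, v_uc = 512, grid_n = 2000) {
  ia <- which(s$symbols == pair[1]); ib <- which(s$symbols == pair[2])
  nbin <- round(r_max / bin_width)
  out <- numeric(nbin)
  for (b in seq_len(nbin)) {
    lo <- (b - 1) * bin_width; hi <- b * bin_width
    r_grid <- seq(lo, hi, length.out = grid_n)
    acc <- 0
    for (i in ia) for (j in ib) {
      if (pair[1] == pair[2] && i == j) next
      R <- sqrt(sum((s$coords[i, ] - s$coords[j, ])^2))
      if (R > r_max + 4 * delta) next
      g <- exp(-(r_grid - R)^2 / (2 * delta^2)) / (delta * sqrt(2 * pi))
      acc <- acc + v_uc / (4 * pi * R^2 * length(ia) * length(ib) *
                             bin_width) *
        sum((g[-1] + g[-grid_n]) / 2) * (hi - lo) / (grid_n - 1)
    }
    out[b] <- acc - 1
  }
  out
}

oracle_structure_distance <- function(s1, s2, v_uc = 512) {
  d2 <- 0
  for (pair in list(c("C", "C"), c("C", "N"))) {
    f <- lapply(list(s1, s2), function(s) {
      has <- if (pair[1] == pair[2]) sum(s$symbols == pair[1]) >= 2 else
        sum(s$symbols == pair[1]) >= 1 && sum(s$symbols == pair[2]) >= 1
      if (has) oracle_fingerprint(s, pair, v_uc = v_uc, grid_n = 400) else
        rep(-1, 16)
    })
    cosv <- sum(f[[1]] * f[[2]]) /
      sqrt(sum(f[[1]]^2)) / sqrt(sum(f[[2]]^2))
    d2 <- d2 + ((1 - cosv) / 2)^2
  }
  sqrt(d2)
}

# naive O(n^3) complete-linkage agglomeration: merge the closest pair of
# clusters (by max inter-point distance) while that distance <= threshold
oracle_complete_linkage <- function(d, threshold) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  repeat {
    k <- length(groups)
    if (k < 2) break
    best <- Inf; bi <- bj <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      link <- max(d[groups[[i]], groups[[j]]])
      if (link < best) { best <- link; bi <- i; bj <- j }
    }
    if (best > threshold) break
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  labels <- integer(n)
  for (g in seq_along(groups)) labels[groups[[g]]] <- g
  labels
}

# partitions equal up to relabelling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}

# direct transcription of the four weight-update rules for a single batch,
# independent of agent_update's implementation
oracle_weight_update <- function(weights, selections, total, bests, best_all,
                                 ids, energies, A, B, C, D, floor = 1) {
  batch_min <- which.min(energies)
  for (r in seq_along(ids)) {
    cl <- ids[r]; e <- energies[r]
    if (r == batch_min && e < best_all) weights[cl] <- weights[cl] + A
    if (e < bests[cl]) weights[cl] <- weights[cl] + B
    else weights[cl] <- weights[cl] - C
    weights[cl] <- weights[cl] - selections[cl] / total * D
  }
  touched <- unique(ids)
  weights[touched] <- pmax(weights[touched], floor)
  weights
}

# sequential transcription of the curation rules on an energy vector;
# returns the kept energies in ascending order (no padding/truncation)
oracle_curate <- function(energies, method, delta_e) {
  e <- sort(energies)
  if (method == 1) {
    keep <- sapply(seq_along(e), function(i)
      all(abs(e[-i] - e[i]) > delta_e))
    e[keep]
  } else {
    kept <- numeric(0)
    for (x in e) {
      if (length(kept) == 0 || x - kept[length(kept)] > delta_e) {
        kept <- c(kept, x)
      }
    }
    kept
  }
}

# a calculator that never moves atoms; energy from a supplied function
stub_calculator <- function(energy_fn) {
  energy_calculator(
    evaluate = energy_fn,
    relax = function(s, max_steps, force_tol) {
      s$energy <- energy_fn(s)
      s
    })
}
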