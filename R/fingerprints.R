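#' Fingerprint configuration
#'
#' Parameters of the pairwise radial-distribution fingerprint: Gaussian
#' smoothing width `delta` (A), histogram bin size `bin_width` (A), radial
#' cutoff `r_max` (A) and the scaling volume `v_uc` (A^3). `r_max` must be an
#' integral number of bins. Defaults are delta = 0.2, bin_width = 0.5,
#' r_max = 8. The scaling volume `v_uc` defaults to `r_max^3` = 512 cubic
#' Angstroms: it multiplies only the Gaussian peaks, not the -1 baseline, so
#' it sets the ratio of structural signal to baseline in the cosine
#' distance. A volume on the scale of the molecule's bounding box makes
#' typical peak weights order one and puts the distance thresholds used for
#' clustering (0.026) and lookalike detection (0.005) on their intended
#' scale; a much smaller volume drives every cosine distance toward zero.
#'
#' @param delta Gaussian kernel width in Angstroms.
#' @param bin_width histogram bin size in Angstroms.
#' @param r_max radial cutoff in Angstroms.
#' @param v_uc scaling volume in cubic Angstroms.
#' @param pairs list of length-2 character vectors naming the element pairs
#'   entering the combined structure distance; default carbon-carbon and
#'   carbon-nitrogen with hydrogen excluded as redundant.
#' @param cosine_convention `"half"` for d = (1 - cos)/2 (bounded in [0,1],
#'   the default) or `"one_minus"` for d = 1 - cos.
#' @return object of class `fp_config`.
#' @export
fingerprint_config <- function(delta = 0.2, bin_width = 0.5, r_max = 8.0,
                               v_uc = r_max^3,
                               pairs = list(c("C", "C"), c("C", "N")),
                               cosine_convention = c("half", "one_minus")) {
  if (delta <= 0 || bin_width <= 0 || r_max <= 0 || v_uc <= 0) {
    stop("delta, bin_width, r_max and v_uc must all be strictly positive")
  }
  nbins <- r_max / bin_width
  if (abs(nbins - round(nbins)) > 1e-9) {
    stop("r_max must be an integral number of bins (r_max/bin_width = ",
         nbins, ")")
  }
  cosine_convention <- match.arg(cosine_convention)
  structure(list(delta = delta, bin_width = bin_width, r_max = r_max,
                 v_uc = v_uc, n_bins = as.integer(round(nbins)),
                 pairs = pairs, cosine_convention = cosine_convention),
            class = "fp_config")
}

#' Radial-distribution fingerprint for one element pair
#'
#' For every A-B atom pair (ordered pairs i != j when A == B) at distance
#' `R_ij`, a Gaussian of width `delta` centred at `R_ij` and weighted by
#' `v_uc / (4 pi R_ij^2 N_A N_B bin_width)` is integrated over each histogram
#' bin on `[0, r_max)`; the baseline -1 is subtracted, so a bin with no
#' nearby pair tends to -1. Pairs farther than `r_max + 4*delta` are skipped:
#' beyond that their Gaussian tail contributes less than 1e-4 of its mass to
#' any bin, so truncation keeps the runtime deterministic without visible
#' effect.
#'
#' @param s a `mol_structure`.
#' @param pair length-2 character vector, e.g. `c("C","C")`.
#' @param cfg a [fingerprint_config()].
#' @return object of class `fingerprint`: list with `pair` and the numeric
#'   `values` vector (one entry per bin).
#' @export
fingerprint <- function(s, pair, cfg = fingerprint_config()) {
  stopifnot(inherits(cfg, "fp_config"), length(pair) == 2)
  a_idx <- which(s$symbols == pair[1])
  b_idx <- which(s$symbols == pair[2])
  same <- pair[1] == pair[2]
  if (length(a_idx) < 1 || length(b_idx) < 1 || (same && length(a_idx) < 2)) {
    stop("structure has no ", pair[1], "-", pair[2], " pair to fingerprint")
  }
  n_a <- length(a_idx); n_b <- length(b_idx)
  # pair distances
  if (same) {
    d <- as.matrix(stats::dist(s$coords[a_idx, , drop = FALSE]))
    rr <- d[upper.tri(d)]
    mult <- 2  # ordered pairs (i,j) and (j,i)
  } else {
    da <- s$coords[a_idx, , drop = FALSE]
    db <- s$coords[b_idx, , drop = FALSE]
    rr2 <- outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * da %*% t(db)
    rr <- as.vector(sqrt(pmax(rr2, 0)))
    mult <- 1
  }
  rr <- rr[rr <= cfg$r_max + 4 * cfg$delta]
  edges <- seq(0, cfg$r_max, by = cfg$bin_width)
  values <- rep(-1, cfg$n_bins)
  if (length(rr) > 0) {
    w <- mult * cfg$v_uc / (4 * pi * rr^2 * n_a * n_b * cfg$bin_width)
    # mass of each pair's Gaussian inside each bin (analytic CDF difference)
    lo <- matrix(edges[-length(edges)], nrow = length(rr),
                 ncol = cfg$n_bins, byrow = TRUE)
    hi <- lo + cfg$bin_width
    mass <- stats::pnorm((hi - rr) / cfg$delta) -
      stats::pnorm((lo - rr) / cfg$delta)
    values <- values + as.vector(t(mass) %*% w)
  }
  structure(list(pair = pair, values = values), class = "fingerprint")
}

#' Cosine distance between two fingerprints
#'
#' `d = (1 - cos theta) / 2` where `cos theta` is the normalised dot product
#' of the two fingerprint vectors (bounded in [0, 1]); the alternative
#' `1 - cos` convention is selected by the config's `cosine_convention`.
#'
#' @param f1,f2 `fingerprint` objects (or bare numeric vectors) over the same
#'   element pair and bin grid.
#' @param convention `"half"` or `"one_minus"`.
#' @return scalar distance.
#' @export
cosine_distance <- function(f1, f2, convention = c("half", "one_minus")) {
  convention <- match.arg(convention)
  v1 <- if (inherits(f1, "fingerprint")) f1$values else as.numeric(f1)
  v2 <- if (inherits(f2, "fingerprint")) f2$values else as.numeric(f2)
  if (inherits(f1, "fingerprint") && inherits(f2, "fingerprint") &&
      !identical(f1$pair, f2$pair)) {
    stop("fingerprints are over different element pairs")
  }
  if (length(v1) != length(v2)) stop("fingerprint lengths differ")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("cosine distance undefined for a zero vector")
  cosv <- sum(v1 * v2) / (n1 * n2)
  cosv <- max(-1, min(1, cosv))
  if (convention == "half") (1 - cosv) / 2 else 1 - cosv
}

# fingerprints of one structure for every configured pair; a missing second
# element (no A-B pair at all) yields the all-baseline (-1) vector, a
# missing *first* element is an error.
structure_fingerprints <- function(s, cfg) {
  lapply(cfg$pairs, function(pair) {
    a_n <- sum(s$symbols == pair[1])
    b_n <- sum(s$symbols == pair[2])
    same <- pair[1] == pair[2]
    enough <- if (same) a_n >= 2 else (a_n >= 1 && b_n >= 1)
    if (!enough) {
      if (a_n < 1) {
        stop("structure has no ", pair[1], " atom; cannot fingerprint")
      }
      return(structure(list(pair = pair, values = rep(-1, cfg$n_bins)),
                       class = "fingerprint"))
    }
    fingerprint(s, pair, cfg)
  })
}

#' Combined fingerprint distance between two structures
#'
#' The per-pair cosine distances (by default carbon-carbon and
#' carbon-nitrogen) are combined with equal weight by the Euclidean formula
#' `sqrt(sum(d_pair^2))`. A structure lacking the second element of a pair
#' entirely contributes the all-baseline fingerprint for that pair rather
#' than an error, so transiently nitrogen-free builder output remains
#' comparable.
#'
#' @param s1,s2 `mol_structure` objects.
#' @param cfg a [fingerprint_config()].
#' @return scalar combined distance.
#' @export
structure_distance <- function(s1, s2, cfg = fingerprint_config()) {
  f1 <- structure_fingerprints(s1, cfg)
  f2 <- structure_fingerprints(s2, cfg)
  d <- mapply(function(a, b) cosine_distance(a, b, cfg$cosine_convention),
              f1, f2)
  sqrt(sum(d^2))
}

#' Pairwise distance matrix over a structure library
#'
#' Fingerprints are computed once per structure and reused for all pairs.
#'
#' @param structures list of `mol_structure` (length >= 2).
#' @param cfg a [fingerprint_config()].
#' @return symmetric numeric matrix with zero diagonal; class
#'   `c("dist_matrix","matrix")`.
#' @export
distance_matrix <- function(structures, cfg = fingerprint_config()) {
  n <- length(structures)
  if (n < 2) stop("distance_matrix needs at least 2 structures")
  fps <- vector("list", n)
  for (i in seq_len(n)) {
    fps[[i]] <- tryCatch(structure_fingerprints(structures[[i]], cfg),
                         error = function(e) {
                           stop("structure ", i, ": ", conditionMessage(e))
                         })
  }
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- mapply(function(a, b)
        cosine_distance(a, b, cfg$cosine_convention),
        fps[[i]], fps[[j]])
      m[i, j] <- m[j, i] <- sqrt(sum(d^2))
    }
  }
  class(m) <- c("dist_matrix", "matrix")
  m
}

#' Write a distance matrix to CSV
#' @param d matrix from [distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path, row.names = FALSE)
  invisible(path)
}
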