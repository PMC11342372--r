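#' Single-bond covalent radii
#'
#' Covalent radii in Angstroms used for bond-length placement in the
#' structure builder, for the clash rule (no pair closer than 70% of the sum
#' of radii), and for the equilibrium distances of the toy pair potential.
#' Values follow the widely used single-bond compilation (C 0.76, H 0.31,
#' N 0.71, ...).
#'
#' @param symbols optional character vector of element symbols; if given,
#'   returns their radii (error on unknown elements), otherwise the full
#'   named vector.
#' @return named numeric vector of radii in Angstroms.
#' @export
#' @examples
#' covalent_radii(c("C", "H", "N"))
covalent_radii <- function(symbols = NULL) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
             P = 1.07, S = 1.05, Cl = 1.02)
  if (is.null(symbols)) return(radii)
  unknown <- setdiff(unique(symbols), names(radii))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  radii[symbols]
}

#' Molecular structure container
#'
#' A structure is the EA's unit of currency: an ordered vector of element
#' symbols, a matrix of Cartesian coordinates in Angstroms and an optional
#' total energy in eV (NA until a calculator has evaluated it).
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstroms).
#' @param energy optional scalar energy in eV.
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(symbols, coords, energy = NA_real_) {
  symbols <- as.character(symbols)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) != nrow(coords)) {
    stop("number of symbols (", length(symbols),
         ") does not match number of coordinate triples (", nrow(coords), ")")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  covalent_radii(symbols)  # validates the element symbols
  stopifnot(length(energy) == 1)
  structure(list(symbols = symbols, coords = coords,
                 energy = as.numeric(energy)),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  comp <- table(x$symbols)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat("<mol_structure> ", formula, ", ", length(x$symbols), " atoms",
      if (!is.na(x$energy)) sprintf(", energy %.4f eV", x$energy) else
        ", energy unset",
      "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `mol_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) length(s$symbols)

#' Element composition of a structure
#' @param s a `mol_structure`.
#' @return named integer vector of atom counts per element (a stoichiometry).
#' @export
composition <- function(s) {
  tab <- table(s$symbols)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# validate a stoichiometry: named non-negative counts summing > 0
check_stoichiometry <- function(stoich) {
  if (is.null(names(stoich)) || any(names(stoich) == "")) {
    stop("stoichiometry must be a named vector of element counts")
  }
  if (any(stoich < 0) || sum(stoich) <= 0) {
    stop("stoichiometry counts must be non-negative and sum to > 0")
  }
  covalent_radii(names(stoich))
  stoich[stoich > 0]
}

#' Read a multi-frame XYZ file
#'
#' Standard XYZ dialect: line 1 the atom count, line 2 a free comment line,
#' then one `Symbol x y z` line per atom; frames are concatenated. If the
#' comment line contains `energy=<float>` the frame's energy is set from it.
#'
#' @param path path to an XYZ file.
#' @return list of [mol_structure] objects, one per frame, in file order.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      stop("line ", i, ": expected an atom count, got '", lines[i], "'")
    }
    if (i + 1L + nat > length(lines)) {
      stop("line ", i, ": declared atom count ", nat,
           " exceeds remaining lines in file")
    }
    comment <- lines[i + 1L]
    energy <- NA_real_
    m <- regmatches(comment,
                    regexpr("energy=([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)",
                            comment))
    if (length(m) == 1 && nzchar(m)) {
      energy <- as.numeric(sub("^energy=", "", m))
    }
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(atom_lines), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad) > 0) {
      stop("line ", i + 1L + bad[1], ": malformed atom line '",
           atom_lines[bad[1]], "'")
    }
    symbols <- vapply(parts, `[[`, "", 1L)
    coords <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      v
    }, numeric(3)))
    if (any(!is.finite(coords))) {
      bad <- which(apply(!is.finite(coords), 1, any))[1]
      stop("line ", i + 1L + bad, ": non-numeric coordinate in '",
           atom_lines[bad], "'")
    }
    frames[[length(frames) + 1L]] <- mol_structure(symbols, coords, energy)
    i <- i + 2L + nat
  }
  frames
}

#' Write structures to a multi-frame XYZ file
#'
#' @param structures a `mol_structure` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structures, path) {
  if (inherits(structures, "mol_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    writeLines(as.character(n_atoms(s)), con)
    comment <- if (!is.na(s$energy)) sprintf("energy=%.10g", s$energy) else ""
    writeLines(comment, con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       s$symbols, s$coords[, 1], s$coords[, 2], s$coords[, 3]),
               con)
  }
  invisible(path)
}

#' Minimum interatomic separation
#'
#' @param s a `mol_structure` with at least two atoms.
#' @return the smallest Euclidean distance over all atom pairs, in Angstroms.
#' @export
min_pair_separation <- function(s) {
  if (n_atoms(s) < 2) stop("min_pair_separation needs at least 2 atoms")
  min(stats::dist(s$coords))
}

# TRUE iff every atom pair is separated by at least
# frac * (sum of the pair's covalent radii)
clash_free <- function(symbols, coords, frac = 0.70) {
  n <- length(symbols)
  if (n < 2) return(TRUE)
  r <- covalent_radii(symbols)
  d <- as.matrix(stats::dist(coords))
  lim <- frac * outer(r, r, `+`)
  all(d[upper.tri(d)] >= lim[upper.tri(lim)])
}

# unit vectors of the canonical attachment geometries
hybridization_directions <- function(hyb) {
  switch(hyb,
    sp = rbind(c(1, 0, 0), c(-1, 0, 0)),
    sp2 = rbind(c(1, 0, 0),
                c(-0.5, sqrt(3) / 2, 0),
                c(-0.5, -sqrt(3) / 2, 0)),
    sp3 = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3),
    terminal = matrix(c(1, 0, 0), nrow = 1),
    stop("unknown hybridization: ", hyb))
}

# uniform random 3x3 rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a random molecular structure atom by atom
#'
#' Emulates an atom-by-atom builder: atoms are drawn in random order from the
#' requested stoichiometry; each new atom is attached to a randomly chosen
#' open attachment site of an already placed atom, at a distance equal to the
#' sum of the two covalent radii. Carbon and nitrogen are assigned sp, sp2 or
#' sp3 hybridization (sampled from `hyb_weights`), which fixes their
#' attachment-site geometry (180 deg linear / 120 deg trigonal planar /
#' 109.47 deg tetrahedral, randomly oriented); hydrogen is terminal. After
#' every placement the clash rule is checked: if any pair of atoms is closer
#' than 70% of the sum of their covalent radii, the whole build restarts.
#' This is a deliberately simplified generator of diverse, chemically
#' plausible input libraries, not a faithful chemistry engine.
#'
#' @param stoich named integer vector, e.g. `c(C = 9, H = 7, N = 1)`.
#' @param hyb_weights named list mapping element to a named probability
#'   vector over `c("sp","sp2","sp3")`; defaults to equal weights for every
#'   non-hydrogen element.
#' @param max_restarts maximum number of full restarts before giving up.
#' @param clash_frac clash-rule fraction of the covalent-radius sum
#'   (default 0.70).
#' @return a `mol_structure` with the requested stoichiometry, energy unset.
#' @export
#' @examples
#' set.seed(1)
#' s <- build_structure(c(C = 9, H = 7, N = 1))
#' composition(s)
build_structure <- function(stoich, hyb_weights = NULL, max_restarts = 200L,
                            clash_frac = 0.70) {
  stoich <- check_stoichiometry(stoich)
  if (max_restarts < 1) stop("max_restarts must be >= 1")
  radii <- covalent_radii(names(stoich))
  hybs <- c("sp", "sp2", "sp3")
  pick_hyb <- function(el) {
    if (el == "H") return("terminal")
    w <- hyb_weights[[el]]
    if (is.null(w)) w <- stats::setNames(rep(1 / 3, 3), hybs)
    if (abs(sum(w) - 1) > 1e-8) stop("hyb_weights for ", el, " must sum to 1")
    sample(names(w), 1, prob = w)
  }
  atom_list <- rep(names(stoich), stoich)
  n <- length(atom_list)

  for (attempt in seq_len(max_restarts)) {
    order_ <- sample(atom_list)
    symbols <- character(0)
    coords <- matrix(numeric(0), ncol = 3)
    # open attachment sites: list of (atom index, unit direction)
    site_atom <- integer(0)
    site_dir <- matrix(numeric(0), ncol = 3)
    ok <- TRUE
    for (k in seq_len(n)) {
      el <- order_[k]
      hyb <- pick_hyb(el)
      dirs <- hybridization_directions(hyb) %*% t(random_rotation())
      if (k == 1L) {
        pos <- c(0, 0, 0)
        new_dirs <- dirs
      } else {
        if (length(site_atom) == 0) { ok <- FALSE; break }
        si <- if (length(site_atom) == 1) 1L else
          sample(length(site_atom), 1)
        anchor <- site_atom[si]
        dir <- site_dir[si, ]
        bond <- covalent_radii(symbols[anchor]) + covalent_radii(el)
        pos <- coords[anchor, ] + bond * dir
        site_atom <- site_atom[-si]
        site_dir <- site_dir[-si, , drop = FALSE]
        # the new atom's first site points back along the bond; drop it
        # and orient the rest away from the anchor
        back <- -dir
        rot <- rotation_onto(dirs[1, ], back)
        dirs <- dirs %*% t(rot)
        new_dirs <- dirs[-1, , drop = FALSE]
      }
      symbols <- c(symbols, el)
      coords <- rbind(coords, pos)
      if (!clash_free(symbols, coords, clash_frac)) { ok <- FALSE; break }
      if (nrow(new_dirs) > 0) {
        site_atom <- c(site_atom, rep(length(symbols), nrow(new_dirs)))
        site_dir <- rbind(site_dir, new_dirs)
      }
    }
    if (ok) {
      rownames(coords) <- NULL
      return(mol_structure(symbols, coords))
    }
  }
  stop("build_structure: failed to place ", n, " atoms within ",
       max_restarts, " restarts")
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_onto <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- axis - sum(axis * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Build a synthetic structure library
#'
#' Convenience wrapper calling [build_structure()] `n` times.
#'
#' @param n number of structures.
#' @param stoich stoichiometry passed to [build_structure()].
#' @param ... further arguments to [build_structure()].
#' @return list of `mol_structure`.
#' @export
build_library <- function(n, stoich = c(C = 9, H = 7, N = 1), ...) {
  lapply(seq_len(n), function(i) build_structure(stoich, ...))
}

# ---- toy Morse pair potential -------------------------------------------

# per-element Morse well depths (eV); pair depth = sqrt(D_i * D_j);
# equilibrium distance = sum of covalent radii; stiffness a = 1.7 / Angstrom.
morse_depths <- c(H = 2.1, C = 3.6, N = 3.4, O = 3.2, F = 2.8,
                  P = 3.0, S = 3.1, Cl = 2.9)
morse_a <- 1.7

#' Toy pairwise Morse energy
#'
#' A deterministic stand-in energy model for desk-scale experiments:
#' the sum over all atom pairs of a Morse term
#' `D_ij * ((1 - exp(-a (r - r_ij)))^2 - 1)` with pair well depth
#' `D_ij = sqrt(D_i D_j)` (depths per element documented in the source),
#' equilibrium distance `r_ij` equal to the sum of the pair's covalent radii,
#' and stiffness `a = 1.7` per Angstrom. Compact clash-free structures score
#' lower than sprawled or clashing ones; the function is exactly invariant
#' under atom permutation and rigid motion. A C-C dimer at its equilibrium
#' separation of 1.52 Angstroms has energy -3.6 eV.
#'
#' @param s a `mol_structure` with at least one atom.
#' @return total energy in eV.
#' @export
toy_energy <- function(s) {
  n <- n_atoms(s)
  if (n < 1) stop("toy_energy needs at least 1 atom")
  if (n == 1) return(0)
  d <- covalent_radii(s$symbols)
  depth <- sqrt(outer(morse_depths[s$symbols], morse_depths[s$symbols]))
  r_eq <- outer(d, d, `+`)
  r <- as.matrix(stats::dist(s$coords))
  ut <- upper.tri(r)
  x <- 1 - exp(-morse_a * (r[ut] - r_eq[ut]))
  sum(depth[ut] * (x^2 - 1))
}

# analytic gradient of toy_energy wrt coordinates (n x 3 matrix, eV/Angstrom)
toy_gradient <- function(s) {
  n <- n_atoms(s)
  if (n < 2) return(matrix(0, n, 3))
  d <- covalent_radii(s$symbols)
  dep <- sqrt(morse_depths[s$symbols])
  r <- as.matrix(stats::dist(s$coords))
  r_eq <- outer(d, d, `+`)
  e <- exp(-morse_a * (r - r_eq))
  # dE/dr = 2 D a e (1 - e); grad_i = sum_j (dEdr/r)_ij (x_i - x_j)
  w <- 2 * outer(dep, dep) * morse_a * e * (1 - e) / r
  diag(w) <- 0
  rowSums(w) * s$coords - w %*% s$coords
}

#' Energy-calculator contract
#'
#' A calculator is a list with two functions: `evaluate(s)` returning the
#' energy of a structure in eV (deterministic for a fixed geometry), and
#' `relax(s, max_steps, force_tol)` returning a locally quenched structure
#' with its energy set, guaranteed never to exceed the input energy.
#' Quantum-chemical backends can be plugged in by supplying any list with
#' this shape; [toy_calculator()] provides the packaged Morse toy model.
#'
#' @param evaluate function `mol_structure -> numeric`.
#' @param relax function `(mol_structure, max_steps, force_tol) ->
#'   mol_structure`.
#' @return object of class `energy_calculator`.
#' @export
energy_calculator <- function(evaluate, relax) {
  stopifnot(is.function(evaluate), is.function(relax))
  structure(list(evaluate = evaluate, relax = relax),
            class = "energy_calculator")
}

#' Toy Morse calculator
#'
#' Packages [toy_energy()] and a steepest-descent quench into the
#' [energy_calculator()] contract. The quench takes capped steepest-descent
#' steps (initial step scale 0.05 A per unit force, displacement capped at
#' 0.2 A, step halved on uphill moves) and stops after `max_steps` steps or
#' when the largest atomic force falls below `force_tol`, mirroring the
#' dual 100-step / 0.05 eV/A stopping rule used with tight-binding quenches.
#' Only energy-lowering steps are accepted, so relaxation never increases
#' the energy.
#'
#' @return an `energy_calculator`.
#' @export
toy_calculator <- function() {
  relax <- function(s, max_steps = 100L, force_tol = 0.05) {
    e <- toy_energy(s)
    alpha <- 0.05
    for (step in seq_len(max_steps)) {
      g <- toy_gradient(s)
      fmax <- sqrt(max(rowSums(g^2)))
      if (fmax <= force_tol) break
      accepted <- FALSE
      a <- alpha
      for (try in 1:8) {
        disp <- -a * g
        dmax <- sqrt(max(rowSums(disp^2)))
        if (dmax > 0.2) disp <- disp * (0.2 / dmax)
        cand <- s
        cand$coords <- s$coords + disp
        e_new <- toy_energy(cand)
        if (e_new < e) {
          s <- cand; e <- e_new; accepted <- TRUE
          alpha <- min(a * 1.2, 0.2)
          break
        }
        a <- a / 2
      }
      if (!accepted) break
    }
    s$energy <- e
    s
  }
  energy_calculator(evaluate = toy_energy, relax = relax)
}
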