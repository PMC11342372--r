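#' Fitness of a population member
#'
#' The half-tanh fitness `F = (1 - tanh(2*rho - 1)) / 2` with
#' `rho = (E - E_lo) / (E_hi - E_lo)`, where `E_lo` and `E_hi` are the
#' minimum and maximum energy in the population. Strictly decreasing in E,
#' bounded in (0, 1). A degenerate population (`E_hi == E_lo`) gets
#' `F = 0.5` for every member.
#'
#' @param E energy (eV); vectorised.
#' @param e_lo,e_hi population minimum and maximum energy.
#' @return fitness value(s) in (0, 1).
#' @export
fitness <- function(E, e_lo, e_hi) {
  if (e_hi < e_lo) stop("e_hi must be >= e_lo")
  if (e_hi == e_lo) return(rep(0.5, length(E)))
  rho <- (E - e_lo) / (e_hi - e_lo)
  (1 - tanh(2 * rho - 1)) / 2
}

#' Uniqueness factor of a population member
#'
#' `U = 1 / sqrt(1 + n) * 1 / sqrt(1 + m)`, where `n` counts how many times
#' the member has participated in a pairing and `m` counts structural
#' lookalikes encountered but not admitted to the population. U(0,0) = 1 and
#' U tends to zero as either count grows, steering selection away from
#' over-used or over-represented members.
#'
#' @param n_pair pairing count(s), >= 0; vectorised.
#' @param m_lookalike lookalike count(s), >= 0.
#' @return uniqueness value(s) in (0, 1].
#' @export
uniqueness <- function(n_pair, m_lookalike = 0) {
  if (any(n_pair < 0) || any(m_lookalike < 0)) {
    stop("uniqueness counts must be >= 0")
  }
  1 / sqrt(1 + n_pair) / sqrt(1 + m_lookalike)
}

#' EA population container
#'
#' Holds structures with energies set, sorted ascending by energy, together
#' with per-member pairing counts `n_pair` and lookalike counts
#' `m_lookalike`. `capacity` bounds the size for swap-only (fixed-size)
#' evolution; `capacity = Inf` gives a growing population.
#'
#' @param structures list of `mol_structure`, all with finite energies.
#' @param capacity maximum size.
#' @return object of class `ea_population`.
#' @export
new_population <- function(structures, capacity = length(structures)) {
  e <- vapply(structures, function(s) s$energy, numeric(1))
  if (any(!is.finite(e))) {
    stop("all population members need finite energies; evaluate them first")
  }
  if (length(structures) > capacity) stop("more members than capacity")
  o <- order(e)
  structure(list(members = structures[o], energies = e[o],
                 n_pair = integer(length(e)),
                 m_lookalike = integer(length(e)),
                 capacity = capacity),
            class = "ea_population")
}

#' @export
print.ea_population <- function(x, ...) {
  cat("<ea_population> ", length(x$members), " members",
      if (is.finite(x$capacity)) paste0(" (capacity ", x$capacity, ")"),
      sprintf(", energies [%.4f, %.4f] eV\n",
              min(x$energies), max(x$energies)), sep = "")
  invisible(x)
}

#' Selection weights F * U of a population
#' @param pop an `ea_population`.
#' @return numeric vector proportional to selection probabilities.
#' @export
selection_weights <- function(pop) {
  f <- fitness(pop$energies, min(pop$energies), max(pop$energies))
  u <- uniqueness(pop$n_pair, pop$m_lookalike)
  f * u
}

#' Select two distinct parents
#'
#' Draws two distinct members with probability proportional to
#' `F_i * U_i` (renormalised) and increments both parents' pairing counts.
#'
#' @param pop an `ea_population` with >= 2 members.
#' @param weights optional replacement weight vector (diagnostics /
#'   testing); defaults to [selection_weights()].
#' @return list with `parents` (indices), `structures` (the two parents)
#'   and the updated `pop`.
#' @export
select_parents <- function(pop, weights = NULL) {
  n <- length(pop$members)
  if (n < 2) stop("parent selection needs at least 2 members")
  w <- if (is.null(weights)) selection_weights(pop) else weights
  if (length(w) != n || any(w < 0) || sum(w > 0) < 2) {
    stop("invalid selection weights")
  }
  idx <- sample.int(n, 2, replace = FALSE, prob = w)
  pop$n_pair[idx] <- pop$n_pair[idx] + 1L
  list(parents = idx,
       structures = pop$members[idx],
       pop = pop)
}

#' Cut-and-splice crossover with stoichiometry repair
#'
#' Both parents are centred on their centroid so their centres coincide; a
#' randomly oriented plane through that common centre divides space, and the
#' child takes parent 1's atoms from one side and parent 2's from the
#' other. Stoichiometry repair: for an element in surplus, the child atoms
#' of that element farthest from the dividing plane are removed; for an
#' element in deficit, unused parent atoms of that element are added at
#' random. The child must satisfy the minimum-separation rule (no pair
#' closer than `min_sep_frac` times the covalent-radius sum); a clashing
#' child is rejected and the whole process restarts with a new random
#' plane, up to `max_retries` times, after which a classed
#' `crossover_failure` error is signalled (EA drivers count the iteration
#' as failed and continue).
#'
#' @param p1,p2 parent `mol_structure`s with the target stoichiometry.
#' @param target named integer stoichiometry; defaults to parent 1's
#'   composition.
#' @param min_sep_frac clash fraction (default 0.70).
#' @param max_retries plane re-draws before giving up.
#' @return a child `mol_structure` (energy unset).
#' @export
cut_and_splice <- function(p1, p2, target = composition(p1),
                           min_sep_frac = 0.70, max_retries = 50L) {
  target <- check_stoichiometry(target)
  if (max_retries < 1) stop("max_retries must be >= 1")
  c1 <- sweep(p1$coords, 2, colMeans(p1$coords))
  c2 <- sweep(p2$coords, 2, colMeans(p2$coords))
  for (try in seq_len(max_retries)) {
    nrm <- stats::rnorm(3)
    nrm <- nrm / sqrt(sum(nrm^2))
    proj1 <- as.vector(c1 %*% nrm)
    proj2 <- as.vector(c2 %*% nrm)
    keep1 <- proj1 >= 0
    keep2 <- proj2 < 0
    symbols <- c(p1$symbols[keep1], p2$symbols[keep2])
    coords <- rbind(c1[keep1, , drop = FALSE], c2[keep2, , drop = FALSE])
    projs <- c(proj1[keep1], proj2[keep2])
    # unused parent atoms, available to fill deficits
    spare_symbols <- c(p1$symbols[!keep1], p2$symbols[!keep2])
    spare_coords <- rbind(c1[!keep1, , drop = FALSE],
                          c2[!keep2, , drop = FALSE])
    spare_projs <- c(proj1[!keep1], proj2[!keep2])
    ok <- TRUE
    for (el in names(target)) {
      have <- which(symbols == el)
      want <- target[[el]]
      if (length(have) > want) {
        # drop the surplus atoms farthest from the dividing plane
        drop_ <- have[order(-abs(projs[have]))][seq_len(length(have) - want)]
        symbols <- symbols[-drop_]
        coords <- coords[-drop_, , drop = FALSE]
        projs <- projs[-drop_]
      } else if (length(have) < want) {
        pool <- which(spare_symbols == el)
        need <- want - length(have)
        if (length(pool) < need) { ok <- FALSE; break }
        add <- if (length(pool) == 1) pool else sample(pool, need)
        add <- add[seq_len(need)]
        symbols <- c(symbols, spare_symbols[add])
        coords <- rbind(coords, spare_coords[add, , drop = FALSE])
        projs <- c(projs, spare_projs[add])
        spare_symbols <- spare_symbols[-add]
        spare_coords <- spare_coords[-add, , drop = FALSE]
        spare_projs <- spare_projs[-add]
      }
    }
    extra <- setdiff(unique(symbols), names(target))
    if (length(extra) > 0) stop("parents contain elements outside target")
    if (ok && length(symbols) > 1 &&
        clash_free(symbols, coords, min_sep_frac)) {
      return(mol_structure(symbols, coords))
    }
  }
  stop(structure(class = c("crossover_failure", "error", "condition"),
                 list(message = paste0("cut_and_splice: no clash-free child",
                                       " within ", max_retries, " retries"),
                      call = sys.call(-1))))
}

#' EA driver configuration
#'
#' @param iters_per_run EA iterations per cluster selection (default 50).
#' @param n_selections cluster-selection budget of the clustered driver
#'   (default 100, so the total iteration budget matches an unclustered
#'   5000-iteration run).
#' @param min_sep_frac offspring clash fraction (default 0.70).
#' @param relax_max_steps quench step cap (default 100).
#' @param force_tol quench force tolerance in eV/A (default 0.05).
#' @param crossover_retries plane redraws per crossover attempt.
#' @param lookalike_threshold combined fingerprint distance below which an
#'   offspring counts as a lookalike of an existing member (rejected, and
#'   the member's m count incremented); 0 disables the check.
#' @param fp_config fingerprint configuration for the lookalike check.
#' @return object of class `ea_config`.
#' @export
ea_config <- function(iters_per_run = 50L, n_selections = 100L,
                      min_sep_frac = 0.70, relax_max_steps = 100L,
                      force_tol = 0.05, crossover_retries = 50L,
                      lookalike_threshold = 0.005,
                      fp_config = fingerprint_config()) {
  if (iters_per_run < 1 || n_selections < 1 || relax_max_steps < 1) {
    stop("ea_config counts must be >= 1")
  }
  structure(list(iters_per_run = as.integer(iters_per_run),
                 n_selections = as.integer(n_selections),
                 min_sep_frac = min_sep_frac,
                 relax_max_steps = as.integer(relax_max_steps),
                 force_tol = force_tol,
                 crossover_retries = as.integer(crossover_retries),
                 lookalike_threshold = lookalike_threshold,
                 fp_config = fp_config),
            class = "ea_config")
}

#' Run a fixed-size (swap-only) EA on one population
#'
#' One iteration = select two parents, create a child by cut-and-splice,
#' quench it with the calculator, and compare it with the current
#' population: a child strictly below the weakest member's energy replaces
#' that member, otherwise it is rejected. A child within the lookalike
#' distance of an existing member is rejected and that member's m count
#' incremented. Crossover or calculator failures count as (failed)
#' iterations. The best member's energy never worsens and the population
#' size is constant.
#'
#' @param pop an `ea_population`.
#' @param calc an [energy_calculator()].
#' @param n_iter number of iterations.
#' @param cfg an [ea_config()].
#' @return list with the final `pop`, `offspring` (list of evaluated
#'   offspring structures, including rejected ones) and `offspring_energies`.
#' @export
ea_run <- function(pop, calc, n_iter, cfg = ea_config()) {
  offspring <- list()
  energies <- numeric(0)
  if (n_iter >= 1 && length(pop$members) >= 2) {
    member_fps <- NULL
    if (cfg$lookalike_threshold > 0) {
      member_fps <- lapply(pop$members, structure_fingerprints,
                           cfg = cfg$fp_config)
    }
    for (it in seq_len(n_iter)) {
      sel <- select_parents(pop)
      pop <- sel$pop
      child <- tryCatch(
        cut_and_splice(sel$structures[[1]], sel$structures[[2]],
                       min_sep_frac = cfg$min_sep_frac,
                       max_retries = cfg$crossover_retries),
        crossover_failure = function(e) NULL)
      if (is.null(child)) next
      child <- tryCatch(
        calc$relax(child, cfg$relax_max_steps, cfg$force_tol),
        error = function(e) {
          warning("calculator failed on a candidate: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(child) || !is.finite(child$energy)) next
      offspring[[length(offspring) + 1L]] <- child
      energies <- c(energies, child$energy)
      # lookalike rejection
      if (cfg$lookalike_threshold > 0) {
        child_fp <- structure_fingerprints(child, cfg$fp_config)
        dists <- vapply(member_fps, function(f)
          sqrt(sum(mapply(function(a, b)
            cosine_distance(a, b, cfg$fp_config$cosine_convention),
            child_fp, f)^2)), numeric(1))
        near <- which(dists < cfg$lookalike_threshold)
        if (length(near) > 0) {
          pop$m_lookalike[near[1]] <- pop$m_lookalike[near[1]] + 1L
          next
        }
      }
      weakest <- length(pop$members)  # sorted ascending
      if (child$energy < pop$energies[weakest]) {
        pop$members[[weakest]] <- child
        pop$energies[weakest] <- child$energy
        pop$n_pair[weakest] <- 0L
        pop$m_lookalike[weakest] <- 0L
        o <- order(pop$energies)
        pop$members <- pop$members[o]
        pop$energies <- pop$energies[o]
        pop$n_pair <- pop$n_pair[o]
        pop$m_lookalike <- pop$m_lookalike[o]
        if (cfg$lookalike_threshold > 0) {
          member_fps[[weakest]] <- child_fp
          member_fps <- member_fps[o]
        }
      }
    }
  }
  list(pop = pop, offspring = offspring, offspring_energies = energies)
}

#' Parent-curation configuration
#'
#' All three curation methods impose an energy threshold `delta_e` to keep
#' near-duplicate energies out of the next parent population and delay
#' premature convergence:
#' * method 1: a molecule is kept only if *no other* pool molecule has an
#'   energy within `delta_e` of it;
#' * method 2: scanning upward in energy, a molecule is kept only if it
#'   exceeds the last kept energy by more than `delta_e` (pool = previous
#'   run's offspring plus previous parents);
#' * method 3: method 2's rule applied to the pool of *all* offspring that
#'   cluster has ever produced plus the previous parents.
#'
#' @param method 1, 2 or 3.
#' @param delta_e energy threshold in eV (> 0).
#' @param target_size parent population size (default 20).
#' @return object of class `curation_config`.
#' @export
curation_config <- function(method = 1L, delta_e = 0.3, target_size = 20L) {
  if (!method %in% 1:3) stop("curation method must be 1, 2 or 3")
  if (delta_e <= 0) stop("delta_e must be > 0")
  if (target_size < 2) stop("target_size must be >= 2")
  structure(list(method = as.integer(method), delta_e = delta_e,
                 target_size = as.integer(target_size)),
            class = "curation_config")
}

#' Curate the next parent population under the energy-threshold rule
#'
#' Applies the configured method to the pooled candidates (see
#' [curation_config()]). Kept molecules are returned lowest-energy first,
#' truncated to `target_size`; if fewer than `target_size` survive the rule
#' (typical for method 3 early on, or for large `delta_e`), the list is
#' padded with the lowest-energy excluded candidates so the population size
#' stays fixed.
#'
#' @param pool list of `mol_structure` with finite energies (offspring and
#'   previous parents, per the method's definition).
#' @param cfg a [curation_config()].
#' @return list of `mol_structure`, at most `target_size` long.
#' @export
curate_parents <- function(pool, cfg) {
  stopifnot(inherits(cfg, "curation_config"))
  if (length(pool) == 0) stop("curation pool is empty")
  e <- vapply(pool, function(s) s$energy, numeric(1))
  if (any(!is.finite(e))) stop("curation pool has members without energies")
  o <- order(e)
  pool <- pool[o]; e <- e[o]
  if (cfg$method == 1L) {
    keep <- vapply(seq_along(e), function(i)
      !any(abs(e[-i] - e[i]) <= cfg$delta_e), logical(1))
  } else {
    keep <- logical(length(e))
    last <- -Inf
    for (i in seq_along(e)) {
      if (e[i] - last > cfg$delta_e) {
        keep[i] <- TRUE
        last <- e[i]
      }
    }
  }
  kept <- which(keep)
  if (length(kept) > cfg$target_size) kept <- kept[seq_len(cfg$target_size)]
  if (length(kept) < cfg$target_size) {
    pad <- setdiff(seq_along(e), kept)
    pad <- pad[seq_len(min(length(pad), cfg$target_size - length(kept)))]
    kept <- sort(c(kept, pad))
  }
  pool[kept]
}

# evaluate library members lacking energies (with optional quench)
ensure_energies <- function(structures, calc, cfg, relax = TRUE) {
  lapply(structures, function(s) {
    if (is.finite(s$energy)) return(s)
    if (relax) {
      calc$relax(s, cfg$relax_max_steps, cfg$force_tol)
    } else {
      s$energy <- calc$evaluate(s)
      s
    }
  })
}

#' Clustered, agent-driven evolutionary algorithm
#'
#' The full dynamic cluster-selection search: `target_size` parents are
#' sampled from each cluster (and quenched if their energies are unset); a
#' fresh agent is initialised over the clusters; then for up to
#' `cfg$n_selections` selections the agent picks one cluster, a swap-only
#' [ea_run()] of `cfg$iters_per_run` iterations runs on that cluster's
#' current parents, the agent is updated with the run's minimum offspring
#' energy, and the cluster's next parents are curated per `cur`. With the
#' defaults (100 selections x 50 iterations) the total iteration budget
#' matches a 5000-iteration unclustered run. The search stops early when an
#' offspring's energy falls below `e_success`.
#'
#' @param clusters list of structure lists, one per cluster, each with at
#'   least `cur$target_size` members.
#' @param params a [learning_params()].
#' @param cur a [curation_config()].
#' @param calc an [energy_calculator()].
#' @param cfg an [ea_config()].
#' @param e_success optional success threshold in eV (-Inf disables early
#'   stopping).
#' @return object of class `clustered_ea_record`: list with per-selection
#'   `log` (data.frame: selection, cluster, run_min, best_so_far),
#'   `weights` matrix (one row per selection), `success_iteration` (NA if
#'   never reached), `best_energy`, `best_structure` and the final `agent`.
#' @export
clustered_ea <- function(clusters, params, cur, calc, cfg = ea_config(),
                         e_success = -Inf) {
  n_cl <- length(clusters)
  if (n_cl < 1) stop("need at least one cluster")
  sizes <- vapply(clusters, length, 0L)
  if (any(sizes < cur$target_size)) {
    stop("every cluster needs at least target_size members")
  }
  parents <- lapply(clusters, function(cl) {
    picked <- cl[sample.int(length(cl), cur$target_size)]
    ensure_energies(picked, calc, cfg)
  })
  all_offspring <- vector("list", n_cl)  # for curation method 3
  state <- init_agent(n_cl)
  best_energy <- Inf
  best_structure <- NULL
  for (cl in parents) {
    for (s in cl) {
      if (s$energy < best_energy) { best_energy <- s$energy
        best_structure <- s }
    }
  }
  log_sel <- integer(0); log_cluster <- integer(0)
  log_min <- numeric(0); log_best <- numeric(0)
  weights_trace <- matrix(numeric(0), ncol = n_cl)
  success_iteration <- NA_integer_
  for (s_idx in seq_len(cfg$n_selections)) {
    sel <- agent_select(state, 1L)
    state <- sel$state
    cl <- sel$ids[1]
    pop <- new_population(parents[[cl]], capacity = cur$target_size)
    res <- ea_run(pop, calc, cfg$iters_per_run, cfg)
    run_min <- if (length(res$offspring_energies) > 0)
      min(res$offspring_energies) else Inf
    state <- agent_update(state, cl, run_min, params)
    if (run_min < best_energy) {
      best_energy <- run_min
      best_structure <- res$offspring[[which.min(res$offspring_energies)]]
    }
    log_sel <- c(log_sel, s_idx); log_cluster <- c(log_cluster, cl)
    log_min <- c(log_min, run_min); log_best <- c(log_best, best_energy)
    weights_trace <- rbind(weights_trace, state$weights)
    all_offspring[[cl]] <- c(all_offspring[[cl]], res$offspring)
    pool <- if (cur$method == 3L) {
      c(all_offspring[[cl]], parents[[cl]])
    } else {
      c(res$offspring, parents[[cl]])
    }
    if (length(pool) > 0) {
      parents[[cl]] <- curate_parents(pool, cur)
    }
    hit <- which(res$offspring_energies < e_success)
    if (length(hit) > 0) {
      success_iteration <- (s_idx - 1L) * cfg$iters_per_run +
        as.integer(hit[1])
      break
    }
  }
  structure(list(log = data.frame(selection = log_sel, cluster = log_cluster,
                                  run_min = log_min,
                                  best_so_far = log_best),
                 weights = weights_trace,
                 success_iteration = success_iteration,
                 best_energy = best_energy,
                 best_structure = best_structure,
                 agent = state),
            class = "clustered_ea_record")
}

#' @export
print.clustered_ea_record <- function(x, ...) {
  cat("<clustered_ea_record> ", nrow(x$log), " cluster selections, best ",
      sprintf("%.4f eV", x$best_energy),
      if (!is.na(x$success_iteration))
        paste0(", success at iteration ", x$success_iteration), "\n",
      sep = "")
  invisible(x)
}

#' Unclustered baseline evolutionary algorithm
#'
#' The whole library forms one growing parent population: every offspring
#' produced (after quenching) is appended and can be drawn from in later
#' iterations. Selection uses the same fitness-times-uniqueness rule as the
#' clustered driver. The running minimum per iteration is logged.
#'
#' @param library list of `mol_structure`; unset energies are quenched
#'   first.
#' @param calc an [energy_calculator()].
#' @param n_iter number of iterations.
#' @param cfg an [ea_config()].
#' @return list with `best_energy`, `best_structure`, `running_min`
#'   (numeric vector, one entry per iteration) and the final population
#'   size `n_members`.
#' @export
unclustered_ea <- function(library, calc, n_iter, cfg = ea_config()) {
  if (length(library) < 2) stop("library must have at least 2 structures")
  members <- ensure_energies(library, calc, cfg)
  energies <- vapply(members, function(s) s$energy, numeric(1))
  n_pair <- integer(length(members))
  best <- min(energies)
  best_structure <- members[[which.min(energies)]]
  running_min <- numeric(0)
  for (it in seq_len(n_iter)) {
    f <- fitness(energies, min(energies), max(energies))
    w <- f * uniqueness(n_pair)
    idx <- sample.int(length(members), 2, prob = w)
    n_pair[idx] <- n_pair[idx] + 1L
    child <- tryCatch(
      cut_and_splice(members[[idx[1]]], members[[idx[2]]],
                     min_sep_frac = cfg$min_sep_frac,
                     max_retries = cfg$crossover_retries),
      crossover_failure = function(e) NULL)
    if (!is.null(child)) {
      child <- tryCatch(calc$relax(child, cfg$relax_max_steps, cfg$force_tol),
                        error = function(e) NULL)
    }
    if (!is.null(child) && is.finite(child$energy)) {
      members[[length(members) + 1L]] <- child
      energies <- c(energies, child$energy)
      n_pair <- c(n_pair, 0L)
      if (child$energy < best) {
        best <- child$energy
        best_structure <- child
      }
    }
    running_min <- c(running_min, best)
  }
  list(best_energy = best, best_structure = best_structure,
       running_min = running_min, n_members = length(members))
}

#' Random-search baseline
#'
#' Iteration-matched control for the EA drivers: each iteration builds one
#' fresh structure with [build_structure()], quenches it and records the
#' energy; the best energy seen is tracked.
#'
#' @param n_iter number of iterations.
#' @param stoich stoichiometry for the builder.
#' @param calc an [energy_calculator()].
#' @param cfg an [ea_config()] (for the quench settings).
#' @param ... further arguments to [build_structure()].
#' @return list with `best_energy`, `best_structure` and `running_min`.
#' @export
random_search <- function(n_iter, stoich, calc, cfg = ea_config(), ...) {
  best <- Inf; best_structure <- NULL
  running_min <- numeric(0)
  for (it in seq_len(n_iter)) {
    s <- tryCatch(build_structure(stoich, ...), error = function(e) NULL)
    if (!is.null(s)) {
      s <- tryCatch(calc$relax(s, cfg$relax_max_steps, cfg$force_tol),
                    error = function(e) NULL)
    }
    if (!is.null(s) && is.finite(s$energy) && s$energy < best) {
      best <- s$energy
      best_structure <- s
    }
    running_min <- c(running_min, best)
  }
  list(best_energy = best, best_structure = best_structure,
       running_min = running_min)
}
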