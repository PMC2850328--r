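# Stochastic population simulator of modular replicators. Entities carry
# a symbol vector of length I over an inventory of size A; a variable
# index set may change during lifetime (probability upsilon per module
# per generation) and its heritable subset is copied to offspring with
# per-module error mu. The non-heritable variable part of an offspring is
# not copied: it is rebuilt ("developed") to the parent's birth state.
# Miscopy targets are uniform over the A - 1 non-current symbols, so the
# realized backmutation probability is 1/(A-1), matching
# default_epsilon() with no free parameter.

# uniformly resample each flagged position to a *different* symbol in 1..A
resample_different <- function(x, flip, A) {
  n <- sum(flip)
  if (n == 0L) return(x)
  x[flip] <- ((x[flip] - 1L + sample.int(A - 1L, n, replace = TRUE)) %% A) + 1L
  x
}

#' A single modular entity
#'
#' @param features integer vector of symbols in `1..A`, length `I`.
#' @param variable_idx indices of the variable part.
#' @param heritable_idx indices of the heritable part (subset of
#'   `variable_idx`).
#' @param A inventory size.
#' @param birth_features the entity's features at its creation; defaults
#'   to `features` (a newborn).
#' @param id,birth_time bookkeeping fields.
#' @return An object of class `modular_entity`.
#' @export
modular_entity <- function(features, variable_idx, heritable_idx, A,
                           birth_features = features, id = "e1",
                           birth_time = 0) {
  features <- as.integer(features)
  variable_idx <- sort(unique(as.integer(variable_idx)))
  heritable_idx <- sort(unique(as.integer(heritable_idx)))
  stopifnot(all(features >= 1L), all(features <= A),
            length(birth_features) == length(features))
  if (!all(heritable_idx %in% variable_idx))
    stop("heritable_idx must be a subset of variable_idx")
  if (length(variable_idx) && max(variable_idx) > length(features))
    stop("variable_idx out of range")
  fixed <- setdiff(seq_along(features), variable_idx)
  if (any(features[fixed] != as.integer(birth_features)[fixed]))
    stop("features may differ from birth_features only at variable indices")
  structure(list(id = id, features = features,
                 birth_features = as.integer(birth_features),
                 variable_idx = variable_idx, heritable_idx = heritable_idx,
                 A = as.integer(A), birth_time = birth_time),
            class = "modular_entity")
}

#' Lifetime change of the variable part
#'
#' Each module of the variable part independently changes to a uniformly
#' chosen different symbol with probability `upsilon`; all other modules
#' are untouched (modularity: changes leave the entity functional).
#'
#' @param entity a [modular_entity()].
#' @param upsilon per-module change probability over one
#'   inter-replication interval.
#' @return The mutated entity (birth snapshot unchanged).
#' @export
mutate_lifetime <- function(entity, upsilon) {
  stopifnot(inherits(entity, "modular_entity"))
  vi <- entity$variable_idx
  if (length(vi) == 0L || upsilon == 0) return(entity)
  flip <- stats::runif(length(vi)) < upsilon
  entity$features[vi] <- resample_different(entity$features[vi], flip, entity$A)
  entity
}

#' Replicate an entity
#'
#' Copying applies to the heritable part only: the offspring's heritable
#' modules are copied from the parent's *current* heritable symbols
#' (lifetime changes there are inherited), each miscopied with
#' probability `mu` to a uniformly chosen different symbol. The
#' offspring's non-heritable variable modules are rebuilt to the
#' parent's birth values - the process recreating the non-heritable part
#' cannot be copying. The stable part is reproduced exactly. The
#' offspring's birth snapshot is its own initial state.
#'
#' @param parent a [modular_entity()].
#' @param mu per-module copy error probability.
#' @param id,birth_time bookkeeping for the offspring.
#' @return The offspring `modular_entity`.
#' @export
replicate_entity <- function(parent, mu, id = paste0(parent$id, ".1"),
                             birth_time = parent$birth_time + 1) {
  stopifnot(inherits(parent, "modular_entity"))
  feat <- parent$birth_features
  hi <- parent$heritable_idx
  if (length(hi)) {
    copied <- parent$features[hi]
    miss <- stats::runif(length(hi)) < mu
    feat[hi] <- resample_different(copied, miss, parent$A)
  }
  modular_entity(feat, parent$variable_idx, parent$heritable_idx, parent$A,
                 id = id, birth_time = birth_time)
}

#' Parent--offspring similarity
#'
#' Counts identical features between a parent and its offspring. Under
#' the `"as_printed"` convention - the one the closed form
#' [expected_similarity()] describes - heritable modules are compared
#' against the parent's state at its own birth while all other modules
#' are compared against the parent's current state. The
#' `"current_parent"` convention compares every module against the
#' parent's current state.
#'
#' @param parent,offspring [modular_entity()] objects with identical
#'   index sets.
#' @param convention `"as_printed"` or `"current_parent"`.
#' @return Integer match count in `0..I`.
#' @export
measure_similarity <- function(parent, offspring,
                               convention = c("as_printed", "current_parent")) {
  convention <- match.arg(convention)
  stopifnot(inherits(parent, "modular_entity"),
            inherits(offspring, "modular_entity"))
  if (length(parent$features) != length(offspring$features) ||
      !identical(parent$variable_idx, offspring$variable_idx) ||
      !identical(parent$heritable_idx, offspring$heritable_idx))
    stop("parent and offspring have mismatched shapes")
  ref <- parent$features
  if (convention == "as_printed" && length(parent$heritable_idx)) {
    ref[parent$heritable_idx] <- parent$birth_features[parent$heritable_idx]
  }
  sum(ref == offspring$features)
}

#' Monte-Carlo estimate of the expected similarity
#'
#' Simulates many independent parent--offspring replications at the
#' given parameters and measures the mean similarity, serving as the
#' Monte-Carlo cross-check of the closed form
#' [expected_similarity()]. Parents are born with uniform random
#' features, undergo one round of lifetime change, then replicate once.
#'
#' @param params a [vh_params()]; its `epsilon` is ignored here - the
#'   simulator's uniform miscopy realizes backmutation at
#'   `default_epsilon(A)` mechanically.
#' @param A inventory size (>= 2).
#' @param reps number of replications.
#' @param seed optional RNG seed.
#' @param convention see [measure_similarity()].
#' @return A one-row tibble: `mean_similarity`, `se`, `reps`, plus the
#'   parameters used.
#' @examples
#' p <- vh_params(50, V = 0.5, H = 0.2, upsilon = 0.1, mu = 0.05)
#' similarity_experiment(p, A = 4, reps = 2000, seed = 1)
#' @export
similarity_experiment <- function(params, A = 4L, reps = 10000L, seed = NULL,
                                  convention = c("as_printed",
                                                 "current_parent")) {
  convention <- match.arg(convention)
  stopifnot(inherits(params, "vh_params"), A >= 2L, reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  I <- params$I
  nV <- params$n_variable
  nH <- params$n_heritable
  u <- params$upsilon
  m <- params$mu
  # layout: [stable | variable non-heritable | heritable]
  var_cols <- if (nV > 0L) (I - nV + 1L):I else integer(0)
  her_cols <- if (nH > 0L) (I - nH + 1L):I else integer(0)
  birth <- matrix(sample.int(A, reps * I, replace = TRUE), reps, I)
  cur <- birth
  if (length(var_cols) && u > 0) {
    sub <- cur[, var_cols, drop = FALSE]
    flip <- matrix(stats::runif(length(sub)) < u, nrow(sub))
    sub[flip] <- ((sub[flip] - 1L +
                   sample.int(A - 1L, sum(flip), replace = TRUE)) %% A) + 1L
    cur[, var_cols] <- sub
  }
  off <- birth  # stable part exact; non-heritable variable part developed
  if (length(her_cols)) {
    sub <- cur[, her_cols, drop = FALSE]
    if (m > 0) {
      miss <- matrix(stats::runif(length(sub)) < m, nrow(sub))
      sub[miss] <- ((sub[miss] - 1L +
                     sample.int(A - 1L, sum(miss), replace = TRUE)) %% A) + 1L
    }
    off[, her_cols] <- sub
  }
  ref <- cur
  if (convention == "as_printed" && length(her_cols)) {
    ref[, her_cols] <- birth[, her_cols]
  }
  sims <- rowSums(ref == off)
  tibble::tibble(mean_similarity = mean(sims),
                 se = stats::sd(sims) / sqrt(reps),
                 reps = reps, I = I, V = params$V, H = params$H,
                 upsilon = u, mu = m, A = as.integer(A),
                 convention = convention)
}

#' Configuration of a population simulation
#'
#' @param I,A,V_frac,H_frac,upsilon,mu module structure and rates as in
#'   [vh_params()].
#' @param types a data frame with columns `name`, `g` (per-entity
#'   replication probability per generation), `d` (death probability)
#'   and `n0` (initial count).
#' @param generations number of discrete generations (>= 1).
#' @param carrying_capacity optional cap enforced by uniform random
#'   culling after reproduction; absent means unlimited resources.
#' @param convention similarity convention recorded per birth.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(I = 10L, A = 4L, V_frac = 0, H_frac = 0,
                              upsilon = 0, mu = 0,
                              types = tibble::tibble(name = "wt", g = 0.5,
                                                     d = 0.1, n0 = 50),
                              generations = 20L,
                              carrying_capacity = NULL,
                              convention = c("as_printed",
                                             "current_parent")) {
  convention <- match.arg(convention)
  types <- tibble::as_tibble(types)
  stopifnot(all(c("name", "g", "d", "n0") %in% names(types)),
            generations >= 1L,
            all(types$g >= 0 & types$g <= 1),
            all(types$d >= 0 & types$d <= 1))
  # reuse the V/H validation
  vh <- vh_params(I, V_frac, H_frac, upsilon, mu)
  structure(list(I = vh$I, A = as.integer(A), V_frac = V_frac,
                 H_frac = H_frac, upsilon = upsilon, mu = mu,
                 n_variable = vh$n_variable, n_heritable = vh$n_heritable,
                 types = types, generations = as.integer(generations),
                 carrying_capacity = carrying_capacity,
                 convention = convention),
            class = "simulation_config")
}

# multivariate-hypergeometric cull of count vector n down to total k
cull_counts <- function(n, k) {
  total <- sum(n)
  if (total <= k) return(n)
  out <- numeric(length(n))
  remaining <- total
  left <- k
  for (i in seq_along(n)) {
    if (left <= 0) break
    take <- stats::rhyper(1, n[i], remaining - n[i], left)
    out[i] <- take
    left <- left - take
    remaining <- remaining - n[i]
  }
  out
}

#' Run a population simulation
#'
#' Discrete non-overlapping bookkeeping: each generation every entity
#' first undergoes lifetime change, then replicates with its type's
#' probability `g` (offspring similarity to the parent recorded at
#' birth), then dies with probability `d`; finally the population is
#' culled uniformly at random to the carrying capacity, if one is set.
#' When the variable fraction is zero entities carry no mutable state
#' and the dynamics reduce exactly to per-type counts, which the
#' simulator exploits to handle the large populations of unlimited
#' growth; see the package vignette.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed; recorded in the trajectory, which is
#'   bit-reproducible given `(config, seed)`.
#' @return An object of class `replicator_trajectory`: [tidy()] gives
#'   per-generation, per-type records (`generation`, `type`, `count`,
#'   `mean_similarity`, `pop_size`); [glance()] a one-row summary;
#'   [autoplot()] the count trajectories.
#' @examples
#' cfg <- simulation_config(types = tibble::tibble(
#'   name = c("fast", "slow"), g = c(0.5, 0.25), d = 0, n0 = c(20, 20)),
#'   generations = 10)
#' traj <- run_simulation(cfg, seed = 1)
#' glance(traj)
#' @export
run_simulation <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  if (config$n_variable == 0L) {
    traj <- run_counts(config)
  } else {
    traj <- run_entities(config)
  }
  structure(list(records = traj$records, status = traj$status,
                 config = config, seed = seed),
            class = "replicator_trajectory")
}

# count-based dynamics for exact replicators (V = 0): no per-entity state
run_counts <- function(config) {
  ty <- config$types
  n <- as.numeric(ty$n0)
  recs <- list()
  status <- "completed"
  for (gen in seq_len(config$generations)) {
    births <- stats::rbinom(length(n), size = pmin(n, .Machine$integer.max),
                            prob = ty$g)
    # rbinom caps size at integer range; split very large counts
    big <- n > .Machine$integer.max
    if (any(big)) {
      births[big] <- round(n[big] * ty$g[big])
    }
    deaths <- stats::rbinom(length(n), size = pmin(n, .Machine$integer.max),
                            prob = ty$d)
    if (any(big)) deaths[big] <- round(n[big] * ty$d[big])
    n <- n - deaths + births
    if (!is.null(config$carrying_capacity)) {
      n <- cull_counts(n, config$carrying_capacity)
    }
    recs[[gen]] <- tibble::tibble(generation = gen, type = ty$name,
                                  count = n,
                                  mean_similarity = as.numeric(config$I),
                                  pop_size = sum(n))
    if (sum(n) == 0) {
      status <- "extinct"
      break
    }
  }
  list(records = dplyr::bind_rows(recs), status = status)
}

# entity-based dynamics: feature matrices, one row per entity
run_entities <- function(config) {
  I <- config$I
  A <- config$A
  nV <- config$n_variable
  nH <- config$n_heritable
  var_cols <- if (nV > 0L) (I - nV + 1L):I else integer(0)
  her_cols <- if (nH > 0L) (I - nH + 1L):I else integer(0)
  ty <- config$types
  n0 <- sum(ty$n0)
  type <- rep(ty$name, ty$n0)
  birth <- matrix(sample.int(A, n0 * I, replace = TRUE), n0, I)
  cur <- birth
  g <- stats::setNames(ty$g, ty$name)
  d <- stats::setNames(ty$d, ty$name)
  recs <- list()
  status <- "completed"
  for (gen in seq_len(config$generations)) {
    n <- length(type)
    # lifetime change
    if (length(var_cols) && config$upsilon > 0 && n > 0) {
      sub <- cur[, var_cols, drop = FALSE]
      flip <- matrix(stats::runif(length(sub)) < config$upsilon, nrow(sub))
      sub[flip] <- ((sub[flip] - 1L +
                     sample.int(A - 1L, sum(flip), replace = TRUE)) %% A) + 1L
      cur[, var_cols] <- sub
    }
    # reproduction
    parents <- which(stats::runif(n) < g[type])
    sim_by_type <- rep(NA_real_, nrow(ty))
    names(sim_by_type) <- ty$name
    if (length(parents)) {
      off <- birth[parents, , drop = FALSE]  # developed + stable part
      if (length(her_cols)) {
        sub <- cur[parents, her_cols, drop = FALSE]
        if (config$mu > 0) {
          miss <- matrix(stats::runif(length(sub)) < config$mu, nrow(sub))
          sub[miss] <- ((sub[miss] - 1L +
                         sample.int(A - 1L, sum(miss), replace = TRUE)) %% A) + 1L
        }
        off[, her_cols] <- sub
      }
      ref <- cur[parents, , drop = FALSE]
      if (config$convention == "as_printed" && length(her_cols)) {
        ref[, her_cols] <- birth[parents, her_cols, drop = FALSE]
      }
      sims <- rowSums(ref == off)
      for (tn in ty$name) {
        sel <- type[parents] == tn
        if (any(sel)) sim_by_type[tn] <- mean(sims[sel])
      }
      # survivors of death among current entities
      die <- stats::runif(n) < d[type]
      keep <- !die
      type <- c(type[keep], type[parents])
      cur <- rbind(cur[keep, , drop = FALSE], off)
      birth <- rbind(birth[keep, , drop = FALSE], off)
    } else {
      die <- stats::runif(n) < d[type]
      keep <- !die
      type <- type[keep]
      cur <- cur[keep, , drop = FALSE]
      birth <- birth[keep, , drop = FALSE]
    }
    # cull to capacity
    cap <- config$carrying_capacity
    if (!is.null(cap) && length(type) > cap) {
      keep <- sample.int(length(type), cap)
      type <- type[keep]
      cur <- cur[keep, , drop = FALSE]
      birth <- birth[keep, , drop = FALSE]
    }
    counts <- vapply(ty$name, function(tn) sum(type == tn), numeric(1))
    recs[[gen]] <- tibble::tibble(generation = gen, type = ty$name,
                                  count = counts,
                                  mean_similarity = unname(sim_by_type),
                                  pop_size = length(type))
    if (length(type) == 0L) {
      status <- "extinct"
      break
    }
  }
  list(records = dplyr::bind_rows(recs), status = status)
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  last <- max(x$records$generation)
  cat("<replicator_trajectory> ", last, " generations, status: ",
      x$status, ", seed ", x$seed, "\n", sep = "")
  print(utils::tail(x$records, nrow(x$config$types)))
  invisible(x)
}

#' @method tidy replicator_trajectory
#' @export
tidy.replicator_trajectory <- function(x, ...) x$records

#' @method glance replicator_trajectory
#' @export
glance.replicator_trajectory <- function(x, ...) {
  last <- x$records[x$records$generation == max(x$records$generation), ]
  tibble::tibble(generations = max(x$records$generation),
                 status = x$status,
                 final_pop = last$pop_size[1],
                 n_types = nrow(x$config$types),
                 seed = x$seed)
}

#' @method autoplot replicator_trajectory
#' @export
autoplot.replicator_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$generation, y = .data$count,
                               colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "generation", y = "count (log1p scale)",
                  colour = "type") +
    ggplot2::theme_minimal()
}

#' Dilution of the slower exact replicator under unlimited growth
#'
#' Two exact-replicator types (no variability, no death, no resource
#' limit) growing with different replication probabilities: relative
#' concentrations shift exactly as in a limiting environment, and the
#' slower type is diluted toward zero frequency. The deterministic
#' expectation of the slow-type frequency is
#' `n0_slow (1+g_slow)^t / (n0_slow (1+g_slow)^t + n0_fast (1+g_fast)^t)`,
#' which the simulated mean tracks.
#'
#' @param g_fast,g_slow per-generation replication probabilities,
#'   `g_fast >= g_slow`.
#' @param generations number of generations (0 returns the initial
#'   frequencies).
#' @param reps independent simulation replicates.
#' @param n0 initial count of each type.
#' @param seed RNG seed; replicate r uses `seed + r - 1`.
#' @return A tibble with one row per generation: `generation`,
#'   `mean_slow_freq`, `se`, `expected_slow_freq`.
#' @examples
#' dilution_experiment(0.5, 0.25, generations = 10, reps = 20, seed = 1)
#' @export
dilution_experiment <- function(g_fast, g_slow, generations = 40L,
                                reps = 200L, n0 = 200L, seed = 1L) {
  stopifnot(g_fast >= g_slow, g_fast <= 1, g_slow >= 0, reps >= 1L)
  if (generations == 0L) {
    return(tibble::tibble(generation = 0L, mean_slow_freq = 0.5, se = 0,
                          expected_slow_freq = 0.5))
  }
  cfg <- simulation_config(
    I = 1L, V_frac = 0, H_frac = 0,
    types = tibble::tibble(name = c("fast", "slow"),
                           g = c(g_fast, g_slow), d = 0,
                           n0 = c(n0, n0)),
    generations = generations)
  freqs <- matrix(NA_real_, reps, generations)
  for (r in seq_len(reps)) {
    traj <- run_simulation(cfg, seed = seed + r - 1L)
    rec <- traj$records
    slow <- rec$count[rec$type == "slow"]
    tot <- rec$pop_size[rec$type == "slow"]
    freqs[r, seq_along(slow)] <- slow / tot
  }
  t <- seq_len(generations)
  expected <- n0 * (1 + g_slow)^t /
    (n0 * (1 + g_slow)^t + n0 * (1 + g_fast)^t)
  tibble::tibble(
    generation = t,
    mean_slow_freq = colMeans(freqs, na.rm = TRUE),
    se = apply(freqs, 2, stats::sd, na.rm = TRUE) / sqrt(reps),
    expected_slow_freq = expected
  )
}
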