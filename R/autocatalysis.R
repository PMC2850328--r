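#' Replication ratio of a species
#'
#' The per-turn replication ratio: starting from the smallest pure seed
#' `{species: k}` that ignites, the number of copies present after the
#' shortest igniting turn divided by `k`, as an exact rational. The
#' formose core doubles glycolaldehyde (ratio 2) while the Calvin cycle
#' turns three 3-phosphoglycerate into four (ratio 4/3). A species whose
#' pure seeds only sustain has ratio 1 (sequential replacement); a
#' species with no igniting or sustaining pure seed up to
#' `max_seed_size` copies has ratio 0 - it may still be multiplied by
#' the cycle from a mixed seed, which [analyze_network()] reports
#' separately.
#'
#' @param net a [reaction_network()].
#' @param species an internal species id.
#' @param max_steps firing bound passed to the token game.
#' @param max_seed_size largest pure-seed copy number tried.
#' @return A [rational()].
#' @examples
#' replication_ratio(fixture("formose"), "glycolaldehyde")  # 2
#' replication_ratio(fixture("calvin"), "PGA")              # 4/3
#' @export
replication_ratio <- function(net, species, max_steps = 50L,
                              max_seed_size = 6L) {
  stopifnot(inherits(net, "reaction_network"))
  role <- stats::setNames(net$species$role, net$species$id)
  if (!species %in% net$species$id) stop("unknown species: ", species)
  if (role[species] != "internal")
    stop("replication ratio is defined for internal species only: ", species)
  any_sustains <- FALSE
  any_undecided <- FALSE
  for (k in seq_len(max_seed_size)) {
    out <- can_ignite(net, stats::setNames(k, species), max_steps = max_steps)
    if (out$status == "ignites") {
      n_after <- out$state[species]
      if (is.na(n_after)) n_after <- 0L
      return(rational(as.integer(n_after), k))
    }
    if (out$status == "sustains") any_sustains <- TRUE
    if (out$status == "undecided") any_undecided <- TRUE
  }
  if (any_sustains) return(rational(1L))
  if (any_undecided) {
    cond <- structure(
      class = c("replikit_undecided", "error", "condition"),
      list(message = paste0("search bound exhausted before deciding pure seeds of '",
                            species, "'; raise max_steps or max_states"),
           call = sys.call(), species = species))
    stop(cond)
  }
  rational(0L)
}

#' Autocatalytic order of a species
#'
#' The order n of the general scheme A + inputs -> B1 + ... + Bk + wastes:
#' the number of product entities equivalent to the focal species after
#' one minimal full turn. n = 0 means the reaction set cannot close to a
#' cycle for this species, n = 1 is sequential replacement (a simple
#' non-autocatalytic cycle intermediate), and n >= 2 is autocatalysis of
#' order n.
#'
#' @inheritParams replication_ratio
#' @param equivalence optional list of character vectors; species within
#'   a group are treated as functionally identical, so products
#'   equivalent to the focal species count toward n.
#' @param seeds optionally, a precomputed [minimal_seeds()] result; for
#'   a species with no pure seed (a dependent replicator) the cycle-level
#'   order is read off the turn of a minimal seed containing it.
#' @return A list with elements `n` (integer) and `label` (one of
#'   `"no_cycle"`, `"sequential_replacement"`, `"autocatalytic"`).
#' @examples
#' classify_order(fixture("formose"), "glycolaldehyde")  # n = 2
#' @export
classify_order <- function(net, species, equivalence = NULL,
                           max_steps = 50L, max_seed_size = 6L,
                           seeds = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (!species %in% net$species$id) stop("unknown species: ", species)
  cmp <- compile_network(net)
  class_of <- projection_matrix(cmp, equivalence)
  focal_class <- class_of[cmp$idx[species]]
  count_focal <- function(state) {
    full <- stats::setNames(integer(cmp$ns), cmp$internal)
    full[names(state)] <- state
    as.integer(sum(full[class_of == focal_class]))
  }
  any_sustains <- FALSE
  for (k in seq_len(max_seed_size)) {
    out <- can_ignite(net, stats::setNames(k, species), max_steps = max_steps,
                      equivalence = equivalence)
    if (out$status == "ignites") {
      return(list(n = count_focal(out$state), label = "autocatalytic"))
    }
    if (out$status == "sustains") any_sustains <- TRUE
  }
  if (any_sustains) return(list(n = 1L, label = "sequential_replacement"))
  # no pure seed: a dependent species is still doubled along the turn of
  # a mixed seed it belongs to (every cycle intermediate is multiplied)
  if (is.null(seeds)) seeds <- minimal_seeds(net, max_seed_size, max_steps)
  for (seed in seeds) {
    if (!species %in% names(seed) || seed[[species]] != 1L) next
    out <- ignite_with_focus(net, seed, species, max_steps)
    if (out$status == "ignites") {
      state <- stats::setNames(out$state, cmp$internal)
      return(list(n = count_focal(state[state > 0L]), label = "autocatalytic"))
    }
  }
  list(n = 0L, label = "no_cycle")
}

# Enumerate seed multisets over `ids` with total count `total`, in
# lexicographic order by species id: all count mass on the first id
# first, etc.
enumerate_multisets <- function(ids, total) {
  if (length(ids) == 1L) {
    return(list(stats::setNames(total, ids)))
  }
  out <- list()
  for (k in total:0) {
    rest <- enumerate_multisets(ids[-1], total - k)
    for (r in rest) {
      v <- if (k > 0L) c(stats::setNames(k, ids[1]), r) else r
      out <- c(out, list(v[v > 0L]))
    }
  }
  out
}

dominates_seed <- function(a, b) {
  # does multiset a contain multiset b?
  all(names(b) %in% names(a)) && all(a[names(b)] >= b)
}

#' Minimal autocatalytic seeds
#'
#' Exhaustively enumerates seed multisets of total count at most
#' `max_seed_size` (ascending by total count, then lexicographically by
#' species id) and returns the igniting ones that do not contain a
#' smaller igniting seed. Any component that can initiate the cycle
#' forms an autocatalytic seed; the minimal ones characterise the
#' network: for the bird--nest cycle they are `{A1}` and `{A2, B}`, and
#' no number of nests alone ever ignites.
#'
#' @inheritParams replication_ratio
#' @param max_seed_size largest total seed count enumerated.
#' @param restrict optional character vector: only seeds drawn from these
#'   species are considered (e.g. PGA-only seeds of the Calvin cycle).
#' @return A list of named integer vectors in deterministic order, with
#'   attribute `incomplete = TRUE` when some candidate was undecided
#'   within the bounds.
#' @examples
#' minimal_seeds(fixture("bird_nest"))
#' minimal_seeds(fixture("calvin"), restrict = "PGA")  # {PGA: 3}
#' @export
minimal_seeds <- function(net, max_seed_size = 6L, max_steps = 50L,
                          max_states = 50000L, restrict = NULL) {
  stopifnot(inherits(net, "reaction_network"), max_seed_size >= 1L)
  ids <- sort_c(net$species$id[net$species$role == "internal"])
  if (!is.null(restrict)) {
    unknown <- setdiff(restrict, ids)
    if (length(unknown)) stop("restrict contains non-internal species: ",
                              paste(unknown, collapse = ", "))
    ids <- sort_c(intersect(ids, restrict))
  }
  found <- list()
  incomplete <- FALSE
  for (total in seq_len(max_seed_size)) {
    for (seed in enumerate_multisets(ids, total)) {
      if (any(vapply(found, function(f) dominates_seed(seed, f), logical(1))))
        next
      out <- can_ignite(net, seed, max_steps = max_steps,
                        max_states = max_states)
      if (out$status == "ignites") {
        found <- c(found, list(seed))
      } else if (out$status == "undecided") {
        incomplete <- TRUE
      }
    }
  }
  attr(found, "incomplete") <- incomplete
  found
}

species_participation <- function(net, species) {
  as_reactant <- FALSE
  as_catalyst <- FALSE
  as_product <- FALSE
  for (i in seq_len(nrow(net$reactions))) {
    if (species %in% names(net$reactions$reactants[[i]])) as_reactant <- TRUE
    if (species %in% names(net$reactions$catalysts[[i]])) as_catalyst <- TRUE
    if (species %in% names(net$reactions$products[[i]])) as_product <- TRUE
  }
  list(reactant = as_reactant, catalyst = as_catalyst, product = as_product)
}

# Token search demanding a strict surplus on one focal species while the
# whole seed is still dominated: "does some turn from this seed multiply
# the focal species?". Returns the raw search result.
ignite_with_focus <- function(net, seed, species, max_steps = 50L,
                              max_states = 50000L) {
  seed <- check_seed(net, seed)
  cmp <- compile_network(net)
  token_search(cmp, seed_to_vec(cmp, seed), max_steps,
               max_states = max_states, surplus_idx = cmp$idx[[species]])
}

# Best per-turn gain of `species` over the minimal seeds that contain it:
# its count after the shortest turn that multiplies it, divided by its
# seed count.
mixed_seed_ratio <- function(net, species, seeds, max_steps = 50L) {
  best <- NULL
  cmp <- compile_network(net)
  for (seed in seeds) {
    if (!species %in% names(seed)) next
    out <- ignite_with_focus(net, seed, species, max_steps)
    if (out$status != "ignites") next
    n_after <- out$state[cmp$idx[[species]]]
    r <- rational(as.integer(n_after), seed[[species]])
    if (is.null(best) || r > best) best <- r
  }
  best
}

# Does any turn from some minimal seed strictly increase `species` while
# maintaining the seed?
multiplied_by_cycle <- function(net, species, seeds, max_steps = 50L) {
  for (seed in seeds) {
    out <- ignite_with_focus(net, seed, species, max_steps)
    if (out$status == "ignites") return(TRUE)
  }
  FALSE
}

#' Classify the role of a species in its cycle
#'
#' Distinguishes obligate from facultative autocatalysts:
#' * `autonomous_obligate` - some pure seed `{species: k}` ignites; the
#'   species can start the cycle on its own (the bird).
#' * `autoinductive_facultative` - the species is multiplied by the
#'   cycle but participates only catalytically, never as a reactant: a
#'   side product that accelerates the sequence without directly
#'   producing more of itself (the nest).
#' * `dependent` - multiplied by the cycle and present in some minimal
#'   seed, but with no pure seed: it needs obligatory partners (the
#'   nesting bird).
#' * `sequential_replacement` - pure seeds only sustain (ratio exactly 1).
#' * `non_autocatalytic` - none of the above.
#'
#' @inheritParams replication_ratio
#' @param seeds optionally, a precomputed [minimal_seeds()] result.
#' @return A single role label.
#' @examples
#' bn <- fixture("bird_nest")
#' classify_role(bn, "A1")  # autonomous_obligate
#' classify_role(bn, "A2")  # dependent
#' classify_role(bn, "B")   # autoinductive_facultative
#' @export
classify_role <- function(net, species, seeds = NULL, max_steps = 50L,
                          max_seed_size = 6L) {
  stopifnot(inherits(net, "reaction_network"))
  if (!species %in% net$species$id) stop("unknown species: ", species)
  if (is.null(seeds)) seeds <- minimal_seeds(net, max_seed_size, max_steps)
  pure <- tryCatch(replication_ratio(net, species, max_steps, max_seed_size),
                   replikit_undecided = function(e) NULL)
  if (!is.null(pure) && pure > rational(1L)) return("autonomous_obligate")
  part <- species_participation(net, species)
  multiplied <- multiplied_by_cycle(net, species, seeds, max_steps)
  if (part$catalyst && !part$reactant && multiplied)
    return("autoinductive_facultative")
  in_seed <- any(vapply(seeds, function(s) species %in% names(s), logical(1)))
  if (in_seed && multiplied) return("dependent")
  if (!is.null(pure) && pure == rational(1L)) return("sequential_replacement")
  "non_autocatalytic"
}

#' Kinetic viability of a multiplying entity
#'
#' Stoichiometric autocatalysis only pays off kinetically when the
#' growth rate exceeds the spontaneous decay rate; at `g == d` the
#' population is only replaced, below it it depletes.
#'
#' @param g growth rate per unit time (non-negative).
#' @param d decay rate per unit time (non-negative).
#' @return `"multiplying"`, `"replacing"` or `"depleting"`.
#' @examples
#' kinetic_viability(2, 0.5)
#' @export
kinetic_viability <- function(g, d) {
  stopifnot(length(g) == 1L, length(d) == 1L)
  if (is.na(g) || is.na(d) || g < 0 || d < 0)
    stop("rates must be non-negative numbers")
  if (g > d) "multiplying" else if (g == d) "replacing" else "depleting"
}

#' Full autocatalysis report for a network
#'
#' Computes, for every internal species (or a subset), the pure-seed
#' replication ratio, the best mixed-seed per-turn ratio, the
#' autocatalytic order, the role label and the minimal seeds of the
#' network. The effective ratio of a species is its pure-seed ratio when
#' one exists and otherwise its mixed-seed ratio, so a facultative
#' autocatalyst like the nest still shows its per-turn multiplication.
#'
#' @inheritParams replication_ratio
#' @param species optional character vector restricting the report.
#' @return An object of class `autocatalysis_report`; use [tidy()] for
#'   the per-species tibble and [glance()] for a one-row summary. The
#'   per-species columns are `species`, `order_n`, `ratio` (effective,
#'   as a string rational), `ratio_value` (numeric), `pure_seed_ratio`,
#'   `mixed_seed_ratio`, `is_autocatalytic`, `role`.
#' @examples
#' rep <- analyze_network(fixture("bird_nest"))
#' tidy(rep)
#' @export
analyze_network <- function(net, species = NULL, max_seed_size = 6L,
                            max_steps = 50L) {
  stopifnot(inherits(net, "reaction_network"))
  internal <- sort_c(net$species$id[net$species$role == "internal"])
  if (!is.null(species)) {
    unknown <- setdiff(species, internal)
    if (length(unknown)) stop("not internal species: ",
                              paste(unknown, collapse = ", "))
    internal <- species
  }
  seeds <- minimal_seeds(net, max_seed_size, max_steps)
  rows <- lapply(internal, function(sp) {
    pure <- tryCatch(replication_ratio(net, sp, max_steps, max_seed_size),
                     replikit_undecided = function(e) NULL)
    mixed <- mixed_seed_ratio(net, sp, seeds, max_steps)
    eff <- if (!is.null(pure) && pure > rational(0L)) pure else mixed
    ord <- classify_order(net, sp, max_steps = max_steps,
                          max_seed_size = max_seed_size, seeds = seeds)
    role <- classify_role(net, sp, seeds = seeds, max_steps = max_steps,
                          max_seed_size = max_seed_size)
    tibble::tibble(
      species = sp,
      order_n = ord$n,
      ratio = if (is.null(eff)) NA_character_ else format(eff),
      ratio_value = if (is.null(eff)) NA_real_ else as.numeric(eff),
      pure_seed_ratio = if (is.null(pure)) NA_character_ else format(pure),
      mixed_seed_ratio = if (is.null(mixed)) NA_character_ else format(mixed),
      is_autocatalytic = !is.null(eff) && eff > rational(1L),
      role = role
    )
  })
  structure(list(
    table = dplyr::bind_rows(rows),
    minimal_seeds = seeds,
    network_hash = network_hash(net),
    bounds = list(max_seed_size = max_seed_size, max_steps = max_steps),
    incomplete = isTRUE(attr(seeds, "incomplete"))
  ), class = "autocatalysis_report")
}

#' @export
print.autocatalysis_report <- function(x, ...) {
  cat("<autocatalysis_report> network ", x$network_hash, "\n", sep = "")
  print(x$table)
  cat("minimal seeds:",
      paste(vapply(x$minimal_seeds, function(s)
        paste0("{", paste0(names(s), ":", s, collapse = ", "), "}"),
        character(1)), collapse = " "), "\n")
  if (x$incomplete) cat("note: seed search incomplete within bounds\n")
  invisible(x)
}

#' @method tidy autocatalysis_report
#' @export
tidy.autocatalysis_report <- function(x, ...) x$table

#' @method glance autocatalysis_report
#' @export
glance.autocatalysis_report <- function(x, ...) {
  sizes <- vapply(x$minimal_seeds, sum, numeric(1))
  tibble::tibble(
    n_species = nrow(x$table),
    n_autocatalytic = sum(x$table$is_autocatalytic),
    n_minimal_seeds = length(x$minimal_seeds),
    min_seed_size = if (length(sizes)) min(sizes) else NA_real_,
    incomplete = x$incomplete,
    network_hash = x$network_hash
  )
}
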