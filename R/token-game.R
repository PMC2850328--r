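# Token-game semantics over a reaction network.
#
# The state of the game is a multiset of non-food species. A reaction may
# fire iff its non-food reactant and catalyst counts are available; firing
# consumes the reactants, returns the catalysts, adds the non-waste
# products, and discards waste. Food species are an unlimited reservoir:
# food reactants are always available and food catalysts always present.

# Precompile a network into integer matrices over internal species.
compile_network <- function(net) {
  internal <- net$species$id[net$species$role == "internal"]
  ns <- length(internal)
  nr <- nrow(net$reactions)
  idx <- stats::setNames(seq_len(ns), internal)
  R <- matrix(0L, ns, nr)
  P <- matrix(0L, ns, nr)
  C <- matrix(0L, ns, nr)
  fill <- function(M, col, v) {
    keep <- names(v)[names(v) %in% internal]
    if (length(keep)) M[idx[keep], col] <- v[keep]
    M
  }
  for (j in seq_len(nr)) {
    R <- fill(R, j, net$reactions$reactants[[j]])
    P <- fill(P, j, net$reactions$products[[j]])
    C <- fill(C, j, net$reactions$catalysts[[j]])
  }
  list(internal = internal, idx = idx, reaction_ids = net$reactions$id,
       need = R + C, delta = P - R, nr = nr, ns = ns)
}

# Validate a user-supplied seed multiset against a network: named positive
# integer counts over non-food, non-waste species.
check_seed <- function(net, seed) {
  if (is.data.frame(seed)) seed <- stats::setNames(as.integer(seed$count), seed$species)
  if (length(seed) == 0L) stop("seed must be a non-empty named integer vector")
  if (is.null(names(seed)) || any(!nzchar(names(seed))))
    stop("seed must be named by species id")
  unknown <- setdiff(names(seed), net$species$id)
  if (length(unknown)) stop("seed references unknown species: ",
                            paste(unknown, collapse = ", "))
  role <- stats::setNames(net$species$role, net$species$id)
  bad <- names(seed)[role[names(seed)] != "internal"]
  if (length(bad)) stop("seed may contain only internal (non-food, non-waste) ",
                        "species: ", paste(bad, collapse = ", "))
  if (any(seed < 1L) || any(seed != floor(seed)))
    stop("seed counts must be positive integers")
  v <- stats::setNames(as.integer(seed), names(seed))
  tapply(v, names(v), sum)[unique(names(v))]
}

# Build the class-projection matrix for an optional species equivalence
# (a list of character vectors partitioning a subset of internal ids;
# unlisted species are singleton classes).
projection_matrix <- function(cmp, equivalence = NULL) {
  ns <- cmp$ns
  class_of <- seq_len(ns)
  if (!is.null(equivalence)) {
    for (grp in equivalence) {
      grp <- intersect(grp, cmp$internal)
      if (length(grp) > 1L) {
        tgt <- min(cmp$idx[grp])
        class_of[cmp$idx[grp]] <- tgt
      }
    }
  }
  class_of
}

project_state <- function(s, class_of) {
  as.integer(rowsum(s, class_of))
}

# Core bounded breadth-first reachability search.
#
# Returns list(status, witness, steps_used, state, nstates, exhausted).
# status: "ignites" when a state is found whose class-projected counts
# dominate the projected seed with strict surplus on at least one seed
# class; "sustains" when the search exhausts without ignition but some
# non-empty firing sequence returns exactly to the seed state; "dies"
# when the search exhausts with neither; "undecided" when the step or
# state budget runs out first.
#
# When `surplus_idx` (an internal species index) is given, the strict
# surplus is required on that particular species class while the seed is
# still dominated - used to ask whether a turn multiplies one focal
# species (e.g. the nest) rather than any seed member.
token_search <- function(cmp, seed_vec, max_steps, class_of = NULL,
                         max_states = 50000L, surplus_idx = NULL) {
  if (is.null(class_of)) class_of <- seq_len(cmp$ns)
  identity_proj <- all(class_of == seq_len(cmp$ns))
  proj_seed <- if (identity_proj) seed_vec else project_state(seed_vec, class_of)
  seed_classes <- which(proj_seed > 0L)
  surplus_class <- NULL
  if (!is.null(surplus_idx)) {
    surplus_class <- if (identity_proj) surplus_idx else {
      # position of the focal species' class in the projected vector
      match(class_of[surplus_idx], sort(unique(class_of)))
    }
  }
  proj_full <- if (identity_proj) seed_vec else project_state(seed_vec, class_of)
  need <- cmp$need
  delta <- cmp$delta
  nr <- cmp$nr
  key <- function(s) paste(s, collapse = ",")
  start_key <- key(seed_vec)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(start_key, TRUE, envir = visited)
  frontier <- list(list(s = seed_vec, path = integer(0)))
  steps <- 0L
  nstates <- 1L
  returned <- FALSE
  budget_hit <- FALSE
  while (length(frontier) > 0L && steps < max_steps && !budget_hit) {
    steps <- steps + 1L
    nxt <- vector("list", length(frontier) * nr)
    m <- 0L
    for (node in frontier) {
      s <- node$s
      for (j in seq_len(nr)) {
        if (all(s >= need[, j])) {
          s2 <- s + delta[, j]
          p2 <- if (identity_proj) s2 else project_state(s2, class_of)
          dominated <- all(p2[seed_classes] >= proj_seed[seed_classes])
          strict <- if (is.null(surplus_class)) {
            any(p2[seed_classes] > proj_seed[seed_classes])
          } else {
            p2[surplus_class] > proj_seed[surplus_class]
          }
          if (dominated && strict) {
            return(list(status = "ignites",
                        witness = cmp$reaction_ids[c(node$path, j)],
                        steps_used = steps, state = s2, nstates = nstates,
                        exhausted = FALSE))
          }
          # "returns exactly the seed": equality of class-projected states,
          # so functionally identical products count as a return
          if (all(p2 == proj_full)) returned <- TRUE
          k2 <- key(s2)
          if (is.null(visited[[k2]])) {
            assign(k2, TRUE, envir = visited)
            nstates <- nstates + 1L
            if (nstates > max_states) {
              budget_hit <- TRUE
              break
            }
            m <- m + 1L
            nxt[[m]] <- list(s = s2, path = c(node$path, j))
          }
        }
      }
      if (budget_hit) break
    }
    frontier <- if (m > 0L) nxt[seq_len(m)] else list()
  }
  exhausted <- length(frontier) == 0L && !budget_hit
  status <- if (exhausted) {
    if (returned) "sustains" else "dies"
  } else {
    "undecided"
  }
  list(status = status, witness = NULL, steps_used = steps, state = NULL,
       nstates = nstates, exhausted = exhausted)
}

seed_to_vec <- function(cmp, seed) {
  v <- integer(cmp$ns)
  v[cmp$idx[names(seed)]] <- as.integer(seed)
  v
}

#' Can a seed ignite a network?
#'
#' Runs the bounded token game from a seed multiset of non-food species.
#' Food is an unlimited reservoir and waste a sink. The seed *ignites*
#' when some firing sequence of at most `max_steps` reactions reaches a
#' state holding at least the seed counts of every seed species with a
#' strict surplus in at least one: one turn of the cycle has produced
#' more offspring than parents. It *sustains* when the reachable set is
#' exhausted without surplus but some sequence returns exactly to the
#' seed (sequential replacement), and *dies* when neither is possible.
#' When the step or state budget is exhausted first the outcome is
#' `undecided` - the search is bounded and never claims completeness it
#' did not establish.
#'
#' @param net a [reaction_network()].
#' @param seed a named integer vector of positive counts over internal
#'   species, e.g. `c(A1 = 1)`.
#' @param max_steps maximum number of reaction firings to explore.
#' @param equivalence optional list of character vectors of species ids;
#'   species within a group are counted as one class when comparing
#'   states to the seed (functionally identical products).
#' @param max_states cap on distinct states explored.
#' @return A list of class `ignition_outcome`: `status` (one of
#'   `"ignites"`, `"sustains"`, `"dies"`, `"undecided"`), `witness` (the
#'   firing sequence of reaction ids, only when igniting), `steps_used`,
#'   and `state` (the witness end state as a named vector, when igniting).
#' @examples
#' bn <- fixture("bird_nest")
#' can_ignite(bn, c(A1 = 1))           # ignites via R1, R2
#' can_ignite(bn, c(B = 1))            # a nest alone dies
#' can_ignite(bn, c(A2 = 1, B = 1))    # the {A2, B} seed ignites
#' @export
can_ignite <- function(net, seed, max_steps = 50L, equivalence = NULL,
                       max_states = 50000L) {
  stopifnot(inherits(net, "reaction_network"), max_steps >= 1L)
  seed <- check_seed(net, seed)
  cmp <- compile_network(net)
  class_of <- projection_matrix(cmp, equivalence)
  res <- token_search(cmp, seed_to_vec(cmp, seed), max_steps, class_of,
                      max_states)
  state <- NULL
  if (!is.null(res$state)) {
    state <- stats::setNames(res$state, cmp$internal)
    state <- state[state > 0L]
  }
  structure(list(status = res$status, witness = res$witness,
                 steps_used = res$steps_used, state = state,
                 seed = seed), class = "ignition_outcome")
}

#' @export
print.ignition_outcome <- function(x, ...) {
  cat("<ignition_outcome> seed {",
      paste0(names(x$seed), ":", x$seed, collapse = ", "),
      "} -> ", x$status, sep = "")
  if (!is.null(x$witness)) cat(" via ", paste(x$witness, collapse = ", "), sep = "")
  cat(" (", x$steps_used, " steps explored)\n", sep = "")
  invisible(x)
}
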