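# Independent brute-force oracle for the token game, plus a random
# network generator for property-style tests.
#
# The oracle enumerates *every* firing sequence up to a depth bound by
# plain recursion over the parsed reaction list. It shares no code with
# the package's compiled-matrix breadth-first search: states are named
# lists, enabling/firing are recomputed from the tibbles each time.

oracle_state_apply <- function(net, state, i) {
  # fire reaction row i on named-count list `state`; NULL if not enabled
  role <- setNames(net$species$role, net$species$id)
  re <- net$reactions$reactants[[i]]
  ca <- net$reactions$catalysts[[i]]
  pr <- net$reactions$products[[i]]
  get <- function(s) if (is.null(state[[s]])) 0L else state[[s]]
  for (s in names(re)) {
    if (role[s] == "food") next
    if (get(s) < re[[s]]) return(NULL)
  }
  for (s in names(ca)) {
    if (role[s] == "food") next
    if (get(s) < ca[[s]]) return(NULL)
  }
  for (s in names(re)) {
    if (role[s] == "food") next
    state[[s]] <- get(s) - re[[s]]
  }
  for (s in names(pr)) {
    if (role[s] %in% c("food", "waste")) next
    state[[s]] <- get(s) + pr[[s]]
  }
  state
}

oracle_dominates <- function(state, seed, strict_on_any = TRUE) {
  get <- function(s) if (is.null(state[[s]])) 0L else state[[s]]
  ge <- vapply(names(seed), function(s) get(s) >= seed[[s]], logical(1))
  gt <- vapply(names(seed), function(s) get(s) > seed[[s]], logical(1))
  all(ge) && (!strict_on_any || any(gt))
}

# TRUE iff some firing sequence of length <= max_steps reaches a state
# dominating the seed with strict surplus on at least one seed species
oracle_ignites <- function(net, seed, max_steps) {
  state0 <- as.list(seed)
  recurse <- function(state, depth) {
    if (depth >= max_steps) return(FALSE)
    for (i in seq_len(nrow(net$reactions))) {
      s2 <- oracle_state_apply(net, state, i)
      if (is.null(s2)) next
      if (oracle_dominates(s2, seed)) return(TRUE)
      if (recurse(s2, depth + 1L)) return(TRUE)
    }
    FALSE
  }
  recurse(state0, 0L)
}

# exhaustive minimal-seed enumeration via the oracle: every multiset of
# total count <= max_seed_size, filtered to the igniting ones with no
# igniting proper sub-multiset
oracle_all_seeds <- function(ids, total) {
  if (length(ids) == 0L) return(if (total == 0L) list(integer(0)) else list())
  out <- list()
  for (k in total:0) {
    for (r in oracle_all_seeds(ids[-1], total - k)) {
      v <- c(if (k > 0L) setNames(k, ids[1]) else integer(0), r)
      out <- c(out, list(v))
    }
  }
  out
}

oracle_minimal_seeds <- function(net, max_seed_size, max_steps) {
  ids <- sort(net$species$id[net$species$role == "internal"])
  cands <- list()
  for (tot in seq_len(max_seed_size)) {
    cands <- c(cands, Filter(length, oracle_all_seeds(ids, tot)))
  }
  ok <- vapply(cands, function(s) oracle_ignites(net, s, max_steps), logical(1))
  winners <- cands[ok]
  contains <- function(a, b) {
    all(names(b) %in% names(a)) && all(a[names(b)] >= b)
  }
  minimal <- Filter(function(s) {
    !any(vapply(winners, function(w)
      !identical(w, s) && contains(s, w), logical(1)))
  }, winners)
  minimal
}

seed_key <- function(s) paste0(names(s), ":", s, collapse = ",")

# random small valid networks: up to n_sp species (some food/waste), up
# to n_rx reactions with counts in 1..2, occasional catalysts
random_network <- function(n_sp = 5L, n_rx = 4L) {
  repeat {
    sp <- paste0("S", seq_len(sample(2:n_sp, 1)))
    n <- length(sp)
    role <- rep("internal", n)
    if (n >= 3L && stats::runif(1) < 0.7) role[n] <- "food"
    if (n >= 4L && stats::runif(1) < 0.4) role[n - 1L] <- "waste"
    internal <- sp[role == "internal"]
    food <- sp[role == "food"]
    waste <- sp[role == "waste"]
    k <- sample(seq_len(n_rx), 1)
    ids <- paste0("R", seq_len(k))
    mk_side <- function(pool, min_n = 1L) {
      m <- sample(min_n:min(2L, length(pool)), 1)
      picks <- sample(pool, m)
      setNames(sample(1:2, m, replace = TRUE), picks)
    }
    rx <- lapply(seq_len(k), function(i) {
      re <- mk_side(c(internal, food))
      pr <- mk_side(c(internal, waste))
      ca <- setNames(integer(0), character(0))
      cat_pool <- setdiff(internal, names(re))
      if (length(cat_pool) && stats::runif(1) < 0.3) {
        ca <- setNames(1L, sample(cat_pool, 1))
      }
      list(re = re, pr = pr, ca = ca)
    })
    used <- unique(unlist(lapply(rx, function(r) names(c(r$re, r$pr, r$ca)))))
    if (!all(sp %in% used)) next
    net <- tryCatch(
      reaction_network(
        species = tibble::tibble(id = sp, name = sp, role = role),
        reactions = tibble::tibble(
          id = ids,
          reactants = lapply(rx, `[[`, "re"),
          products = lapply(rx, `[[`, "pr"),
          catalysts = lapply(rx, `[[`, "ca"))),
      error = function(e) NULL)
    if (!is.null(net)) return(net)
  }
}

# random seed multiset over a network's internal species
random_seed <- function(net, max_total = 3L) {
  ids <- net$species$id[net$species$role == "internal"]
  tot <- sample(seq_len(max_total), 1)
  picks <- sample(ids, min(tot, length(ids)), replace = TRUE)
  v <- table(picks)
  setNames(as.integer(v), names(v))
}
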