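#' Limited versus unlimited hereditary potential (S/N space)
#'
#' Classifies a replicator by the number of its possible stable states
#' `S` against the population size `N`. With only one stable state there
#' is no variation at all (an exact replicator); a lone individual is no
#' population; when the population outnumbers the possible variants
#' (`N > S`) heredity is limited; when `N <= S` it is unlimited and can
#' support open-ended evolution. The boundary `N == S` belongs to the
#' unlimited domain.
#'
#' Note on symbols: `S` here is a *state count* (see
#' [sequence_state_count()]), not the parent-offspring *similarity*
#' returned by [expected_similarity()]; the two quantities share a letter
#' in the literature but never mix in this package.
#'
#' @param S number of possible stable states: a positive number, `Inf`,
#'   or a `replikit_bigcount` from [sequence_state_count()].
#' @param N population size (positive integer or `Inf`).
#' @return One of `"no_variation_exact"`, `"no_population"`,
#'   `"limited_hereditary"`, `"unlimited_hereditary"`.
#' @examples
#' classify_sn(1, 1000)                          # no variation at all
#' classify_sn(4, 100)                           # limited
#' classify_sn(sequence_state_count(30, 4), 1e6) # unlimited
#' @export
classify_sn <- function(S, N) {
  if (!inherits(S, "replikit_bigcount")) {
    if (!is.numeric(S) || length(S) != 1L || is.na(S) || S < 1 ||
        (is.finite(S) && S != floor(S)))
      stop("S must be a positive integer count or Inf")
  }
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 ||
      (is.finite(N) && N != floor(N)))
    stop("N must be a positive integer count or Inf")
  if (state_count_cmp(S, 1) == 0L) return("no_variation_exact")
  if (is.finite(N) && N == 1) return("no_population")
  if (state_count_cmp(S, N) < 0L) "limited_hereditary" else "unlimited_hereditary"
}

#' Parameters of the variability--heredity model
#'
#' A replicator's information content is a set of `I` features
#' (modules). A fraction `V` of them is variable - able to change state
#' during the entity's lifetime without destroying it - and a
#' sub-fraction `H <= V` is heritable: changes there can be passed on by
#' copying (the genotype). Two per-module probabilities drive the
#' dynamics: `upsilon`, the probability that a variable module changes
#' over one inter-replication interval, and `mu`, the probability that a
#' heritable module is miscopied during replication. `epsilon` is the
#' probability that a miscopied module lands back on its original state
#' (backmutation); with a uniform miscopy over an inventory of `A`
#' symbols it equals `1/(A-1)` (see [default_epsilon()]).
#'
#' @param I total feature count (positive integer).
#' @param V fraction of I that is variable, in `[0, 1]`.
#' @param H fraction of I that is heritable, in `[0, V]`.
#' @param upsilon per-module lifetime change probability.
#' @param mu per-module copy error probability.
#' @param epsilon per-module backmutation probability; default 0 (large
#'   inventory).
#' @return An object of class `vh_params`. Module counts `n_variable` and
#'   `n_heritable` are the fractions rounded to the nearest integer with
#'   the heritable count capped at the variable count, for use by the
#'   simulator.
#' @examples
#' vh_params(I = 100, V = 0.5, H = 0.2, upsilon = 0.1, mu = 0.01)
#' @export
vh_params <- function(I, V, H, upsilon = 0, mu = 0, epsilon = 0) {
  stopifnot(length(I) == 1L, length(V) == 1L, length(H) == 1L)
  if (is.na(I) || I < 1 || I != floor(I)) stop("I must be a positive integer")
  if (is.na(V) || V < 0 || V > 1) stop("V must be in [0, 1]")
  if (is.na(H) || H < 0) stop("H must be in [0, V]")
  if (H > V) stop("invariant violated: H must not exceed V")
  for (p in list(upsilon = upsilon, mu = mu, epsilon = epsilon)) {
    if (is.na(p) || p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  }
  n_var <- round(I * V)
  n_her <- min(round(I * H), n_var)
  structure(list(I = as.integer(I), V = V, H = H, upsilon = upsilon,
                 mu = mu, epsilon = epsilon,
                 n_variable = as.integer(n_var),
                 n_heritable = as.integer(n_her)),
            class = "vh_params")
}

#' @export
print.vh_params <- function(x, ...) {
  cat(sprintf("<vh_params> I = %d, V = %g (%d modules), H = %g (%d modules), upsilon = %g, mu = %g, epsilon = %g\n",
              x$I, x$V, x$n_variable, x$H, x$n_heritable,
              x$upsilon, x$mu, x$epsilon))
  invisible(x)
}

#' Expected parent--offspring similarity
#'
#' The closed-form expected number of identical features between a
#' parent and its offspring, counted at the offspring's birth:
#' \deqn{S = I(1-V) + I(V-H)(1-\upsilon) + I H (1-\upsilon)(1-\mu) +
#'       I H \upsilon \mu \epsilon.}
#' The four terms are the stable part (never changes), the variable
#' non-heritable part that did not change during the parent's lifetime,
#' the heritable modules neither changed during lifetime nor miscopied,
#' and the heritable modules changed during lifetime and then miscopied
#' straight back to the original state (backmutation, probability
#' `epsilon` per miscopy).
#'
#' Heritable modules are compared against the parent's state at its own
#' birth; all other modules against the parent's current state. The
#' simulator's `"as_printed"` convention in [measure_similarity()]
#' reproduces this formula exactly (see the package vignette for the
#' discussion of this reference convention).
#'
#' @param params a [vh_params()].
#' @return The expected similarity, a number in `[I(1-V), I]`.
#' @examples
#' expected_similarity(vh_params(100, V = 0.5, H = 0.2,
#'                               upsilon = 0.1, mu = 0.01))  # 94.82
#' @export
expected_similarity <- function(params) {
  stopifnot(inherits(params, "vh_params"))
  I <- params$I
  V <- params$V
  H <- params$H
  u <- params$upsilon
  m <- params$mu
  e <- params$epsilon
  I * (1 - V) + I * (V - H) * (1 - u) + I * H * (1 - u) * (1 - m) +
    I * H * u * m * e
}

#' Default backmutation probability
#'
#' Under a uniform miscopy to one of the `A - 1` non-current symbols, a
#' module that changed away from its original state is copied back to it
#' with probability `1/(A-1)`: certainty for a binary inventory, and
#' negligible for large inventories.
#'
#' @param A inventory (alphabet) size, at least 2.
#' @return `1/(A-1)`.
#' @examples
#' default_epsilon(2)    # 1
#' default_epsilon(5)    # 0.25
#' default_epsilon(1e6)  # effectively 0
#' @export
default_epsilon <- function(A) {
  if (!is.numeric(A) || length(A) != 1L || is.na(A) || A < 2 || A != floor(A))
    stop("inventory size A must be an integer >= 2")
  1 / (A - 1)
}

#' Classify a replicator in the V/H space
#'
#' * `V = 0`: an exact replicator - holistic, non-informational, with no
#'   variability at all.
#' * `V > 0, H = 0`: a variable replicator - it can acquire changes but
#'   cannot pass any of them on; still non-informational.
#' * `H > 0`: an informational replicator; when a population context is
#'   supplied the hereditary potential is refined into limited versus
#'   unlimited via [classify_sn()].
#' * `V = H = 1`: additionally flagged as the hypothetical ideal
#'   replicator, which can change anywhere and pass on every change.
#'
#' @param params a [vh_params()].
#' @param S,N optional state count and population size forwarded to
#'   [classify_sn()] to refine informational replicators.
#' @return A one-row tibble with columns `label`, `informational`,
#'   `ideal`, `hereditary_potential` (NA unless refined).
#' @examples
#' classify_vh(vh_params(10, V = 0, H = 0))
#' classify_vh(vh_params(10, V = 0.4, H = 0))
#' classify_vh(vh_params(10, V = 1, H = 1))
#' @export
classify_vh <- function(params, S = NULL, N = NULL) {
  stopifnot(inherits(params, "vh_params"))
  V <- params$V
  H <- params$H
  if (V == 0) {
    label <- "exact_replicator"
    informational <- FALSE
  } else if (H == 0) {
    label <- "variable_replicator"
    informational <- FALSE
  } else {
    label <- "informational_replicator"
    informational <- TRUE
  }
  hereditary <- NA_character_
  if (informational && !is.null(S) && !is.null(N)) {
    hereditary <- classify_sn(S, N)
  }
  tibble::tibble(label = label, informational = informational,
                 ideal = V == 1 && H == 1,
                 hereditary_potential = hereditary)
}

#' Profile of a multiplying entity for the hierarchy classifier
#'
#' @param regenerates can the entity produce at least one entity
#'   equivalent to itself?
#' @param order_n autocatalytic order (see [classify_order()]).
#' @param g,d growth and decay rates per unit time.
#' @param V,H variable and heritable fractions as in [vh_params()].
#' @param has_development is the non-heritable part rebuilt by a
#'   developmental process (a declared property, not an inferred one)?
#' @return An object of class `hierarchy_profile`.
#' @seealso [classify_hierarchy()]
#' @export
hierarchy_profile <- function(regenerates, order_n, g, d, V, H,
                              has_development = FALSE) {
  stopifnot(is.logical(regenerates), length(regenerates) == 1L)
  if (H > V) stop("invariant violated: H must not exceed V")
  if (H > 0 && V == 0) stop("inconsistent profile: H > 0 with V = 0")
  structure(list(regenerates = regenerates, order_n = as.integer(order_n),
                 g = g, d = d, V = V, H = H,
                 has_development = isTRUE(has_development)),
            class = "hierarchy_profile")
}

#' Hierarchy of multiplying entities
#'
#' The decision chain of the replicator hierarchy; each deeper label
#' presupposes every capability above it:
#' 1. not regenerating: `not_multiplying`;
#' 2. regenerating but order 1 or `g <= d`: sequential replacement only
#'    (`regenerator_sequential_replacement`);
#' 3. autocatalytic (order >= 2, `g > d`) with `V = 0`:
#'    `exact_replicator`;
#' 4. `V > 0, H = 0`: `variable_replicator` (changes arise but cannot be
#'    passed on);
#' 5. `H > 0`: `informational_replicator`;
#' 6. informational with development building the non-heritable part:
#'    `reproducer` (e.g. an asexual organism).
#'
#' @param profile a [hierarchy_profile()].
#' @return The deepest applicable label.
#' @examples
#' # glycolaldehyde in the formose core: order 2, no variability
#' classify_hierarchy(hierarchy_profile(TRUE, 2, g = 1, d = 0.1,
#'                                      V = 0, H = 0))
#' # an asexual organism: informational with development
#' classify_hierarchy(hierarchy_profile(TRUE, 2, g = 1, d = 0.1,
#'                                      V = 0.9, H = 0.1,
#'                                      has_development = TRUE))
#' @export
classify_hierarchy <- function(profile) {
  stopifnot(inherits(profile, "hierarchy_profile"))
  p <- profile
  if (!p$regenerates) return("not_multiplying")
  if (p$order_n < 2L || p$g <= p$d) return("regenerator_sequential_replacement")
  if (p$V == 0) return("exact_replicator")
  if (p$H == 0) return("variable_replicator")
  if (p$has_development) return("reproducer")
  "informational_replicator"
}
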