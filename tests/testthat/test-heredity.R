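test_that("S/N classification covers all four domains and the N = S boundary", {
  expect_equal(classify_sn(1, 1000), "no_variation_exact")
  expect_equal(classify_sn(1, 1), "no_variation_exact")  # S = 1 takes priority
  expect_equal(classify_sn(4, 1), "no_population")
  expect_equal(classify_sn(4, 100), "limited_hereditary")
  expect_equal(classify_sn(sequence_state_count(30, 4), 1e6),
               "unlimited_hereditary")
  # boundary N = S belongs to the unlimited domain
  expect_equal(classify_sn(100, 100), "unlimited_hereditary")
  expect_equal(classify_sn(99, 100), "limited_hereditary")
  expect_equal(classify_sn(Inf, 1e9), "unlimited_hereditary")
  expect_error(classify_sn(0, 10), "positive")
  expect_error(classify_sn(4, 0), "positive")
})

test_that("scaling S and N together never flips the domain unless the boundary crosses", {
  set.seed(5)
  for (i in 1:20) {
    S <- sample(2:1000, 1)
    N <- sample(2:1000, 1)
    k <- sample(2:50, 1)
    expect_equal(classify_sn(S * k, N * k), classify_sn(S, N))
  }
})

test_that("sequence state counts are exact, including beyond double precision", {
  expect_equal(sequence_state_count(0, 4), 1)
  expect_equal(sequence_state_count(3, 4), 64)  # all 4^3 triplets
  expect_equal(sequence_state_count(1, 1), 1)
  big <- sequence_state_count(40, 4)
  expect_s3_class(big, "replikit_bigcount")
  # 4^40 = 2^80, computed independently by repeated decimal doubling
  chk <- "1"
  dbl <- function(s) {
    d <- rev(as.integer(strsplit(s, "")[[1]])) * 2L
    carry <- 0L
    for (j in seq_along(d)) {
      v <- d[j] + carry
      d[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      d <- c(d, carry %% 10L)
      carry <- carry %/% 10L
    }
    paste(rev(d), collapse = "")
  }
  for (i in 1:80) chk <- dbl(chk)
  expect_equal(format(big), chk)
  # ordering against population sizes is exact
  expect_equal(classify_sn(big, 1e15), "unlimited_hereditary")
})

test_that("vh_params enforces H <= V and valid probabilities", {
  p <- vh_params(100, V = 0.5, H = 0.2, upsilon = 0.1, mu = 0.01)
  expect_equal(p$n_variable, 50L)
  expect_equal(p$n_heritable, 20L)
  expect_error(vh_params(100, V = 0.2, H = 0.5), "H must not exceed V")
  expect_error(vh_params(100, V = 0.5, H = 0.2, upsilon = 1.5), "0, 1")
  expect_error(vh_params(0, V = 0, H = 0), "positive integer")
  # rounding keeps the heritable count within the variable count
  q <- vh_params(10, V = 0.26, H = 0.25)
  expect_lte(q$n_heritable, q$n_variable)
})

test_that("expected similarity: closed form and its limiting cases", {
  # V = 0: only the stable term remains and equals I
  expect_equal(expected_similarity(vh_params(100, 0, 0, upsilon = 0.7,
                                             mu = 0.9)), 100)
  # no lifetime change and no miscopy: full identity whatever V, H
  expect_equal(expected_similarity(vh_params(100, 0.5, 0.2)), 100)
  # frozen regression value, confirmed against the Monte-Carlo oracle
  expect_equal(expected_similarity(vh_params(100, 0.5, 0.2, upsilon = 0.1,
                                             mu = 0.01)), 94.82)
})

test_that("expected similarity is bounded and monotone in the error rates", {
  grid <- expand.grid(V = c(0, 0.3, 0.7, 1), Hf = c(0, 0.5, 1),
                      u = c(0, 0.1, 0.4), m = c(0, 0.1, 0.4))
  for (i in seq_len(nrow(grid))) {
    V <- grid$V[i]
    H <- V * grid$Hf[i]
    s <- expected_similarity(vh_params(100, V, H, grid$u[i], grid$m[i]))
    expect_lte(s, 100)
    expect_gte(s, 100 * (1 - V))
    # with epsilon = 0, raising upsilon or mu never raises similarity
    s_u <- expected_similarity(vh_params(100, V, H, min(grid$u[i] + 0.1, 1),
                                         grid$m[i]))
    s_m <- expected_similarity(vh_params(100, V, H, grid$u[i],
                                         min(grid$m[i] + 0.1, 1)))
    expect_lte(s_u, s + 1e-12)
    expect_lte(s_m, s + 1e-12)
  }
})

test_that("default backmutation probability follows the inventory size", {
  expect_equal(default_epsilon(2), 1)     # binary inventory: certainty
  expect_equal(default_epsilon(5), 0.25)
  expect_lt(default_epsilon(1e6), 1e-5)   # large inventory: negligible
  expect_error(default_epsilon(1), ">= 2")
})

test_that("V/H classification distinguishes exact, variable, informational, ideal", {
  expect_equal(classify_vh(vh_params(10, 0, 0))$label, "exact_replicator")
  v <- classify_vh(vh_params(10, 0.4, 0))
  expect_equal(v$label, "variable_replicator")
  expect_false(v$informational)
  i <- classify_vh(vh_params(10, 0.5, 0.3))
  expect_equal(i$label, "informational_replicator")
  expect_true(i$informational)
  ideal <- classify_vh(vh_params(10, 1, 1))
  expect_true(ideal$ideal)
  # refinement by population context
  lim <- classify_vh(vh_params(10, 0.5, 0.3), S = 4, N = 100)
  expect_equal(lim$hereditary_potential, "limited_hereditary")
  unl <- classify_vh(vh_params(10, 0.5, 0.3), S = sequence_state_count(30, 4),
                     N = 1e6)
  expect_equal(unl$hereditary_potential, "unlimited_hereditary")
})

test_that("hierarchy classifier walks the decision chain", {
  expect_equal(classify_hierarchy(hierarchy_profile(FALSE, 0, 1, 0, 0, 0)),
               "not_multiplying")
  expect_equal(classify_hierarchy(hierarchy_profile(TRUE, 1, 1, 0, 0, 0)),
               "regenerator_sequential_replacement")
  expect_equal(classify_hierarchy(hierarchy_profile(TRUE, 2, 0.5, 0.5, 0, 0)),
               "regenerator_sequential_replacement")  # g <= d
  # formose glycolaldehyde: order 2, viable kinetics, no variability
  expect_equal(classify_hierarchy(hierarchy_profile(TRUE, 2, 1, 0.1, 0, 0)),
               "exact_replicator")
  expect_equal(classify_hierarchy(hierarchy_profile(TRUE, 2, 1, 0.1, 0.4, 0)),
               "variable_replicator")
  expect_equal(classify_hierarchy(hierarchy_profile(TRUE, 2, 1, 0.1, 0.5, 0.2)),
               "informational_replicator")
  # asexual organism: informational plus development
  expect_equal(classify_hierarchy(hierarchy_profile(TRUE, 2, 1, 0.1, 0.9, 0.1,
                                                    has_development = TRUE)),
               "reproducer")
  expect_error(hierarchy_profile(TRUE, 2, 1, 0.1, 0, 0.2), "H must not exceed")
})

test_that("hierarchy labels subsume all shallower capabilities", {
  depth <- c(not_multiplying = 0, regenerator_sequential_replacement = 1,
             exact_replicator = 2, variable_replicator = 3,
             informational_replicator = 4, reproducer = 5)
  set.seed(13)
  for (i in 1:60) {
    reg <- stats::runif(1) < 0.8
    n <- sample(0:3, 1)
    g <- stats::runif(1)
    d <- stats::runif(1)
    V <- stats::runif(1)
    H <- stats::runif(1) * V
    dev <- stats::runif(1) < 0.5
    prof <- hierarchy_profile(reg, n, g, d, V, H, dev)
    lab <- classify_hierarchy(prof)
    lvl <- depth[[lab]]
    # each level certifies every capability beneath it
    if (lvl >= 1) expect_true(prof$regenerates)
    if (lvl >= 2) {
      expect_gte(prof$order_n, 2)
      expect_gt(prof$g, prof$d)
    }
    if (lvl >= 3) expect_gt(prof$V, 0)
    if (lvl >= 4) expect_gt(prof$H, 0)
    if (lvl >= 5) expect_true(prof$has_development)
  }
})
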