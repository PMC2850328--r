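make_entity <- function(I = 10L, nV = 6L, nH = 3L, A = 4L) {
  modular_entity(rep(1L, I), variable_idx = (I - nV + 1L):I,
                 heritable_idx = (I - nH + 1L):I, A = A)
}

test_that("lifetime mutation respects the variable index set", {
  e <- make_entity()
  expect_identical(mutate_lifetime(e, 0)$features, e$features)
  set.seed(1)
  m <- mutate_lifetime(e, 1)
  # every variable module changed (to a different symbol), others untouched
  expect_true(all(m$features[e$variable_idx] != e$features[e$variable_idx]))
  fixed <- setdiff(seq_along(e$features), e$variable_idx)
  expect_identical(m$features[fixed], e$features[fixed])
  # binary inventory with certain change flips deterministically
  b <- modular_entity(rep(1L, 4), 1:4, 1:2, A = 2)
  expect_true(all(mutate_lifetime(b, 1)$features == 2L))
})

test_that("lifetime change counts are binomial", {
  set.seed(2)
  I <- 10000L
  e <- modular_entity(rep(1L, I), seq_len(I), integer(0), A = 4)
  changed <- vapply(1:20, function(i) {
    sum(mutate_lifetime(e, 0.1)$features != e$features)
  }, numeric(1))
  # mean 1000, sd sqrt(I * .1 * .9) = 30; the 20-trial mean has se ~ 6.7
  expect_lt(abs(mean(changed) - 1000), 3 * 30 / sqrt(20))
})

test_that("replication copies the current heritable part and develops the rest", {
  set.seed(3)
  e <- make_entity()
  # acquire a lifetime change in a heritable module and a non-heritable one
  e2 <- e
  e2$features[e$heritable_idx[1]] <- 2L
  nh <- setdiff(e$variable_idx, e$heritable_idx)[1]
  e2$features[nh] <- 3L
  off <- replicate_entity(e2, mu = 0)
  # heritable change inherited; non-heritable module developed to birth state
  expect_equal(off$features[e$heritable_idx[1]], 2L)
  expect_equal(off$features[nh], e$birth_features[nh])
  # the offspring's birth snapshot is its own initial state
  expect_identical(off$features, off$birth_features)
  # certain miscopy on a binary inventory flips every heritable module
  b <- modular_entity(rep(1L, 4), 1:4, 1:4, A = 2)
  expect_true(all(replicate_entity(b, mu = 1)$features == 2L))
})

test_that("similarity conventions differ only on lifetime-changed heritable modules", {
  e <- make_entity()
  off <- replicate_entity(e, mu = 0)
  expect_equal(measure_similarity(e, off, "as_printed"), 10L)
  expect_equal(measure_similarity(e, off, "current_parent"), 10L)
  # change a heritable module after birth, then copy it faithfully
  e$features[e$heritable_idx[1]] <- 2L
  off <- replicate_entity(e, mu = 0)
  # against the parent's birth state the changed module does not match
  expect_equal(measure_similarity(e, off, "as_printed"), 9L)
  # against the current parent it does
  expect_equal(measure_similarity(e, off, "current_parent"), 10L)
  bad <- modular_entity(rep(1L, 4), 1:2, 1:2, A = 4)
  expect_error(measure_similarity(e, bad), "mismatched")
})

test_that("Monte-Carlo similarity matches the closed form at a spot check", {
  p <- vh_params(100, V = 0.5, H = 0.2, upsilon = 0.1, mu = 0.05)
  mc <- similarity_experiment(p, A = 4, reps = 20000, seed = 4)
  closed <- expected_similarity(vh_params(100, 0.5, 0.2, 0.1, 0.05,
                                          epsilon = default_epsilon(4)))
  expect_lt(abs(mc$mean_similarity - closed), 4 * mc$se)
  # degenerate corner: nothing changes anywhere
  still <- similarity_experiment(vh_params(100, 0.5, 0.2), A = 4,
                                 reps = 500, seed = 5)
  expect_equal(still$mean_similarity, 100)
  expect_equal(still$se, 0)
})

test_that("heritability contract: mu = 0 passes lifetime changes to all descendants", {
  set.seed(6)
  e <- make_entity()
  e$features[e$heritable_idx] <- c(2L, 3L, 4L)
  child <- replicate_entity(e, mu = 0)
  grandchild <- replicate_entity(child, mu = 0)
  expect_equal(grandchild$features[e$heritable_idx], c(2L, 3L, 4L))
  # H = 0: no lifetime change ever reaches an offspring
  f <- modular_entity(rep(1L, 10), 1:6, integer(0), A = 4)
  f <- mutate_lifetime(f, 1)
  off <- replicate_entity(f, mu = 0)
  expect_true(all(off$features == 1L))
})

test_that("trajectories are bit-reproducible given config and seed", {
  cfg <- simulation_config(I = 20, A = 4, V_frac = 0.5, H_frac = 0.2,
                           upsilon = 0.1, mu = 0.05,
                           types = tibble::tibble(name = c("a", "b"),
                                                  g = c(0.4, 0.3), d = 0.1,
                                                  n0 = c(30, 30)),
                           generations = 15, carrying_capacity = 200)
  t1 <- run_simulation(cfg, seed = 7)
  t2 <- run_simulation(cfg, seed = 7)
  expect_identical(tidy(t1), tidy(t2))
  t3 <- run_simulation(cfg, seed = 8)
  expect_false(identical(tidy(t1), tidy(t3)))
})

test_that("g = 0 populations only decay, and extinction is recorded", {
  cfg <- simulation_config(types = tibble::tibble(name = "x", g = 0, d = 0.5,
                                                  n0 = 40),
                           generations = 50)
  traj <- run_simulation(cfg, seed = 9)
  counts <- tidy(traj)$count
  expect_true(all(diff(counts) <= 0))
  expect_equal(glance(traj)$status, "extinct")
  expect_equal(min(counts), 0)
})

test_that("without death, two growing types still shift in frequency", {
  cfg <- simulation_config(types = tibble::tibble(name = c("fast", "slow"),
                                                  g = c(0.5, 0.2), d = 0,
                                                  n0 = c(50, 50)),
                           generations = 25)
  rec <- tidy(run_simulation(cfg, seed = 10))
  # both types grow in absolute number
  final <- rec[rec$generation == 25, ]
  expect_true(all(final$count > 50))
  # but the slow type's frequency falls
  f0 <- 0.5
  f_end <- final$count[final$type == "slow"] / final$pop_size[1]
  expect_lt(f_end, f0)
})

test_that("carrying capacity caps the population via uniform culling", {
  cfg <- simulation_config(types = tibble::tibble(name = "x", g = 0.8, d = 0,
                                                  n0 = 50),
                           generations = 20, carrying_capacity = 120)
  rec <- tidy(run_simulation(cfg, seed = 11))
  expect_true(all(rec$pop_size <= 120))
})

test_that("dilution matches the two-type closed-form expectation", {
  res <- dilution_experiment(0.5, 0.25, generations = 15, reps = 60,
                             n0 = 100, seed = 12)
  # closed form is monotone decreasing and the simulation tracks it
  expect_true(all(diff(res$expected_slow_freq) < 0))
  expect_true(all(abs(res$mean_slow_freq - res$expected_slow_freq) <=
                    3 * pmax(res$se, 1e-12)))
  expect_lt(res$mean_slow_freq[15], 0.5)
  # symmetric rates stay at one half in expectation
  sym <- dilution_experiment(0.4, 0.4, generations = 10, reps = 60,
                             n0 = 100, seed = 13)
  expect_true(all(sym$expected_slow_freq == 0.5))
  expect_true(all(abs(sym$mean_slow_freq - 0.5) <= 3 * pmax(sym$se, 1e-12)))
  # no dynamics at zero generations
  none <- dilution_experiment(0.5, 0.25, generations = 0)
  expect_equal(none$mean_slow_freq, 0.5)
})

test_that("autoplot returns a ggplot of the count trajectories", {
  cfg <- simulation_config(generations = 5)
  p <- autoplot(run_simulation(cfg, seed = 14))
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_similarity_surface(n = 11), "ggplot")
})
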