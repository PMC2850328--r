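test_that("the bird alone ignites the cycle, the nest alone dies", {
  bn <- fixture("bird_nest")
  a1 <- can_ignite(bn, c(A1 = 1), max_steps = 10)
  expect_equal(a1$status, "ignites")
  expect_equal(a1$witness, c("R1", "R2"))
  expect_equal(can_ignite(bn, c(B = 1), max_steps = 10)$status, "dies")
  expect_equal(can_ignite(bn, c(A2 = 1, B = 1), max_steps = 10)$status,
               "ignites")
  # a nesting bird without its nest is stuck
  expect_equal(can_ignite(bn, c(A2 = 1), max_steps = 10)$status, "dies")
  expect_error(can_ignite(bn, c(Z = 1)), "unknown species")
  expect_error(can_ignite(bn, c(x1 = 1)), "non-food")
})

test_that("replication ratios are exact rationals: formose 2, Calvin 4/3", {
  expect_true(replication_ratio(fixture("formose"), "glycolaldehyde") ==
                rational(2))
  expect_true(replication_ratio(fixture("calvin"), "PGA") == rational(4, 3))
  expect_true(replication_ratio(fixture("rna_only"), "RNA") == rational(2))
  # the nest has no pure seed at any size
  expect_true(replication_ratio(fixture("bird_nest"), "B") == rational(0))
  expect_error(replication_ratio(fixture("formose"), "formaldehyde"),
               "internal")
})

test_that("sequential replacement: ratio 1 and order 1 under equivalence", {
  net <- parse_network(c("R1: A + x -> A2 + y", "R2: A2 + x -> A + y",
                         "food: x", "waste: y"))
  # two-phase cycle: each pure seed only sustains
  expect_true(replication_ratio(net, "A") == rational(1))
  ord <- classify_order(net, "A")
  expect_equal(ord$label, "sequential_replacement")
  expect_equal(ord$n, 1L)
  # one-step replacement visible only through declared equivalence
  one <- parse_network(c("R1: A + x -> Aprime + y", "food: x", "waste: y"))
  expect_equal(classify_order(one, "A")$label, "no_cycle")
  expect_equal(classify_order(one, "A")$n, 0L)
  eq <- classify_order(one, "A", equivalence = list(c("A", "Aprime")))
  expect_equal(eq$label, "sequential_replacement")
  expect_equal(eq$n, 1L)
})

test_that("orders: formose glycolaldehyde is 2; plain conversion is 0", {
  ord <- classify_order(fixture("formose"), "glycolaldehyde")
  expect_equal(ord$n, 2L)
  expect_equal(ord$label, "autocatalytic")
  none <- parse_network(c("R1: A + x -> B + y", "food: x", "waste: y"))
  expect_equal(classify_order(none, "A")$n, 0L)
})

test_that("minimal seeds of the bird-nest cycle are {A1} and {A2, B}", {
  seeds <- minimal_seeds(fixture("bird_nest"))
  expect_false(attr(seeds, "incomplete"))
  keys <- vapply(seeds, seed_key, character(1))
  expect_equal(sort(keys), c("A1:1", "A2:1,B:1"))
  # no pure-nest seed at any enumerated size
  expect_false(any(grepl("^B:", keys)))
})

test_that("Calvin: smallest mixed seed has two molecules, PGA-only needs three", {
  cal <- fixture("calvin")
  seeds <- minimal_seeds(cal, max_seed_size = 3)
  sizes <- vapply(seeds, sum, numeric(1))
  expect_equal(min(sizes), 2)
  keys <- vapply(seeds, seed_key, character(1))
  expect_true("DHAP:1,Se7P:1" %in% keys)
  # no single molecule ignites the network
  expect_false(any(sizes == 1))
  pga_only <- minimal_seeds(cal, restrict = "PGA")
  expect_equal(length(pga_only), 1L)
  expect_equal(pga_only[[1]], c(PGA = 3L))
})

test_that("roles: autonomous bird, dependent nesting bird, autoinductive nest", {
  bn <- fixture("bird_nest")
  seeds <- minimal_seeds(bn)
  expect_equal(classify_role(bn, "A1", seeds), "autonomous_obligate")
  expect_equal(classify_role(bn, "A2", seeds), "dependent")
  expect_equal(classify_role(bn, "B", seeds), "autoinductive_facultative")
  # nest per-turn ratio exceeds one even though it has no pure seed
  rep <- analyze_network(bn)
  tb <- tidy(rep)
  expect_gt(tb$ratio_value[tb$species == "B"], 1)
  expect_true(all(tb$is_autocatalytic))
  expect_true(all(tb$order_n >= 2))
})

test_that("heterocatalytic product of the simple bird cycle is not a replicator", {
  bc <- fixture("bird_catalyst")
  tb <- tidy(analyze_network(bc))
  expect_equal(tb$role[tb$species == "A"], "autonomous_obligate")
  expect_equal(tb$role[tb$species == "B"], "non_autocatalytic")
  expect_false(tb$is_autocatalytic[tb$species == "B"])
})

test_that("obligate gene-enzyme coupling: neither partner ignites alone", {
  ro <- fixture("rna_protein_obligate")
  expect_equal(can_ignite(ro, c(DNA = 1))$status, "dies")
  expect_equal(can_ignite(ro, c(E = 1))$status, "dies")
  expect_equal(can_ignite(ro, c(DNA = 1, E = 1))$status, "ignites")
  tb <- tidy(analyze_network(ro))
  expect_equal(tb$role[tb$species == "DNA"], "dependent")
  expect_equal(tb$role[tb$species == "E"], "autoinductive_facultative")
})

test_that("reported autocatalysts have positive net production on a witness turn", {
  for (nm in c("formose", "bird_nest", "rna_only", "reductive_tca")) {
    net <- fixture(nm)
    rep <- analyze_network(net)
    for (seed in rep$minimal_seeds) {
      out <- can_ignite(net, seed)
      firing <- table(out$witness)
      delta <- net_stoichiometry(net, setNames(as.integer(firing),
                                               names(firing)))
      gains <- setNames(delta$net, delta$species)
      # the witness turn strictly increases at least one seed species
      expect_true(any(gains[names(seed)] > 0), label = nm)
    }
  }
})

test_that("ignition is monotone: any seed dominating an igniting seed ignites", {
  set.seed(11)
  checked <- 0
  while (checked < 40) {
    net <- random_network()
    seed <- random_seed(net)
    out <- can_ignite(net, seed, max_steps = 8)
    if (out$status != "ignites") next
    checked <- checked + 1
    bigger <- seed
    extra <- sample(names(seed), 1)
    bigger[extra] <- bigger[extra] + 1L
    expect_equal(can_ignite(net, bigger, max_steps = 9)$status, "ignites")
  }
})

test_that("kinetic viability compares growth against decay", {
  expect_equal(kinetic_viability(2, 0.5), "multiplying")
  expect_equal(kinetic_viability(1, 1), "replacing")
  expect_equal(kinetic_viability(0, 0.1), "depleting")
  expect_error(kinetic_viability(-1, 0), "non-negative")
})

test_that("report glance summarises seed structure", {
  gl <- glance(analyze_network(fixture("bird_nest")))
  expect_equal(gl$n_minimal_seeds, 2L)
  expect_equal(gl$min_seed_size, 1)
  expect_false(gl$incomplete)
})
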