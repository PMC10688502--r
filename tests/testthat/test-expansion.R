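test_that("neighbor_frontier is the neighbor union minus the exclusion set", {
  net <- path_network()
  expect_identical(neighbor_frontier(net, "b"), c("a", "c"))
  expect_identical(neighbor_frontier(net, net$nodes), character(0))
  expect_identical(neighbor_frontier(net, "b", exclude = net$nodes), character(0))
})

test_that("seed initialization draws one distinct protein per non-empty sub-network", {
  ds <- suppressMessages(generate_dataset(small_config(2)))
  avg <- average_expression(ds$expression)
  subs <- build_subnetworks(ds$ppi, activity_model(avg))
  wm <- build_weight_model(ds$ppi, avg, ds$bundle, subs)
  cfg <- expansion_config(n = 15, rng_seed = 123)
  st <- init_seeds(ds$ppi, subs, wm, cfg)
  seeds <- st$seed_ids
  expect_false(anyDuplicated(seeds) > 0)
  non_empty <- which(vapply(subs$v, length, integer(1)) > 0)
  expect_length(seeds, length(non_empty))
  for (j in seq_along(seeds))
    expect_true(seeds[j] %in% subs$v[[non_empty[j]]])
  # determinism of the seeded draw
  st2 <- init_seeds(ds$ppi, subs, wm, cfg)
  expect_identical(st2$seed_ids, seeds)
  # a different seed gives (generically) different draws
  st3 <- init_seeds(ds$ppi, subs, wm, expansion_config(n = 15, rng_seed = 321))
  expect_false(identical(st3$seed_ids, seeds))
})

test_that("a sub-network whose nodes are all taken contributes no seed", {
  fx <- manual_expansion_fixture(
    nodes = c("a", "b"),
    whole_edges = cbind(c("a"), c("b")),
    sub_v = list("a", "a"),  # both sub-networks offer only protein a
    sub_edges = list(cbind(character(0), character(0)),
                     cbind(character(0), character(0))),
    sub_w = list(numeric(0), numeric(0)),
    score_initial = c(a = 1, b = 2))
  expect_warning(
    st <- init_seeds(fx$ppi, fx$subnets, fx$weights, expansion_config(n = 1)),
    "skipped")
  expect_identical(st$seed_ids, "a")
})

test_that("expansion selects the global maximum over the per-sub-network maxima", {
  fx <- manual_expansion_fixture(
    nodes = c("a", "b", "c", "d"),
    whole_edges = cbind(c("a", "c", "b"), c("b", "d", "d")),
    sub_v = list(c("a", "b"), c("c", "d")),
    sub_edges = list(cbind("a", "b"), cbind("c", "d")),
    sub_w = list(0.4, 0.7),
    score_initial = c(a = 0, b = 0, c = 0, d = 0))
  st <- init_seeds(fx$ppi, fx$subnets, fx$weights,
                   expansion_config(n = 4, seeds = c("a", "c")))
  sel <- select_expansion_node(st)
  expect_identical(sel$node, "d")
  expect_identical(sel$index, 2L)
  expect_equal(sel$score, 0.7)
  expect_equal(score_w(st, "b", 1L), 0.4)
  expect_equal(score_w(st, "d", 2L), 0.7)
  expect_true(expansion_step(st))
  expect_identical(expansion_k(st), c("a", "c", "d"))
  # d entered the sub-network set it belongs to
  expect_true(st$in_ki[2, st$idx_of[["d"]]])
  expect_false(st$in_ki[1, st$idx_of[["d"]]])
})

test_that("zero-score frontier candidates are not expandable", {
  fx <- manual_expansion_fixture(
    nodes = c("a", "b"),
    whole_edges = cbind("a", "b"),
    sub_v = list(c("a", "b")),
    sub_edges = list(cbind("a", "b")),
    sub_w = list(0),
    score_initial = c(a = 0, b = 0))
  st <- init_seeds(fx$ppi, fx$subnets, fx$weights,
                   expansion_config(n = 2, seeds = "a"))
  expect_null(select_expansion_node(st))
  expect_false(expansion_step(st))
})

test_that("error correction swaps the weakest member for the strongest frontier protein", {
  fx <- manual_expansion_fixture(
    nodes = c("a", "b", "c"),
    whole_edges = cbind(c("a", "b"), c("c", "c")),
    sub_v = list("a", "b"),
    sub_edges = list(cbind(character(0), character(0)),
                     cbind(character(0), character(0))),
    sub_w = list(numeric(0), numeric(0)),
    score_initial = c(a = 0.1, b = 0.5, c = 0.4))
  st <- init_seeds(fx$ppi, fx$subnets, fx$weights,
                   expansion_config(n = 3, seeds = c("a", "b")))
  expect_true(error_correction_step(st))
  expect_identical(expansion_k(st), c("b", "c"))
  expect_identical(st$ids[st$removed], "a")

  # frontier maximum not exceeding the K minimum leaves the state unchanged
  expect_false(error_correction_step(st))
  expect_identical(expansion_k(st), c("b", "c"))
})

test_that("a protein can be removed only once; re-added members are immune", {
  fx <- manual_expansion_fixture(
    nodes = c("a", "b", "c"),
    whole_edges = cbind(c("a", "b"), c("c", "c")),
    sub_v = list("a", "b"),
    sub_edges = list(cbind(character(0), character(0)),
                     cbind(character(0), character(0))),
    sub_w = list(numeric(0), numeric(0)),
    score_initial = c(a = 0.1, b = 0.5, c = 0.4))
  st <- init_seeds(fx$ppi, fx$subnets, fx$weights,
                   expansion_config(n = 3, seeds = c("a", "b")))
  # pretend a was removed once before (i.e. it re-entered K afterwards)
  st$removed[st$idx_of[["a"]]] <- TRUE
  expect_true(error_correction_step(st))
  # c was added; a (the score minimum, already in the ledger) stayed
  expect_identical(expansion_k(st), c("a", "b", "c"))
})

test_that("run_expansion returns the seeds when n equals the seed count", {
  ds <- suppressMessages(generate_dataset(small_config(4)))
  avg <- average_expression(ds$expression)
  subs <- build_subnetworks(ds$ppi, activity_model(avg))
  wm <- build_weight_model(ds$ppi, avg, ds$bundle, subs)
  st <- init_seeds(ds$ppi, subs, wm, expansion_config(n = 10, rng_seed = 5))
  k0 <- length(st$seed_ids)
  pred <- run_expansion(ds$ppi, subs, wm, expansion_config(n = k0, rng_seed = 5))
  expect_identical(pred$protein, st$seed_ids)
  expect_true(all(pred$provenance == "seed"))
})

test_that("components unreachable from every seed force early termination below n", {
  # two components; sub-network and seeds confined to the first
  fx <- manual_expansion_fixture(
    nodes = c("a", "b", "x", "y", "z"),
    whole_edges = cbind(c("a", "x", "y"), c("b", "y", "z")),
    sub_v = list(c("a", "b")),
    sub_edges = list(cbind("a", "b")),
    sub_w = list(0.5),
    score_initial = c(a = 1, b = 2, x = 5, y = 5, z = 5))
  expect_warning(
    pred <- run_expansion(fx$ppi, fx$subnets, fx$weights,
                          expansion_config(n = 4, seeds = "a")),
    "stalled")
  expect_lt(nrow(pred), 4L)
  expect_true(attr(pred, "truncated"))
  expect_true(all(pred$protein %in% c("a", "b")))
})

test_that("identical inputs and seed give identical rankings", {
  ds <- suppressMessages(generate_dataset(small_config(7)))
  avg <- average_expression(ds$expression)
  subs <- build_subnetworks(ds$ppi, activity_model(avg))
  wm <- build_weight_model(ds$ppi, avg, ds$bundle, subs)
  cfg <- expansion_config(n_fraction = 1 / 4, rng_seed = 77)
  p1 <- suppressWarnings(run_expansion(ds$ppi, subs, wm, cfg))
  p2 <- suppressWarnings(run_expansion(ds$ppi, subs, wm, cfg))
  expect_identical(p1$protein, p2$protein)
  expect_identical(attr(p1, "removed"), attr(p2, "removed"))
})

test_that("the predicted set grows monotonically and stays consistent with the sub-network sets", {
  ds <- suppressMessages(generate_dataset(small_config(8)))
  avg <- average_expression(ds$expression)
  subs <- build_subnetworks(ds$ppi, activity_model(avg))
  wm <- build_weight_model(ds$ppi, avg, ds$bundle, subs)
  st <- init_seeds(ds$ppi, subs, wm, expansion_config(n = 12, rng_seed = 9))
  len <- length(st$k_order)
  for (iter in 1:10) {
    before <- length(st$k_order)
    expansion_step(st)
    expect_gte(length(st$k_order), before)
    error_correction_step(st)
    expect_gte(length(st$k_order), before)
    expect_false(anyDuplicated(st$k_order) > 0)
    # every sub-network set is inside K and inside its node universe
    for (i in seq_len(st$m)) {
      ki <- which(st$in_ki[i, ])
      expect_true(all(st$in_k[ki]))
      expect_true(all(st$v_in_sub[i, ki]))
    }
    # removed nodes are out of K unless re-added later by the mechanisms
    len <- length(st$k_order)
  }
})
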