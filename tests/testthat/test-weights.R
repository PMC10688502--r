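test_that("GO overlap weight matches its closed form", {
  expect_equal(go_weight(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(go_weight(c("a", "b"), c("c", "d")), 0)
  expect_equal(go_weight(c("a", "b", "c", "d"), c("a", "b")), 0.5)
  expect_equal(go_weight(character(0), c("a")), 0)
})

test_that("Pearson correlation and its standardization behave at the boundaries", {
  x <- c(1, 2, 3)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, c(6, 4, 2)), -1)
  expect_equal(pcc(x, c(1, 2, 4)), 0.9819805061, tolerance = 1e-8)
  expect_equal(pcc(x, c(5, 5, 5)), 0)           # zero variance convention
  expect_error(pcc(x, c(1, 2)), "equal length")
  expect_equal(gene_weight(x, x), 1)
  expect_equal(gene_weight(x, c(6, 4, 2)), 0)
  expect_equal(gene_weight(x, c(5, 5, 5)), 0.5) # no-information midpoint
})

test_that("complex membership weight matches its closed form", {
  expect_equal(complex_weight(4, 4, 4), 1)
  expect_equal(complex_weight(0, 3, 4), 0)
  expect_equal(complex_weight(2, 3, 4), 0.375)
  expect_equal(complex_weight(0, 0, 0), 0)
})

test_that("compartment selection uses a strict threshold and protein-count scoring", {
  subcell <- list(p1 = "A", p2 = "A", p3 = "A", p4 = "A", p5 = "A",
                  p6 = "A", p7 = "A", p8 = "A", p9 = "A", p10 = "A")
  sc <- subcellular_scoring(subcell, essentials = c("p1", "p2", "p3"),
                            proteins = names(subcell), reference = "pair",
                            ep = 1, p = 10)
  expect_equal(unname(sc$epi["A"]), 0.3)
  expect_identical(sc$selected, "A")

  # EPI equal to the threshold is NOT selected (strict >)
  expect_warning(
    sc2 <- subcellular_scoring(subcell, essentials = c("p1", "p2"),
                               proteins = names(subcell), reference = "pair",
                               ep = 2, p = 10),
    "no compartment selected")
  expect_length(sc2$selected, 0L)

  # protein-count scoring of the selected compartments
  sub3 <- c(lapply(stats::setNames(sprintf("e%03d", 1:200), sprintf("e%03d", 1:200)),
                   function(.) "big"),
            lapply(stats::setNames(sprintf("f%03d", 1:50), sprintf("f%03d", 1:50)),
                   function(.) "small"))
  sc3 <- subcellular_scoring(sub3, essentials = names(sub3),
                             proteins = names(sub3), reference = "pair",
                             ep = 1, p = 100)
  expect_equal(unname(sc3$scs[c("big", "small")]), c(1, 0.25))
})

test_that("subcellular node weights normalize by the network maximum", {
  scoring <- structure(list(epi = c(A = 0.5, B = 0.4, C = 0.3), ep_threshold = 0.1,
                            selected = c("A", "B", "C"),
                            scs = c(A = 1, B = 0.5, C = 0.25)),
                       class = "subcellular_scoring")
  subcell <- list(v = c("A", "B"), u = c("A", "B", "C"), w = "Z")
  sw <- subcellular_weight(scoring, subcell, c("v", "u", "w"))
  expect_equal(unname(sw["u"]), 1)          # attains the maximum 1.75
  expect_equal(unname(sw["v"]), 1.5 / 1.75)
  expect_equal(unname(sw["w"]), 0)

  empty <- structure(list(epi = numeric(0), ep_threshold = 0.5,
                          selected = character(0), scs = numeric(0)),
                     class = "subcellular_scoring")
  expect_warning(sw2 <- subcellular_weight(empty, subcell, c("v", "u")),
                 "falling back")
  expect_equal(unname(sw2), c(1, 1))
})

test_that("ablation exponents delete factors instead of zeroing products", {
  expect_equal(edge_weight(0.5, 0.8, 0.375), 0.15)
  expect_equal(edge_weight(0, 0.8, 0.5, alpha = c(0, 1, 1, 1, 1, 1, 1, 1)), 0.4)
  expect_equal(edge_weight(0, 0.8, 0.5), 0)
  expect_identical(alpha_preset("yeast_best"), c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L))
  expect_identical(alpha_preset("fly_best"), c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L))
  expect_error(alpha_preset(c(1, 2, 1, 1, 1, 1, 1, 1)), "0 or 1")
})

test_that("weight model components take their hand-constructed values", {
  fx <- controlled_weight_fixture()
  avg <- average_expression(fx$expr)
  act <- activity_model(avg)
  subs <- build_subnetworks(fx$ppi, act)
  wm <- build_weight_model(fx$ppi, avg, fx$bundle, subs)

  key <- paste(wm$edges[, 1], wm$edges[, 2])
  uv <- match("u v", key)
  vx <- match("v x", key)
  expect_equal(wm$gow[uv], 0.5)    # overlap 2 of |4| x |2| terms
  expect_equal(wm$gow[vx], 0)      # disjoint GO sets
  expect_equal(unname(wm$pc[c("u", "v", "x")]), c(3L, 2L, 4L))
  expect_equal(wm$pcw[uv], 6 / 16)
  expect_equal(wm$gw[uv], gene_weight(avg$ge["u", ], avg$ge["v", ]))

  # only compartment B (essential fraction 1 > 1/3) is selected; it holds v
  expect_identical(wm$scoring$selected, "B")
  expect_equal(unname(wm$sw[c("u", "v", "x")]), c(0, 1, 0))

  # score_initial: sum of incident combined weights times SW
  expect_equal(unname(wm$score_initial["v"]),
               (wm$w_edge[uv] + wm$w_edge[vx]) * 1)
  expect_equal(unname(wm$score_initial["u"]), 0)  # SW_u = 0 annihilates
  expect_equal(node_score_initial(wm, "v"), unname(wm$score_initial["v"]))
})

test_that("weight matrix entries multiply GO, activity, complex and subcellular factors", {
  fx <- controlled_weight_fixture()
  avg <- average_expression(fx$expr)
  act <- activity_model(avg)
  subs <- build_subnetworks(fx$ppi, act)
  wm <- build_weight_model(fx$ppi, avg, fx$bundle, subs)
  key <- paste(wm$edges[, 1], wm$edges[, 2])
  for (i in seq_len(subs$m)) {
    e <- subs$edges[[i]]
    for (k in seq_len(nrow(e))) {
      a <- e[k, 1]; b <- e[k, 2]
      j <- match(paste(a, b), key)
      expect_equal(wmatrix_entry(wm, subs, i, a, b),
                   wm$gow[j] * subs$w[[i]][k] * wm$pcw[j] * wm$sw[[a]] * wm$sw[[b]])
    }
  }
  expect_error(wmatrix_entry(wm, subs, 1L, "u", "x"), "not in sub-network")
})

test_that("a hand-assembled weight matrix entry reproduces the worked product", {
  # GOW = 0.5, Ap = (0.99, 0.95), PCW = 0.375, SW = (1.0, 0.8)
  expect_equal(0.5 * (0.99 * 0.95) * 0.375 * (1.0 * 0.8), 0.141075)
  # with the complex factor ablated the 0-valued PCW drops out
  a <- alpha_preset("yeast_best")
  val <- sesn:::pow_alpha(0.5, a[5]) * sesn:::pow_alpha(0.99 * 0.95, a[6]) *
    sesn:::pow_alpha(0, a[7]) * sesn:::pow_alpha(1.0 * 0.8, a[8])
  expect_equal(val, 0.5 * 0.99 * 0.95 * 0.8)
})

test_that("all weight families stay within [0, 1] and are symmetric on synthetic data", {
  ds <- suppressMessages(generate_dataset(small_config(9)))
  avg <- average_expression(ds$expression)
  act <- activity_model(avg)
  subs <- build_subnetworks(ds$ppi, act)
  wm <- build_weight_model(ds$ppi, avg, ds$bundle, subs)
  in01 <- function(x) all(x >= 0 & x <= 1)
  expect_true(in01(wm$gow))
  expect_true(in01(wm$gw))
  expect_true(in01(wm$pcw))
  expect_true(in01(wm$sw))
  expect_true(in01(wm$w_edge))
  expect_true(in01(unlist(wm$wmatrix)))
  # symmetry of the pairwise families
  set.seed(1)
  for (k in sample(nrow(ds$ppi$edges), 10)) {
    a <- ds$ppi$edges[k, 1]; b <- ds$ppi$edges[k, 2]
    expect_equal(go_weight(ds$bundle$go_terms[[a]], ds$bundle$go_terms[[b]]),
                 go_weight(ds$bundle$go_terms[[b]], ds$bundle$go_terms[[a]]))
    expect_equal(gene_weight(avg$ge[a, ], avg$ge[b, ]),
                 gene_weight(avg$ge[b, ], avg$ge[a, ]))
  }
})

test_that("the all-ones exponent vector reproduces the unablated formulas exactly", {
  ds <- suppressMessages(generate_dataset(small_config(10)))
  avg <- average_expression(ds$expression)
  act <- activity_model(avg)
  subs <- build_subnetworks(ds$ppi, act)
  wm <- build_weight_model(ds$ppi, avg, ds$bundle, subs, alpha = "all_ones")
  expect_identical(wm$w_edge, wm$gow * wm$gw * wm$pcw)
  key <- paste(wm$edges[, 1], wm$edges[, 2])
  for (i in seq_len(subs$m)) {
    e <- subs$edges[[i]]
    if (!nrow(e)) next
    j <- match(paste(e[, 1], e[, 2]), key)
    expect_identical(wm$wmatrix[[i]],
                     wm$gow[j] * subs$w[[i]] * wm$pcw[j] *
                       unname(wm$sw[e[, 1]] * wm$sw[e[, 2]]))
  }
})
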