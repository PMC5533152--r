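ranges3 <- function() data.frame(tip = c("A", "B", "C"),
                                 max_date = c(50, 60, 70),
                                 min_date = c(50, 60, 70))

test_that("draw_tip_ages: degenerate ranges, uniform mean, determinism, validation", {
  ages <- draw_tip_ages(ranges3(), seed = 1)
  expect_equal(ages, c(A = 50, B = 60, C = 70))

  rg <- data.frame(tip = "X", max_date = 131, min_date = 120)
  draws <- replicate(10000, draw_tip_ages(rg)[["X"]])
  expect_lt(abs(mean(draws) - 125.5), 0.2)   # mean of Uniform(120, 131)
  expect_true(all(draws >= 120 & draws <= 131))

  expect_identical(draw_tip_ages(rg, seed = 7), draw_tip_ages(rg, seed = 7))

  bad <- data.frame(tip = "Y", max_date = 100, min_date = 110)
  expect_error(draw_tip_ages(bad), "Y")
})

test_that("basic_timescale applies the max-descendant-age rule", {
  topo <- ape::read.tree(text = "((A,B),C);")
  bt <- basic_timescale(topo, c(A = 50, B = 60, C = 70))
  expect_equal(bt$root.time, 70)
  ages <- node_ages(bt)
  expect_equal(ages[4], 70)  # root
  expect_equal(ages[5], 60)  # node(A,B)
  expect_equal(tip_ages(bt), c(A = 50, B = 60, C = 70))
  # branch node -> B has zero length
  expect_true(any(bt$edge.length == 0))

  st <- basic_timescale(star_tree(4, labels = letters[1:4]),
                        c(a = 10, b = 10, c = 10, d = 10))
  expect_equal(st$root.time, 10)
  expect_equal(st$edge.length, rep(0, 4))

  two <- basic_timescale(ape::read.tree(text = "(A,B);"), c(A = 10, B = 30))
  expect_equal(two$root.time, 30)
  expect_setequal(two$edge.length, c(20, 0))
})

test_that("equal_timescale reproduces the hand-worked 3-tip redistribution", {
  topo <- ape::read.tree(text = "((A,B),C);")
  et <- equal_timescale(basic_timescale(topo, c(A = 50, B = 60, C = 70)),
                        root_extension = 10)
  expect_equal(et$root.time, 80)
  ages <- node_ages(et)
  expect_equal(ages[5], 70)  # node(A,B) slid from 60 to 70
  len <- function(parent, child) {
    i <- which(et$edge[, 1] == parent & et$edge[, 2] == child)
    et$edge.length[i]
  }
  tipn <- function(lab) match(lab, et$tip.label)
  expect_equal(len(4, 5), 10)          # root -> node(A,B)
  expect_equal(len(5, tipn("B")), 10)  # node -> B
  expect_equal(len(5, tipn("A")), 20)  # node -> A
  expect_equal(len(4, tipn("C")), 10)  # root -> C
  expect_equal(tip_ages(et), c(A = 50, B = 60, C = 70))
})

test_that("equal_timescale with no zero branches only extends the root", {
  topo <- ape::read.tree(text = "((A,B),C);")
  bt <- basic_timescale(topo, c(A = 50, B = 60, C = 70))
  # make all branches positive by hand before redistribution
  bt$edge.length <- bt$edge.length + 1
  bt$root.time <- bt$root.time + 1
  et <- equal_timescale(bt, root_extension = 10)
  # internal branch lengths preserved except those incident to the root
  expect_equal(et$root.time, bt$root.time + 10)
  internal <- et$edge[, 1] != ape::Ntip(et) + 1
  expect_equal(et$edge.length[internal], bt$edge.length[internal])
})

test_that("equal_timescale shares one donor across a multi-branch zero chain", {
  # caterpillar ((A,B),C),D with all tips age 50: every internal node dates
  # to 50, so three zero branches chain up to the extended root
  topo <- ape::read.tree(text = "(((A,B),C),D);")
  ages <- c(A = 50, B = 50, C = 50, D = 50)
  et <- equal_timescale(basic_timescale(topo, ages), root_extension = 12)
  expect_true(all(et$edge.length > 0))
  expect_equal(tip_ages(et), ages)
  expect_equal(et$root.time, 62)
  # the chain root -> n1 -> n2 -> A shares the 12 Ma extension equally
  path_lens <- sort(unique(round(et$edge.length, 9)))
  expect_true(4 %in% path_lens)
})

test_that("equal_timescale preserves tip ages and positivity on random fossils", {
  set.seed(99)
  for (i in 1:100) {
    tr <- simulate_fossil_tree(sample(5:20, 1), seed = i)
    fr <- simulate_fossil_ranges(tr, half_width = 3, seed = i + 1000)
    ages <- draw_tip_ages(fr$ranges, seed = i + 2000)
    et <- equal_timescale(basic_timescale(fr$topology, ages),
                          root_extension = 1)
    expect_true(all(et$edge.length > 0))
    expect_true(max(abs(tip_ages(et)[names(ages)] - ages)) < 1e-9)
    # total length can only grow relative to basic dating
    bt <- basic_timescale(fr$topology, ages)
    expect_gte(sum(et$edge.length), sum(bt$edge.length) - 1e-9)
  }
})

test_that("enlarging root_extension never shortens basal redistribution", {
  topo <- ape::read.tree(text = "((A,B),C);")
  ages <- c(A = 50, B = 60, C = 70)
  e1 <- equal_timescale(basic_timescale(topo, ages), root_extension = 5)
  e2 <- equal_timescale(basic_timescale(topo, ages), root_extension = 15)
  expect_true(all(e2$edge.length - e1$edge.length > -1e-12))
})

test_that("generate_calibration_sample is deterministic and in-range", {
  topo <- ape::read.tree(text = "((A,B),C);")
  rg <- data.frame(tip = c("A", "B", "C"),
                   max_date = c(55, 66, 72), min_date = c(48, 58, 68))
  s1 <- generate_calibration_sample(topo, rg, n_draws = 25, seed = 3)
  s2 <- generate_calibration_sample(topo, rg, n_draws = 25, seed = 3)
  expect_identical(write_trees(s1), write_trees(s2))
  expect_length(s1, 25)
  for (tr in s1) {
    expect_true(all(tr$edge.length > 0))
    ta <- tip_ages(tr)[rg$tip]
    expect_true(all(ta >= rg$min_date - 1e-9 & ta <= rg$max_date + 1e-9))
  }
  # degenerate ranges with one draw give a fully determined tree
  one <- generate_calibration_sample(topo, ranges3(), n_draws = 1, seed = 1)
  expect_equal(tip_ages(one[[1]]), c(A = 50, B = 60, C = 70))
})
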