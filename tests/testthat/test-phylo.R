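test_that("patristic distances are path sums with zero diagonal", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- patristic_matrix(tree, c("A", "B", "C"))
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  expect_equal(D, t(D))
})

test_that("patristic matrix matches the naive path-walk oracle", {
  set.seed(11)
  for (i in 1:5) {
    tree <- ape::rtree(12)
    D <- patristic_matrix(tree, tree$tip.label)
    expect_equal(D, bf_patristic(tree)[tree$tip.label, tree$tip.label],
                 tolerance = 1e-12)
  }
})

test_that("age smoothing interpolates unconstrained nodes evenly", {
  # root(10) -> n1(free) -> tip: midpoint
  tr <- ape::read.tree(text = "((A:1):1,B:2);")
  tr$node.label <- c("root", "n1")
  out <- bladj_smooth(tr, c(root = 10))
  depth <- ape::node.depth.edgelength(out)
  ages <- max(depth) - depth
  expect_equal(unname(ages[4]), 5)  # n1 is node 4 (ntip = 2)

  # two free nodes between age-12 root and tip: even thirds (8, 4)
  tr2 <- ape::read.tree(text = "(((A:1):1):1,B:3);")
  tr2$node.label <- c("root", "n1", "n2")
  out2 <- bladj_smooth(tr2, c(root = 12))
  d2 <- ape::node.depth.edgelength(out2)
  ages2 <- max(d2) - d2
  expect_equal(unname(ages2[4:5]), c(8, 4))
})

test_that("random constraint sets are honored and bounded", {
  set.seed(21)
  for (rep in 1:5) {
    tree <- ape::rtree(20)
    ntip <- 20
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
    # consistent ages from topological depth: deeper nodes younger
    depth <- ape::node.depth.edgelength(ape::compute.brlen(tree, 1))
    steps <- round(depth[(ntip + 1):(ntip + tree$Nnode)])
    true_age <- 100 * (1 - steps / (max(steps) + 1))
    pick <- sort(unique(c(1, sample(seq_len(tree$Nnode),
                                    tree$Nnode %/% 3))))
    ages <- setNames(true_age[pick], tree$node.label[pick])
    out <- bladj_smooth(tree, ages)
    d <- ape::node.depth.edgelength(out)
    age_all <- max(d) - d
    # ultrametric: all tips at age ~0, max pairwise distance = 2 * root age
    expect_lt(max(abs(age_all[1:ntip])), 1e-9)
    D <- patristic_matrix(out)
    expect_equal(max(D), 2 * ages[["n1"]], tolerance = 1e-9)
    # constrained ages honored exactly
    got <- age_all[ntip + pick]
    expect_equal(unname(got), unname(ages), tolerance = 1e-9)
    # every branch non-negative; unconstrained nodes strictly between
    # parent and oldest constrained descendant by construction
    expect_true(all(out$edge.length >= -1e-12))
    # idempotence
    out2 <- bladj_smooth(out, ages)
    expect_equal(out2$edge.length, out$edge.length, tolerance = 1e-9)
  }
})

test_that("conflicting constraints are rejected", {
  tr <- ape::read.tree(text = "((A:1,B:1)n2:1,C:2)n1;")
  expect_error(bladj_smooth(tr, c(n1 = 5, n2 = 9)), "conflict")
  expect_error(bladj_smooth(tr, c(n2 = 3)), "root age")
  expect_error(bladj_smooth(tr, c(n1 = 5, bogus = 1)), "unknown node")
})
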