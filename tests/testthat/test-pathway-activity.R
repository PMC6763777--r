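test_that("ssGSEA scores match the hand-computed running sums", {
  v <- c(g1 = 3, g2 = 2, g3 = 1)
  expect_equal(ssgsea_score(v, "g1", tau = 1), 1.5)
  expect_equal(ssgsea_score(v, "g3", tau = 0), -1.5)
  # the closed form and the literal step sum agree on random cases
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      ids <- sprintf("f%02d", seq_len(n))
      vals <- stats::setNames(rnorm(n), ids)
      vals[sample(n, n %/% 5)] <- NA # some missing
      set <- sample(ids, sample(seq_len(n - 1), 1))
      tau <- sample(c(0, 0.25, 1), 1)
      expect_equal(ssgsea_score(vals, set, tau), stepwise_ssgsea(vals, set, tau))
    }
  })
})

test_that("ssGSEA is invariant under strictly monotone value transforms", {
  withr::with_seed(4, {
    ids <- sprintf("f%02d", 1:30)
    vals <- stats::setNames(rnorm(30), ids)
    set <- sample(ids, 7)
    base <- ssgsea_score(vals, set)
    expect_equal(ssgsea_score(exp(vals), set), base)
    expect_equal(ssgsea_score(2 * vals + 10, set), base)
    expect_equal(ssgsea_score(rank(vals), set), base)
  })
})

test_that("pathway_activity drops unmeasured sets, is sample-equivariant, and tracks rank position", {
  withr::with_seed(9, {
    expr <- matrix(rnorm(200), 20, 10,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
    sets <- gene_set_collection(list(A = c("g01", "g02", "g03"),
                                     B = c("nope1", "nope2")))
    expect_warning(act <- pathway_activity(expr, sets),
                   class = "dsn_dropped_pathways")
    expect_identical(rownames(act), "A")

    # permuting sample columns permutes activity columns identically
    sets2 <- gene_set_collection(list(A = c("g01", "g02", "g03")))
    act1 <- pathway_activity(expr, sets2)
    perm <- sample(ncol(expr))
    act2 <- pathway_activity(expr[, perm], sets2)
    expect_equal(act2, act1[, perm, drop = FALSE])

    # members top-ranked in one sample, bottom-ranked in another
    expr2 <- expr
    expr2[c("g01", "g02", "g03"), 1] <- max(expr2) + 1:3
    expr2[c("g01", "g02", "g03"), 2] <- min(expr2) - 1:3
    act3 <- pathway_activity(expr2, sets2)
    expect_gt(act3["A", 1], act3["A", 2])
  })
  # a set covering every measured feature is degenerate
  expr_small <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(
    pathway_activity(expr_small, gene_set_collection(list(X = c("a", "b")))),
    class = "dsn_degenerate_set"
  )
  expect_error(
    pathway_activity(expr_small, gene_set_collection(list(X = "zz"))),
    class = "dsn_empty_result"
  )
})

test_that("hypergeometric tail matches exact enumeration and boundary values", {
  expect_equal(hypergeom_overlap_p(0, 5, 3, 10), 1)
  expect_equal(hypergeom_overlap_p(2, 5, 2, 10), 10 / 45)
  expect_equal(hypergeom_overlap_p(4, 4, 4, 4), 1)
  expect_error(hypergeom_overlap_p(3, 2, 3, 10), class = "dsn_bad_argument")
  # brute force over all draws for small universes
  withr::with_seed(2, {
    for (rep in 1:15) {
      N <- sample(4:12, 1)
      K <- sample(seq_len(N - 1), 1)
      n <- sample(seq_len(N - 1), 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeom_overlap_p(k, K, n, N),
                   enumerate_hypergeom_tail(k, K, N, n))
    }
  })
})

test_that("microRNA pathway assignment follows the hypergeometric rule", {
  universe <- sprintf("g%02d", 1:10)
  sets <- gene_set_collection(list(P = universe[1:5], Q = universe[6:7]))
  targets <- list(
    mirA = universe[1:5],        # exactly P: p = 1/C(10,5) < 0.05
    mirB = c("x1", "x2", "x3")   # disjoint from the universe
  )
  mp <- build_mirna_pathways(targets, sets, universe = universe)
  expect_identical(mp[["P"]], "mirA")
  expect_false("Q" %in% names(mp))
  expect_equal(hypergeom_overlap_p(5, 5, 5, 10), 1 / choose(10, 5))

  # alpha = 0 admits nothing
  expect_warning(
    empty <- build_mirna_pathways(targets, sets, universe = universe, alpha = 0),
    class = "dsn_empty_result"
  )
  expect_length(empty, 0L)
  expect_error(build_mirna_pathways(targets, sets, universe = character(0)),
               class = "dsn_bad_argument")
})

test_that("redundant pathway removal drops the smaller set and leaves no violating pair", {
  g <- sprintf("g%02d", 1:20)
  sets <- gene_set_collection(list(
    A = g[1:5],          # overlap with B: 5/5 = 1.00 and 5/6 = 0.833 -> drop A
    B = g[c(1:5, 6)],
    C = g[10:14]         # disjoint
  ))
  out <- remove_redundant_pathways(sets, 0.80)
  expect_setequal(names(out), c("B", "C"))

  # identical duplicated set: exactly one survives (later name dropped)
  dup <- gene_set_collection(list(Z1 = g[1:4], Z2 = g[1:4]))
  expect_identical(names(remove_redundant_pathways(dup)), "Z1")

  # disjoint collections are untouched; output is always overlap-free
  dis <- gene_set_collection(list(A = g[1:3], B = g[4:6]))
  expect_identical(remove_redundant_pathways(dis), dis)
  withr::with_seed(21, {
    for (rep in 1:10) {
      rnd <- gene_set_collection(stats::setNames(
        lapply(1:8, function(i) sample(g, sample(3:8, 1))),
        sprintf("S%d", 1:8)
      ))
      pruned <- remove_redundant_pathways(rnd, 0.8)
      if (length(pruned) >= 2L) {
        pairs <- utils::combn(names(pruned), 2L)
        viol <- apply(pairs, 2L, function(ab) {
          ov <- length(intersect(pruned[[ab[1]]], pruned[[ab[2]]]))
          ov / length(pruned[[ab[1]]]) > 0.8 && ov / length(pruned[[ab[2]]]) > 0.8
        })
        expect_false(any(viol))
      }
    }
  })
})
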