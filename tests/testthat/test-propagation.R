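test_that("column normalization produces a column-stochastic transition structure", {
  path <- drug_network(data.frame(from = c("a", "b"), to = c("b", "c")))
  A <- column_normalize(path)
  expect_equal(A["a", "b"], 0.5)
  expect_equal(A["c", "b"], 0.5)
  expect_equal(unname(Matrix::colSums(A)), c(1, 1, 1))

  iso <- drug_network(data.frame(from = "a", to = "b"), nodes = c("a", "b", "z"))
  Ai <- column_normalize(iso)
  expect_equal(sum(Ai[, "z"]), 0) # isolated column stays all-zero
  expect_equal(unname(Matrix::colSums(Ai)[c("a", "b")]), c(1, 1))
})

test_that("two-node walk matches the closed-form solve and symmetry fixed point", {
  net <- drug_network(data.frame(from = "a", to = "b"))
  fit <- rwr(net, "a", alpha = 0.7, p0_mode = "normalized")
  expect_equal(fit$scores$prior_score[fit$scores$drug_id == "a"], 0.7 / 0.91,
               tolerance = 1e-9)
  expect_equal(fit$scores$prior_score[fit$scores$drug_id == "b"], 0.21 / 0.91,
               tolerance = 1e-9)

  both <- rwr(net, c("a", "b"), p0_mode = "normalized")
  expect_equal(both$scores$prior_score, c(0.5, 0.5))
})

test_that("iterative walk agrees with the direct linear solve on random graphs", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      net <- random_network(sample(20:80, 1), 0.08)
      seeds <- sample(network_nodes(net), 3)
      for (mode in c("unit", "normalized")) {
        fit <- rwr(net, seeds, p0_mode = mode)
        direct <- rwr_direct_solve(net, seeds, p0_mode = mode)
        got <- stats::setNames(fit$scores$prior_score, fit$scores$drug_id)
        expect_lt(sum(abs(got[names(direct)] - direct)), 1e-9)
      }
    }
  })
})

test_that("walk conserves mass on zero-column-free graphs and scores stay nonnegative", {
  withr::with_seed(3, {
    net <- random_network(40, 0.15)
    deg <- network_degree(net)
    connected <- deg$drug_id[deg$degree > 0]
    sub <- drug_network(network_edges(net)) # nodes = endpoints only
    seeds <- sample(network_nodes(sub), 4)
    fit <- rwr(sub, seeds, p0_mode = "normalized")
    expect_equal(sum(fit$scores$prior_score), 1, tolerance = 1e-8)
    expect_true(all(fit$scores$prior_score >= 0))
    # every node reachable from a seed gets strictly positive mass
    g <- igraph::graph_from_data_frame(network_edges(sub)[, 1:2],
                                       directed = FALSE,
                                       vertices = network_nodes(sub))
    reach <- igraph::subcomponent(g, seeds[1])$name
    sc <- stats::setNames(fit$scores$prior_score, fit$scores$drug_id)
    expect_true(all(sc[reach] > 0))
  })
})

test_that("node relabeling permutes scores identically", {
  withr::with_seed(19, {
    net <- random_network(25, 0.15)
    seeds <- sample(network_nodes(net), 3)
    relab <- stats::setNames(sprintf("x%02d", sample(25)), network_nodes(net))
    e <- network_edges(net)
    net2 <- drug_network(data.frame(from = relab[e$from], to = relab[e$to]),
                         nodes = relab)
    fit1 <- rwr(net, seeds)
    fit2 <- rwr(net2, relab[seeds])
    s1 <- stats::setNames(fit1$scores$prior_score, fit1$scores$drug_id)
    s2 <- stats::setNames(fit2$scores$prior_score, fit2$scores$drug_id)
    expect_equal(unname(s2[relab[names(s1)]]), unname(s1))
  })
})

test_that("unit and normalized seed mass give identical rankings", {
  withr::with_seed(23, {
    net <- random_network(30, 0.12)
    seeds <- sample(network_nodes(net), 4)
    f_unit <- rwr(net, seeds, p0_mode = "unit")
    f_norm <- rwr(net, seeds, p0_mode = "normalized")
    expect_identical(f_unit$scores$drug_id, f_norm$scores$drug_id)
    expect_equal(f_unit$scores$prior_score,
                 f_norm$scores$prior_score * length(seeds))
  })
})

test_that("seed validation and non-convergence are hard errors", {
  net <- drug_network(data.frame(from = "a", to = "b"))
  expect_error(rwr(net, character(0)), class = "dsn_empty_seed_set")
  expect_error(rwr(net, "zzz"), class = "dsn_empty_seed_set")
  expect_error(rwr(net, c("a", "zzz")), class = "dsn_unmapped_seeds")
  err <- expect_error(rwr(net, "a", tol = 1e-12, max_iter = 3),
                      class = "dsn_no_convergence")
  expect_match(conditionMessage(err), "residual")
})
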