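test_that("pathway-drug correlations match Pearson on shared samples", {
  act <- rbind(P1 = c(1, 2, 3, 4), P2 = c(4, 1, 3, 2))
  colnames(act) <- paste0("CL", 1:4)
  drugs <- rbind(
    dA = 2 * act["P1", ] + 5,   # affine transform -> r = 1
    dB = -act["P1", ],          # negation -> r = -1
    dC = c(2, 1, 4, 3)          # hand-computed r vs P1 = 0.6
  )
  pd <- pathway_drug_correlation(act, drugs)
  expect_equal(pd$r["P1", "dA"], 1)
  expect_equal(pd$r["P1", "dB"], -1)
  expect_equal(pd$r["P1", "dC"], 0.6)
  expect_true(all(pd$n == 4))

  # shared-sample guards
  other <- drugs
  colnames(other) <- paste0("XX", 1:4)
  expect_error(pathway_drug_correlation(act, other),
               class = "dsn_no_shared_samples")
  expect_error(pathway_drug_correlation(act[, 1:2, drop = FALSE], drugs),
               class = "dsn_no_shared_samples")

  # pairwise-complete entries with < 3 complete pairs become missing
  drugs_na <- drugs
  drugs_na["dC", 1:2] <- NA
  pd2 <- pathway_drug_correlation(act, drugs_na)
  expect_true(is.na(pd2$r["P1", "dC"]))
  expect_equal(pd2$r["P1", "dA"], 1)
})

test_that("drug-drug similarity equals a per-pair Pearson oracle and pools FDR correctly", {
  withr::with_seed(13, {
    profiles <- matrix(rnorm(80), 8, 10,
                       dimnames = list(sprintf("P%d", 1:8), sprintf("d%02d", 1:10)))
    profiles[sample(80, 8)] <- NA
    pd <- drugsimnet:::new_cor_matrix(profiles, matrix(12, 8, 10), NULL)
    dd <- drug_drug_similarity(pd)
    for (i in 1:9) {
      for (j in (i + 1):10) {
        expect_equal(dd$r[i, j], plain_pearson(profiles[, i], profiles[, j]),
                     tolerance = 1e-12)
      }
    }
    expect_equal(dd$r, t(dd$r))
    expect_equal(unname(diag(dd$r)), rep(1, 10))
    expect_true(all(is.na(diag(dd$fdr)))) # diagonal excluded from the pool
    # BH over the 45 unordered pairs, mapped back symmetrically
    ut <- upper.tri(dd$p)
    expect_equal(dd$fdr[ut], p.adjust(dd$p[ut], "BH"))

    # identical profiles give r = 1
    pd_id <- drugsimnet:::new_cor_matrix(cbind(a = profiles[, 1], b = profiles[, 1]),
                                         matrix(12, 8, 2), NULL)
    expect_no_warning(dd_id <- drug_drug_similarity(pd_id))
    expect_equal(dd_id$r["a", "b"], 1)
  })
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.04, 0.5)), c(0.015, 0.06, 0.5))
  expect_error(bh_fdr(c(0.1, 1.3)), class = "dsn_bad_argument")
})

test_that("edge selection applies the (r AND fdr) OR top-rank rule", {
  mk_dd <- function(r, fdr) {
    diag(r) <- 1
    drugsimnet:::new_cor_matrix(r, matrix(60, nrow(r), ncol(r)), NULL, fdr)
  }
  ids <- c("a", "b", "c")
  r <- matrix(0.9, 3, 3, dimnames = list(ids, ids))
  fdr <- matrix(0.01, 3, 3, dimnames = list(ids, ids))
  net <- select_edges(mk_dd(r, fdr), top_frac = 0)
  expect_equal(nrow(network_edges(net)), 3L) # complete graph on 3 nodes

  # nothing passes r/FDR but each drug still gets ceiling(top_frac*(n-1)) = 1
  # top-rank partner
  expect_equal(ceiling(0.0005 * 2000), 1) # the rank-rule arithmetic at n = 2001
  withr::with_seed(5, {
    n <- 30
    ids <- sprintf("d%02d", 1:n)
    r <- matrix(runif(n * n, -0.5, 0.5), n, n, dimnames = list(ids, ids))
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    fdr <- matrix(1, n, n, dimnames = list(ids, ids))
    net2 <- select_edges(mk_dd(r, fdr), r_min = 0.7, fdr_max = 0.05,
                         top_frac = 1 / (n - 1)) # per-drug top-1
    deg <- network_degree(net2)
    expect_true(all(deg$degree >= 1)) # min-degree guarantee from the rank rule
    # intersect mode is a subset of union mode
    net3 <- suppressWarnings(select_edges(mk_dd(r, fdr), top_frac = 1 / (n - 1),
                                          rule = "intersect"))
    eu <- network_edges(net2); ei <- network_edges(net3)
    expect_true(all(paste(ei$from, ei$to) %in% paste(eu$from, eu$to)))
  })

  # thresholds at their limits produce an empty (but valid) network
  ids <- c("a", "b", "c")
  r <- matrix(0.5, 3, 3, dimnames = list(ids, ids))
  fdr <- matrix(1, 3, 3, dimnames = list(ids, ids))
  expect_warning(net4 <- select_edges(mk_dd(r, fdr), r_min = 1.01, top_frac = 0),
                 class = "dsn_empty_network")
  expect_equal(nrow(network_edges(net4)), 0L)
  expect_setequal(network_nodes(net4), ids)
})

test_that("edge selection is invariant under drug relabeling/permutation", {
  withr::with_seed(8, {
    n <- 20
    ids <- sprintf("d%02d", 1:n)
    r <- matrix(runif(n * n, -1, 1), n, n)
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    diag(r) <- 1
    fdr <- matrix(runif(n * n), n, n)
    fdr[lower.tri(fdr)] <- t(fdr)[lower.tri(fdr)]
    dimnames(r) <- dimnames(fdr) <- list(ids, ids)
    dd <- drugsimnet:::new_cor_matrix(r, matrix(60, n, n), NULL, fdr)
    net <- select_edges(dd, r_min = 0.6, fdr_max = 0.2, top_frac = 0.06)
    perm <- sample(n)
    dd_p <- drugsimnet:::new_cor_matrix(r[perm, perm], matrix(60, n, n), NULL,
                                        fdr[perm, perm])
    net_p <- select_edges(dd_p, r_min = 0.6, fdr_max = 0.2, top_frac = 0.06)
    expect_equal(network_edges(net_p)[, c("from", "to")],
                 network_edges(net)[, c("from", "to")])
  })
})

test_that("network merge is a union with the empty network as identity", {
  a <- drug_network(data.frame(from = "a", to = "b"))
  b <- drug_network(data.frame(from = "b", to = "c"))
  empty <- drug_network(NULL)
  m <- merge_networks(a, b)
  expect_setequal(network_nodes(m), c("a", "b", "c"))
  expect_equal(nrow(network_edges(m)), 2L)
  expect_equal(merge_networks(a, empty), a)
  withr::with_seed(17, {
    for (rep in 1:10) {
      x <- random_network(12, 0.2)
      y <- random_network(12, 0.2)
      mm <- merge_networks(x, y)
      ex <- nrow(network_edges(x)); ey <- nrow(network_edges(y))
      em <- nrow(network_edges(mm))
      expect_lte(em, ex + ey)
      shared <- nrow(dplyr::intersect(network_edges(x)[, 1:2],
                                      network_edges(y)[, 1:2]))
      expect_equal(em, ex + ey - shared)
    }
  })
})
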