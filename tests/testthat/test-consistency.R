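# build the raw probability list for a set of networks and similarity
# tables, returning transition models too
.make_pair <- function(A, B, sim) {
  tmA <- build_transition_model(A); tmB <- build_transition_model(B)
  p <- alignment_probabilities(correspondence_scores(tmA, tmB, sim))
  list(p = p, tmA = tmA, tmB = tmB)
}

test_that("intra transform is the identity at alpha = 1", {
  set.seed(3)
  A <- rand_net("A", 6, p = 0.5, connected = TRUE)
  B <- rand_net("B", 6, p = 0.5, connected = TRUE)
  mk <- .make_pair(A, B, rand_sim(A, B, density = 0.5))
  q <- intra_transform(mk$p, mk$tmA, mk$tmB, alpha = 1)
  expect_equal(as.matrix(q$m), as.matrix(mk$p$m))
  expect_equal(q$stage, "intra")
})

test_that("an isolated node's entries are simply scaled by alpha", {
  A <- ppi_network("A", data.frame(from = "a1", to = "a2"),
                   nodes = c("a1", "a2", "iso"))
  B <- path_net("B", c("b1", "b2"))
  sim <- similarity_scores(A, B, data.frame(
    node_a = c("a1", "iso"), node_b = c("b1", "b2"), score = c(5, 5)))
  # hand-build a raw matrix including the isolated node
  M <- matrix(0, 3, 2, dimnames = list(c("a1", "a2", "iso"), c("b1", "b2")))
  M["a1", "b1"] <- 0.6; M["iso", "b2"] <- 0.8
  p <- pm_from_matrix("A", "B", M, rn = rownames(M), cn = colnames(M))
  tmA <- build_transition_model(A); tmB <- build_transition_model(B)
  q <- intra_transform(p, tmA, tmB, alpha = 0.7, top_fraction = 1)
  expect_equal(q$m["iso", "b2"], 0.7 * 0.8)
})

test_that("intra transform reproduces the nested-sum hand example", {
  # two unit paths, probability 0.9 on the identity-like pairs, alpha 0.9:
  # q(b, e) = 0.9*0.9 + 0.1*(0.25*0.9 + 0.25*0.9) = 0.855
  A <- path_net("A", c("a", "b", "c"))
  B <- path_net("B", c("d", "e", "f"))
  M <- diag(0.9, 3)
  p <- pm_from_matrix("A", "B", M, rn = c("a", "b", "c"),
                      cn = c("d", "e", "f"))
  tmA <- build_transition_model(A); tmB <- build_transition_model(B)
  q <- intra_transform(p, tmA, tmB, alpha = 0.9, top_fraction = 1)
  expect_equal(q$m["b", "e"], 0.855, tolerance = 1e-12)
})

test_that("intra transform agrees with the quadruple-loop oracle", {
  set.seed(17)
  for (rep in 1:8) {
    A <- rand_net("A", sample(3:6, 1L), p = 0.6, connected = TRUE)
    B <- rand_net("B", sample(3:6, 1L), p = 0.6, connected = TRUE)
    mk <- .make_pair(A, B, rand_sim(A, B, density = 0.6))
    alpha <- stats::runif(1)
    q <- intra_transform(mk$p, mk$tmA, mk$tmB, alpha = alpha,
                         top_fraction = 1)
    oq <- oracle_intra(as.matrix(mk$p$m), as.matrix(A$adj),
                       as.matrix(B$adj), alpha)
    expect_lt(max(abs(as.matrix(q$m) - oq)), 1e-12)
    expect_true(all(as.matrix(q$m) >= -1e-15 & as.matrix(q$m) <= 1 + 1e-12))
  }
})

test_that("the sparsity filter keeps support plus the top quantile only", {
  set.seed(19)
  A <- rand_net("A", 8, p = 0.5, connected = TRUE)
  B <- rand_net("B", 8, p = 0.5, connected = TRUE)
  mk <- .make_pair(A, B, rand_sim(A, B, density = 0.25))
  q_small <- intra_transform(mk$p, mk$tmA, mk$tmB, alpha = 0.5,
                             top_fraction = 1e-9)
  q_big <- intra_transform(mk$p, mk$tmA, mk$tmB, alpha = 0.5,
                           top_fraction = 1)
  supp <- function(m) {
    tr <- Matrix::summary(methods::as(m, "TsparseMatrix"))
    paste(tr$i, tr$j)[tr$x != 0]
  }
  s0 <- supp(mk$p$m); s_small <- supp(q_small$m); s_big <- supp(q_big$m)
  # with a vanishing quantile, support can only shrink toward the original
  # support (plus the single top value, kept by the closed threshold)
  expect_lte(length(setdiff(s_small, s0)), 1L)
  expect_true(all(s_small %in% s_big))
})

test_that("intra transform preserves pair symmetry", {
  set.seed(29)
  A <- rand_net("A", 6, p = 0.5, connected = TRUE)
  B <- rand_net("B", 7, p = 0.5, connected = TRUE)
  sim <- rand_sim(A, B, density = 0.4)
  mk <- .make_pair(A, B, sim)
  mk_t <- .make_pair(B, A, sim_transpose(sim))
  q_ab <- intra_transform(mk$p, mk$tmA, mk$tmB, alpha = 0.9,
                          top_fraction = 0.05)
  q_ba <- intra_transform(mk_t$p, mk_t$tmA, mk_t$tmB, alpha = 0.9,
                          top_fraction = 0.05)
  expect_lt(max(abs(as.matrix(q_ab$m) - t(as.matrix(q_ba$m)))), 1e-12)
})

test_that("homology weight solves the small matching cases exactly", {
  # 2x2 hand case: best matching is the anti-diagonal, value 1.3/2
  M <- matrix(c(0.8, 0.7, 0.6, 0.1), 2, 2)
  p <- pm_from_matrix("A", "B", M, stage = "intra")
  hw <- homology_weight(p)
  expect_equal(hw$value, 0.65, tolerance = 1e-12)
  expect_setequal(paste(hw$matching$node_a, hw$matching$node_b),
                  c("a1 b2", "a2 b1"))

  # identity with all ones -> perfect homology
  pI <- pm_from_matrix("A", "B", diag(1, 3), stage = "intra")
  expect_equal(homology_weight(pI)$value, 1)

  # all-zero matrix -> weight 0, empty matching
  p0 <- pm_from_matrix("A", "B", matrix(0, 2, 2), stage = "intra")
  hw0 <- homology_weight(p0)
  expect_equal(hw0$value, 0)
  expect_equal(nrow(hw0$matching), 0L)
})

test_that("homology weight equals the exhaustive matching oracle", {
  set.seed(37)
  for (rep in 1:25) {
    nr <- sample(2:3, 1L); nc <- sample(2:3, 1L)
    M <- matrix(stats::runif(nr * nc), nr, nc)
    M[stats::runif(nr * nc) < 0.3] <- 0
    p <- pm_from_matrix("A", "B", M, stage = "intra")
    hw <- homology_weight(p)
    expect_equal(hw$value, min(1, oracle_max_matching(M) / min(nr, nc)),
                 tolerance = 1e-10)
    # alternative normalizer: matching cardinality
    hw2 <- homology_weight(p, normalizer = "matching_size")
    if (nrow(hw2$matching) > 0) {
      expect_equal(hw2$value,
                   min(1, sum(hw2$matching$p) / nrow(hw2$matching)),
                   tolerance = 1e-10)
    }
  }
})

test_that("cross transform is the identity for a two-network run", {
  set.seed(41)
  A <- rand_net("A", 5, p = 0.6, connected = TRUE)
  B <- rand_net("B", 5, p = 0.6, connected = TRUE)
  mk <- .make_pair(A, B, rand_sim(A, B))
  q <- intra_transform(mk$p, mk$tmA, mk$tmB)
  hw <- homology_weight(q)
  out <- cross_transform(list(q), list(hw), "A", "B")
  expect_equal(as.matrix(out$m), as.matrix(q$m), tolerance = 1e-12)
  expect_equal(out$stage, "cross")
})

test_that("a perfect-copy intermediate leaves the pair unchanged", {
  # C is an exact copy of B: P_AC = P_AB, P_CB = identity, all weights 1
  M <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  p_ab <- pm_from_matrix("A", "B", M, stage = "intra",
                         rn = c("a1", "a2"), cn = c("b1", "b2"))
  p_ac <- pm_from_matrix("A", "C", M, stage = "intra",
                         rn = c("a1", "a2"), cn = c("c1", "c2"))
  p_cb <- pm_from_matrix("C", "B", diag(1, 2), stage = "intra",
                         rn = c("c1", "c2"), cn = c("b1", "b2"))
  w <- list(structure(list(net_a = "A", net_b = "B", value = 1), class = "homology_weight"),
            structure(list(net_a = "A", net_b = "C", value = 1), class = "homology_weight"),
            structure(list(net_a = "C", net_b = "B", value = 1), class = "homology_weight"))
  out <- cross_transform(list(p_ab, p_ac, p_cb), w, "A", "B",
                         networks = c("A", "B", "C"))
  expect_equal(as.matrix(out$m), as.matrix(p_ab$m), tolerance = 1e-12)
})

test_that("cross transform agrees with the explicit triple-sum oracle", {
  set.seed(43)
  for (rep in 1:8) {
    nets <- c("A", "B", "C")
    dims <- stats::setNames(sample(2:3, 3, replace = TRUE), nets)
    mats <- list(A = list(), B = list(), C = list())
    pms <- list()
    for (i in 1:2) for (j in (i + 1):3) {
      a <- nets[i]; b <- nets[j]
      M <- matrix(stats::runif(dims[a] * dims[b]), dims[a], dims[b])
      mats[[a]][[b]] <- M
      mats[[b]][[a]] <- t(M)
      pms[[length(pms) + 1L]] <- pm_from_matrix(
        a, b, M, stage = "intra",
        rn = paste0(tolower(a), seq_len(dims[a])),
        cn = paste0(tolower(b), seq_len(dims[b])))
    }
    wv <- stats::runif(3, 0.2, 1)
    w <- list(
      structure(list(net_a = "A", net_b = "B", value = wv[1]), class = "homology_weight"),
      structure(list(net_a = "A", net_b = "C", value = wv[2]), class = "homology_weight"),
      structure(list(net_a = "B", net_b = "C", value = wv[3]), class = "homology_weight"))
    wmap <- list("A|B" = wv[1], "A|C" = wv[2], "B|C" = wv[3],
                 "A|A" = 1, "B|B" = 1, "C|C" = 1)
    for (i in 1:2) for (j in (i + 1):3) {
      a <- nets[i]; b <- nets[j]
      out <- cross_transform(pms, w, a, b, networks = nets,
                             top_fraction = 1)
      om <- oracle_cross(mats, wmap, nets, a, b)
      expect_lt(max(abs(as.matrix(out$m) - om)), 1e-12)
      expect_true(all(as.matrix(out$m) >= -1e-15 &
                        as.matrix(out$m) <= 1 + 1e-12))
      # pair symmetry of the transform
      out_t <- cross_transform(pms, w, b, a, networks = nets,
                               top_fraction = 1)
      expect_lt(max(abs(as.matrix(out$m) - t(as.matrix(out_t$m)))), 1e-12)
    }
  }
})

test_that("cross transform names a missing pair matrix", {
  M <- matrix(0.5, 2, 2)
  p_ab <- pm_from_matrix("A", "B", M, stage = "intra")
  w <- list(structure(list(net_a = "A", net_b = "B", value = 1), class = "homology_weight"))
  expect_error(cross_transform(list(p_ab), w, "A", "B",
                               networks = c("A", "B", "C")),
               "C")
})
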