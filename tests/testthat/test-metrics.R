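.cls2 <- function(...) {
  rows <- list(...)
  data.frame(net = vapply(rows, `[[`, "", 1L),
             node = vapply(rows, `[[`, "", 2L), stringsAsFactors = FALSE)
}
.ann <- function(...) {
  kv <- list(...)
  stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
}

test_that("evaluation filter removes unannotated nodes then singletons", {
  ann <- .ann(c("A::x", "f1"), c("B::y", "f1"), c("C::z", "f2"))
  al <- network_alignment(list(
    .cls2(c("A", "x"), c("B", "u")),            # u unannotated -> singleton
    .cls2(c("B", "y"), c("C", "z"), c("C", "w"))))  # w dropped, class kept
  filt <- filter_for_eval(al, ann)
  expect_equal(length(filt$classes), 1L)
  expect_setequal(filt$classes[[1L]]$node, c("y", "z"))

  # fully annotated alignment passes through unchanged
  al2 <- network_alignment(list(.cls2(c("A", "x"), c("B", "y"))))
  expect_equal(length(filter_for_eval(al2, ann)$classes), 1L)
})

test_that("specificity and correct nodes follow the hand counts", {
  ann <- .ann(c("A::x1", "f1"), c("B::y1", "f1"), c("A::x2", "f1"),
              c("B::y2", "f1"), c("C::z1", "f1"), c("A::x3", "f1"),
              c("B::y3", "f2"))
  # two pure classes of sizes 2 and 3
  al <- network_alignment(list(
    .cls2(c("A", "x1"), c("B", "y1")),
    .cls2(c("A", "x2"), c("B", "y2"), c("C", "z1"))))
  sc <- specificity_cn(al, ann)
  expect_equal(sc$spe, 100)
  expect_equal(sc$cn, 5L)

  # one pure, one mixed -> spe 50, cn 2
  al2 <- network_alignment(list(
    .cls2(c("A", "x1"), c("B", "y1")),
    .cls2(c("A", "x3"), c("B", "y3"))))
  sc2 <- specificity_cn(al2, ann)
  expect_equal(sc2$spe, 50)
  expect_equal(sc2$cn, 2L)

  # single mixed class -> 0 / 0
  al3 <- network_alignment(list(.cls2(c("A", "x3"), c("B", "y3"))))
  sc3 <- specificity_cn(al3, ann)
  expect_equal(sc3$spe, 0)
  expect_equal(sc3$cn, 0L)

  expect_warning(specificity_cn(network_alignment(list()), ann), "empty")
})

test_that("normalized entropy matches hand values", {
  ann <- .ann(c("A::x", "f1"), c("B::y", "f1"), c("C::z", "f2"),
              c("A::u", "f1"), c("B::v", "f2"), c("C::w", "f2"))
  pure <- network_alignment(list(.cls2(c("A", "x"), c("B", "y"))))
  expect_equal(mean_normalized_entropy(pure, ann), 0)

  half <- network_alignment(list(.cls2(c("A", "u"), c("B", "v"))))
  expect_equal(mean_normalized_entropy(half, ann), 1)

  third <- network_alignment(list(.cls2(c("A", "x"), c("B", "y"),
                                        c("C", "z"))))
  expect_equal(mean_normalized_entropy(third, ann), 0.9183,
               tolerance = 1e-4)
})

test_that("conserved interactions: identical triangles give 3 per pair", {
  tri <- function(name, v) {
    ppi_network(name, data.frame(from = v[c(1, 2, 3)], to = v[c(2, 3, 1)]))
  }
  A <- tri("A", c("a1", "a2", "a3"))
  B <- tri("B", c("b1", "b2", "b3"))
  al <- network_alignment(list(.cls2(c("A", "a1"), c("B", "b1")),
                               .cls2(c("A", "a2"), c("B", "b2")),
                               .cls2(c("A", "a3"), c("B", "b3"))))
  ann <- .ann(c("A::a1", "g1"), c("B::b1", "g1"), c("A::a2", "g2"),
              c("B::b2", "g2"), c("A::a3", "g3"), c("B::b3", "g3"))
  ci <- conserved_interactions(al, list(A, B), ann)
  expect_equal(ci$ci, 3L)
  expect_equal(ci$coi, 3L)     # all classes correct: CI = COI

  # edgeless networks conserve nothing
  E1 <- ppi_network("A", data.frame(from = character(), to = character()),
                    nodes = c("a1", "a2"))
  E2 <- ppi_network("B", data.frame(from = character(), to = character()),
                    nodes = c("b1", "b2"))
  expect_equal(conserved_interactions(al, list(E1, E2), ann)$ci, 0L)
})

test_that("conserved interactions match the brute-force oracle", {
  set.seed(73)
  for (rep in 1:6) {
    nn <- sample(3:4, 1L)
    nets <- lapply(seq_len(nn), function(k) {
      rand_net(paste0("N", k), sample(6:10, 1L), p = 0.35)
    })
    # random disjoint classes over the union of nodes
    pool <- do.call(rbind, lapply(nets, function(nt) {
      data.frame(net = nt$name, node = nt$nodes, stringsAsFactors = FALSE)
    }))
    pool <- pool[sample(nrow(pool)), ]
    k <- sample(4:7, 1L)
    grp <- sample(rep(seq_len(k), length.out = nrow(pool)))
    classes <- Filter(function(cl) nrow(cl) >= 2L,
                      split(pool, grp))
    al <- network_alignment(unname(classes))
    ann <- stats::setNames(sample(c("f1", "f2"), nrow(pool), replace = TRUE),
                           paste(pool$net, pool$node, sep = "::"))
    got <- conserved_interactions(al, nets, ann)
    want <- oracle_ci(al, nets, ann)
    expect_equal(got$ci, want$ci)
    expect_equal(got$coi, want$coi)
    expect_lte(got$coi, got$ci)
  }
})

test_that("coverage histograms bin classes by spanned networks", {
  al <- network_alignment(list(
    .cls2(c("A", "x1"), c("B", "y1")),
    .cls2(c("A", "x2"), c("B", "y2")),
    .cls2(c("A", "x3"), c("B", "y3"), c("C", "z1"))))
  cov <- coverage(al, 3L)
  expect_equal(unname(cov$class_coverage), c(0L, 2L, 1L))
  expect_equal(unname(cov$node_coverage), c(0L, 4L, 3L))
  # node-coverage mass equals total aligned nodes
  expect_equal(sum(cov$node_coverage), n_aligned_nodes(al))

  one <- network_alignment(list(.cls2(c("A", "x"), c("B", "y"),
                                      c("C", "z"))))
  expect_equal(unname(coverage(one, 3L)$class_coverage), c(0L, 0L, 1L))
})

test_that("sensitivity is consistent with the CN numerator", {
  ann <- .ann(c("A::x1", "f1"), c("B::y1", "f1"),
              c("A::x2", "f1"), c("B::y2", "f2"))
  al <- network_alignment(list(.cls2(c("A", "x1"), c("B", "y1")),
                               .cls2(c("A", "x2"), c("B", "y2"))))
  expect_equal(sensitivity(al, ann), 50)        # cn = 2 of 4 nodes
  pure <- network_alignment(list(.cls2(c("A", "x1"), c("B", "y1"))))
  expect_equal(sensitivity(pure, ann), 100)
  expect_equal(sensitivity(al, ann),
               100 * specificity_cn(al, ann)$cn / n_aligned_nodes(al))
})

test_that("evaluate_alignment assembles a coherent report", {
  set.seed(79)
  fam <- grow_family("DMC", ancestor_size = 20,
                     target_sizes = c(30, 35), seed = 83)
  sims <- simulate_scores(fam, score_model(bias = 500, sparsity = 0.01),
                          seed = 89)
  run <- align_networks(fam$networks, sims)
  ann <- family_annotations(fam)
  rep <- evaluate_alignment(run$alignment, ann, fam$networks,
                            truth = fam$truth)
  expect_s3_class(rep, "metrics_report")
  expect_true(rep$spe >= 0 && rep$spe <= 100)
  expect_true(rep$sensitivity >= 0 && rep$sensitivity <= 100)
  expect_true(rep$mne >= 0 && rep$mne <= 1)
  expect_lte(rep$coi, rep$ci)
  expect_equal(sum(rep$node_coverage), rep$n_aligned_nodes)
  expect_true(rep$pair_accuracy >= 0 && rep$pair_accuracy <= 1)
  # restricting to all-species classes cannot raise the class count
  rep2 <- evaluate_alignment(run$alignment, ann, fam$networks,
                             require_all_species = TRUE)
  expect_lte(rep2$cn, rep$n_aligned_nodes)
})
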