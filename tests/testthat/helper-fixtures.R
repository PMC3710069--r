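# Fixtures and independent oracles used across the test files.
# Oracles deliberately use explicit dense/enumerative computations, not the
# package's sparse code paths.

path_net <- function(name, nodes) {
  ppi_network(name, data.frame(from = nodes[-length(nodes)],
                               to = nodes[-1L], stringsAsFactors = FALSE))
}

# random network on n nodes: G(n, p) conditioned on having >= 1 edge;
# optionally guaranteed connected by overlaying a random spanning tree
rand_net <- function(name, n, p = 0.4, connected = FALSE) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (connected) {
      t <- igraph::sample_tree(n)
      g <- igraph::union(g, t)
    }
    el <- igraph::as_edgelist(g)
    if (nrow(el) >= 1L) break
  }
  w <- round(stats::runif(nrow(el), 0.5, 3), 3)
  ppi_network(name, data.frame(from = paste0("v", el[, 1L]),
                               to = paste0("v", el[, 2L]), weight = w,
                               stringsAsFactors = FALSE),
              nodes = paste0("v", seq_len(n)))
}

rand_sim <- function(net_a, net_b, density = 0.5, max_score = 50) {
  na <- length(net_a$nodes); nb <- length(net_b$nodes)
  grid <- expand.grid(node_a = net_a$nodes, node_b = net_b$nodes,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < density
  if (!any(keep)) keep[sample.int(nrow(grid), 1L)] <- TRUE
  grid <- grid[keep, , drop = FALSE]
  grid$score <- round(stats::runif(nrow(grid), 1, max_score), 3)
  similarity_scores(net_a, net_b, grid)
}

# --- SMRW oracle --------------------------------------------------------
# Explicit product-graph semi-Markov occupancy: build the dense product
# adjacency (Kronecker product of the two adjacency matrices), take the
# product walk's stationary law proportional to product weighted degree,
# multiply by the holding time h and renormalize over the support.
oracle_product_occupancy <- function(net_a, net_b, sim) {
  A <- as.matrix(net_a$adj); B <- as.matrix(net_b$adj)
  H <- as.matrix(sim$mat)
  W <- kronecker(B, A)                     # state (x, y) = index x + (y-1)*na
  deg <- rowSums(W)
  stat <- deg / sum(deg)
  occ <- stat * as.vector(H)               # H[x, y] in column-major order
  occ[as.vector(H) <= 0] <- 0
  matrix(occ / sum(occ), nrow = nrow(A),
         dimnames = list(net_a$nodes, net_b$nodes))
}

# stationary check for the explicit product chain: pi %*% T = pi on the
# support of the walk (rows with positive degree)
oracle_product_stationary_residual <- function(net_a, net_b) {
  A <- as.matrix(net_a$adj); B <- as.matrix(net_b$adj)
  W <- kronecker(B, A)
  deg <- rowSums(W)
  live <- deg > 0
  Tm <- W[live, live, drop = FALSE] / deg[live]
  stat <- deg[live] / sum(deg[live])
  max(abs(as.vector(stat %*% Tm) - stat))
}

# --- consistency oracles ------------------------------------------------
# quadruple-loop intra-network transformation (no sparsity filter)
oracle_intra <- function(P, A, B, alpha) {
  Ta <- A / ifelse(rowSums(A) > 0, rowSums(A), 1)
  Tb <- B / ifelse(rowSums(B) > 0, rowSums(B), 1)
  Q <- matrix(0, nrow(P), ncol(P))
  for (x in seq_len(nrow(P))) for (y in seq_len(ncol(P))) {
    s <- 0
    for (xp in seq_len(nrow(P))) for (yp in seq_len(ncol(P))) {
      s <- s + Ta[x, xp] * Tb[y, yp] * P[xp, yp]
    }
    Q[x, y] <- alpha * P[x, y] + (1 - alpha) * s
  }
  Q
}

# triple-loop cross-network transformation over intermediates `mats` is a
# named list of lists: mats[[a]][[b]] = dense matrix for ordered pair
oracle_cross <- function(mats, w, nets, a, b) {
  P_ab <- mats[[a]][[b]]
  acc <- 0 * P_ab
  total <- 0
  for (z in nets) {
    r <- w[[paste(sort(c(a, z)), collapse = "|")]] *
      w[[paste(sort(c(z, b)), collapse = "|")]]
    if (z %in% c(a, b)) r <- w[[paste(sort(c(a, b)), collapse = "|")]]
    if (r == 0) next
    term <- if (z %in% c(a, b)) P_ab else mats[[a]][[z]] %*% mats[[z]][[b]]
    acc <- acc + r * term
    total <- total + r
  }
  pmin(acc / total, 1)   # matches the implementation's probability clamp
}

# --- matching oracle ----------------------------------------------------
# exhaustive maximum-weight bipartite matching by permutation enumeration
# of the zero-padded square matrix (weights >= 0, so the best permutation
# attains the best matching weight)
oracle_max_matching <- function(M) {
  n <- max(dim(M))
  S <- matrix(0, n, n)
  S[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- 0
  for (p in perms(seq_len(n))) {
    best <- max(best, sum(S[cbind(seq_len(n), p)]))
  }
  best
}

# --- conserved-interaction oracle --------------------------------------
# brute-force loop over class pairs, network pairs and edges: a u-edge
# (first network of the pair, in input order) between two distinct classes
# counts once if the second network has any edge between the same classes
oracle_ci <- function(alignment, networks, ann = NULL) {
  cls <- alignment$classes
  key <- function(net, node) paste(net, node, sep = "::")
  member <- function(cl, net, node) any(cl$net == net & cl$node == node)
  correct <- function(cl) {
    lab <- ann[key(cl$net, cl$node)]
    !anyNA(lab) && length(unique(lab)) == 1L
  }
  ci <- 0L; coi <- 0L
  nn <- length(networks)
  if (length(cls) < 2L) return(list(ci = 0L, coi = 0L))
  for (c1 in seq_along(cls)) for (c2 in seq_along(cls)) {
    if (c1 >= c2) next
    for (u in seq_len(nn)) for (v in seq_len(nn)) {
      if (u >= v) next
      eu <- network_edges(networks[[u]])
      ev <- network_edges(networks[[v]])
      between <- function(ed, net, i, j) {
        (member(cls[[i]], net, ed$from) & member(cls[[j]], net, ed$to)) |
          (member(cls[[j]], net, ed$from) & member(cls[[i]], net, ed$to))
      }
      if (nrow(ev) == 0L || nrow(eu) == 0L) next
      vu <- vapply(seq_len(nrow(ev)), function(r) {
        between(ev[r, ], networks[[v]]$name, c1, c2)
      }, TRUE)
      if (!any(vu)) next
      for (r in seq_len(nrow(eu))) {
        if (between(eu[r, ], networks[[u]]$name, c1, c2)) {
          ci <- ci + 1L
          if (!is.null(ann) && correct(cls[[c1]]) && correct(cls[[c2]])) {
            coi <- coi + 1L
          }
        }
      }
    }
  }
  list(ci = ci, coi = coi)
}

# dense matrix -> prob_matrix helper for hand-constructed cases
pm_from_matrix <- function(net_a, net_b, M, stage = "raw",
                           rn = NULL, cn = NULL) {
  if (is.null(rn)) rn <- paste0("a", seq_len(nrow(M)))
  if (is.null(cn)) cn <- paste0("b", seq_len(ncol(M)))
  dimnames(M) <- list(rn, cn)
  smrwalign:::new_prob_matrix(net_a, net_b,
                              methods::as(Matrix::Matrix(M, sparse = TRUE),
                                          "CsparseMatrix"), stage)
}
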