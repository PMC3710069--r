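# Greedy maximum-expected-accuracy (MEA) alignment construction.
#
# With consistency-transformed probabilities as posteriors, the exact MEA
# problem is maximum-weight n-partite matching (NP-hard), so the alignment
# is grown greedily: node pairs are visited in decreasing probability
# order and inserted into equivalence classes subject to a per-network
# cardinality cap and a coherence test that keeps a new same-network node
# from joining a class it fits much worse than the incumbents do.

# mean alignment probability of (net, node) against the members of
# `cls` (data frame net/node) drawn from other networks; absent sparse
# entries count as 0
.coherence <- function(idx, net, node, cls) {
  other <- cls[cls$net != net, , drop = FALSE]
  if (nrow(other) == 0L) {
    stop("coherence is undefined: class has no members from a network ",
         "other than '", net, "'")
  }
  total <- 0
  for (zn in unique(other$net)) {
    znodes <- other$node[other$net == zn]
    k <- pair_key(net, zn)
    if (exists(k, envir = idx, inherits = FALSE)) {
      m <- get(k, envir = idx, inherits = FALSE)$m
      total <- total + sum(m[node, znodes])
    } else {
      m <- get(pair_key(zn, net), envir = idx, inherits = FALSE)$m
      total <- total + sum(m[znodes, node])
    }
  }
  total / nrow(other)
}

#' Coherence of a node with an equivalence class
#'
#' The probability of appearance of a node in an alignment group: the mean
#' of its pairwise alignment probabilities against the class members that
#' belong to other networks. Pairs absent from the sparse probability
#' matrices contribute 0.
#'
#' @param x length-2 character vector `c(network, node)`
#' @param cls data frame with columns `net`, `node` (an equivalence class);
#'   must contain at least one member from a network other than `x`'s
#' @param probs list of `prob_matrix` objects covering the needed pairs
#' @return the mean probability, a number in \[0, 1\]
#' @export
coherence_probability <- function(x, cls, probs) {
  .coherence(.pm_index(probs), x[[1L]], x[[2L]], as.data.frame(cls))
}

#' Greedy maximum-expected-accuracy multiple alignment
#'
#' Visits all candidate node pairs across all network pairs in strictly
#' decreasing probability order (ties broken lexicographically for
#' determinism). A pair of unassigned nodes opens a new class. If exactly
#' one node is already in a class C, the free node is inserted when (i) its
#' network's cap `max_per_net` is respected and (ii) if C already holds
#' nodes from that network, its coherence with C is at least `gamma` times
#' their average coherence. Pairs whose nodes are both already assigned are
#' skipped (classes are never merged). Classes left with fewer than two
#' members are dropped from the output.
#'
#' @param probs list of `prob_matrix` objects, one per unordered network
#'   pair (any stage; conventionally cross-transformed)
#' @param config a [run_config()] (uses `gamma` and `max_per_net`)
#' @param log_provenance record the decision taken for every candidate
#'   pair in the returned alignment's `provenance` data frame
#' @return a [network_alignment]
#' @export
greedy_mea_align <- function(probs, config = run_config(),
                             log_provenance = FALSE) {
  idx <- .pm_index(probs)
  cand <- do.call(rbind, lapply(probs, function(pm) {
    tr <- .sp_triplets(pm$m)
    tr <- tr[tr$x > 0, , drop = FALSE]
    data.frame(p = tr$x,
               na = pm$net_a, ia = rownames(pm$m)[tr$i],
               nb = pm$net_b, ib = colnames(pm$m)[tr$j],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(network_alignment(list()))
  }
  ord <- order(-cand$p, cand$na, cand$ia, cand$nb, cand$ib, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  n <- nrow(cand)

  assign_env <- new.env(parent = emptyenv())
  classes <- vector("list", 0L)
  action <- if (log_provenance) character(n) else NULL
  kx_all <- node_key(cand$na, cand$ia)
  ky_all <- node_key(cand$nb, cand$ib)

  for (t in seq_len(n)) {
    kx <- kx_all[[t]]; ky <- ky_all[[t]]
    cx <- get0(kx, envir = assign_env, inherits = FALSE)
    cy <- get0(ky, envir = assign_env, inherits = FALSE)
    if (!is.null(cx) && !is.null(cy)) {
      if (log_provenance) action[[t]] <- "skip-both-assigned"
      next
    }
    if (is.null(cx) && is.null(cy)) {
      cid <- length(classes) + 1L
      classes[[cid]] <- data.frame(net = c(cand$na[[t]], cand$nb[[t]]),
                                   node = c(cand$ia[[t]], cand$ib[[t]]),
                                   stringsAsFactors = FALSE)
      assign(kx, cid, envir = assign_env)
      assign(ky, cid, envir = assign_env)
      if (log_provenance) action[[t]] <- "open"
      next
    }
    if (is.null(cy)) {
      cid <- cx; f_net <- cand$nb[[t]]; f_node <- cand$ib[[t]]; f_key <- ky
    } else {
      cid <- cy; f_net <- cand$na[[t]]; f_node <- cand$ia[[t]]; f_key <- kx
    }
    cls <- classes[[cid]]
    same <- cls$net == f_net
    if (sum(same) >= config$max_per_net) {
      if (log_provenance) action[[t]] <- "reject-cap"
      next
    }
    if (any(same)) {
      coh_f <- .coherence(idx, f_net, f_node, cls)
      coh_in <- vapply(which(same), function(r) {
        .coherence(idx, f_net, cls$node[[r]], cls[-r, , drop = FALSE])
      }, 0)
      if (coh_f < config$gamma * mean(coh_in)) {
        if (log_provenance) action[[t]] <- "reject-coherence"
        next
      }
      if (log_provenance) action[[t]] <- "insert-same-net"
    } else {
      if (log_provenance) action[[t]] <- "insert-new-net"
    }
    classes[[cid]] <- rbind(cls, data.frame(net = f_net, node = f_node,
                                            stringsAsFactors = FALSE))
    assign(f_key, cid, envir = assign_env)
  }

  keep <- vapply(classes, nrow, 0L) >= 2L
  prov <- NULL
  if (log_provenance) {
    prov <- cbind(cand, data.frame(action = action, stringsAsFactors = FALSE))
  }
  network_alignment(classes[keep], provenance = prov)
}

# canonical keys of the cross-network node pairs induced by an alignment:
# each class induces all unordered member pairs drawn from two different
# networks
.induced_pairs <- function(alignment) {
  out <- lapply(alignment$classes, function(cl) {
    m <- nrow(cl)
    if (m < 2L) return(character())
    keys <- node_key(cl$net, cl$node)
    ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    cross <- cl$net[ij[, 1L]] != cl$net[ij[, 2L]]
    if (!any(cross)) return(character())
    a <- keys[ij[cross, 1L]]; b <- keys[ij[cross, 2L]]
    paste(pmin(a, b), pmax(a, b), sep = "\t")
  })
  unique(unlist(out))
}

#' Pairwise accuracy of an alignment against a reference
#'
#' The relative proportion of correctly matched nodes: each equivalence
#' class induces all its cross-network member pairs, and the accuracy is
#' the fraction of the reference's induced pairs that the predicted
#' alignment also induces.
#'
#' @param predicted,truth [network_alignment] objects; `truth` must induce
#'   at least one cross-network pair
#' @return a number in \[0, 1\]
#' @export
pair_accuracy <- function(predicted, truth) {
  tp <- .induced_pairs(truth)
  if (length(tp) == 0L) stop("reference alignment induces no cross-network pairs")
  pp <- .induced_pairs(predicted)
  length(intersect(pp, tp)) / length(tp)
}
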