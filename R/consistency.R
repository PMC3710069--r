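# Probabilistic consistency transformations.
#
# Two refinements of the raw pairwise alignment probabilities:
#   * intra-network: nodes whose neighbors align well are themselves more
#     likely to align, so each probability is mixed with a random-walk
#     average of its neighbors' probabilities;
#   * cross-network: every third network serves as an intermediate — if x
#     aligns with w and w aligns with y then x should align with y — with
#     intermediates weighted by how homologous they are to both endpoint
#     networks.
# After either transformation, entries outside the original support are
# kept only if they rank in the top `top_fraction` of transformed values
# (closed threshold: ties at the cutoff are kept), so sparsity never grows
# beyond support plus the top quantile set.

# keep transformed entries on the original support, plus the global
# top-`top_fraction` of transformed values (per network pair)
.support_filter <- function(orig_m, trans_m, top_fraction) {
  tr <- .sp_triplets(trans_m)
  if (nrow(tr) == 0L) return(trans_m)
  k <- ceiling(top_fraction * nrow(tr))
  cutoff <- sort(tr$x, decreasing = TRUE)[min(k, nrow(tr))]
  os <- .sp_triplets(orig_m)
  in_support <- paste(tr$i, tr$j) %in% paste(os$i, os$j)
  keep <- in_support | tr$x >= cutoff
  Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep],
                       dims = dim(trans_m), dimnames = dimnames(trans_m))
}

#' Intra-network probabilistic consistency transformation
#'
#' Mixes each pairwise alignment probability with the transition-weighted
#' average of the neighbors' probabilities:
#' `q(x,y) = alpha * p(x,y) + (1-alpha) * sum over neighbors x' of x and
#' y' of y of trans_a(x,x') * trans_b(y,y') * p(x',y')`. A node with no
#' neighbors contributes an empty sum, so its entries are simply scaled by
#' `alpha`. Entries outside the support of `p` survive only if they rank
#' in the top `top_fraction` of transformed values.
#'
#' @param p a raw-stage `prob_matrix` for networks (a, b)
#' @param tm_a,tm_b the two [build_transition_model()] results
#' @param alpha mixing weight on the original probability, in \[0, 1\]
#' @param top_fraction sparsity-filter quantile in (0, 1\]
#' @return a `prob_matrix` with `stage = "intra"`
#' @export
intra_transform <- function(p, tm_a, tm_b, alpha = 0.9, top_fraction = 0.01) {
  stopifnot(inherits(p, "prob_matrix"), alpha >= 0, alpha <= 1)
  if (!identical(p$net_a, tm_a$network) || !identical(p$net_b, tm_b$network)) {
    stop("probability matrix (", p$net_a, ", ", p$net_b,
         ") does not match transition models")
  }
  if (alpha == 1) {
    q <- p$m
  } else {
    neigh <- tm_a$trans %*% p$m %*% Matrix::t(tm_b$trans)
    q <- alpha * p$m + (1 - alpha) * neigh
    q <- .support_filter(p$m, q, top_fraction)
  }
  new_prob_matrix(p$net_a, p$net_b, q, "intra")
}

#' Network homology weight
#'
#' Estimates the probability that two networks are homologous as the total
#' weight of the maximum-weight bipartite matching of their alignment
#' probability matrix, normalized by the smaller network's size (default)
#' or by the matching cardinality, and clamped to \[0, 1\]. Two identical
#' networks with perfect alignment probabilities score exactly 1 under the
#' default normalizer.
#'
#' @param p a `prob_matrix` (conventionally intra-stage)
#' @param normalizer `"min_size"` or `"matching_size"`
#' @return object of class `homology_weight` with fields `net_a`, `net_b`,
#'   `value` and `matching` (data frame `node_a`, `node_b`, `p`)
#' @export
homology_weight <- function(p, normalizer = c("min_size", "matching_size")) {
  stopifnot(inherits(p, "prob_matrix"))
  normalizer <- match.arg(normalizer)
  na <- nrow(p$m); nb <- ncol(p$m)
  tr <- .sp_triplets(p$m)
  tr <- tr[tr$x > 0, , drop = FALSE]
  empty <- data.frame(node_a = character(), node_b = character(),
                      p = numeric(), stringsAsFactors = FALSE)
  if (nrow(tr) == 0L) {
    return(structure(list(net_a = p$net_a, net_b = p$net_b, value = 0,
                          matching = empty),
                     class = "homology_weight"))
  }
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    rbind(tr$i, na + tr$j), directed = FALSE)
  mm <- igraph::max_bipartite_match(g, weights = tr$x)
  mi <- mm$matching[seq_len(na)]
  hit <- !is.na(mi)
  matching <- data.frame(node_a = rownames(p$m)[which(hit)],
                         node_b = colnames(p$m)[mi[hit] - na],
                         p = p$m[cbind(which(hit), mi[hit] - na)],
                         stringsAsFactors = FALSE)
  denom <- if (normalizer == "min_size") min(na, nb) else nrow(matching)
  value <- if (denom > 0) min(1, max(0, sum(matching$p) / denom)) else 0
  structure(list(net_a = p$net_a, net_b = p$net_b, value = value,
                 matching = matching),
            class = "homology_weight")
}

# --- collections over network pairs ------------------------------------

# index a list of prob_matrix objects by unordered network pair
.pm_index <- function(all_p) {
  idx <- new.env(parent = emptyenv())
  for (pm in all_p) {
    stopifnot(inherits(pm, "prob_matrix"))
    assign(pair_key(pm$net_a, pm$net_b), pm, envir = idx)
  }
  idx
}

# oriented sparse matrix for the ordered pair (a, b), a != b
.pm_oriented <- function(idx, a, b) {
  k <- pair_key(a, b)
  if (exists(k, envir = idx, inherits = FALSE)) {
    return(get(k, envir = idx, inherits = FALSE)$m)
  }
  k2 <- pair_key(b, a)
  if (exists(k2, envir = idx, inherits = FALSE)) {
    return(Matrix::t(get(k2, envir = idx, inherits = FALSE)$m))
  }
  stop("no probability matrix for network pair (", a, ", ", b, ")")
}

# homology weight lookup; weight(a, a) = 1 by convention
.hw_value <- function(weights, a, b) {
  if (a == b) return(1)
  for (w in weights) {
    if ((w$net_a == a && w$net_b == b) || (w$net_a == b && w$net_b == a)) {
      return(w$value)
    }
  }
  stop("no homology weight for network pair (", a, ", ", b, ")")
}

#' Cross-network probabilistic consistency transformation
#'
#' Updates the (a, b) alignment probabilities using every network z as an
#' intermediate: the two-hop product `P_az %*% P_zb` propagates alignment
#' evidence through z, and each intermediate is weighted by
#' `r_z = weight(a,z) * weight(z,b)`, its estimated homology to both
#' endpoints. The endpoints themselves act as intermediates through
#' identity hops (`P_aa = I`, `weight(a,a) = 1`), so direct evidence is
#' never discarded; with only two networks in the run the transformation
#' is the identity. The weighted sum is normalized by the total
#' intermediate weight, keeping entries in \[0, 1\]. The support filter of
#' [intra_transform()] is applied afterwards.
#'
#' @param all_p list of intra-stage `prob_matrix` objects, one per
#'   unordered network pair in the run
#' @param weights list of [homology_weight()] objects, one per unordered
#'   network pair
#' @param net_a,net_b names of the pair being transformed
#' @param networks character vector of all network names in the run;
#'   defaults to every name appearing in `all_p`
#' @param top_fraction sparsity-filter quantile in (0, 1\]
#' @return a `prob_matrix` with `stage = "cross"`
#' @export
cross_transform <- function(all_p, weights, net_a, net_b, networks = NULL,
                            top_fraction = 0.01) {
  idx <- .pm_index(all_p)
  if (is.null(networks)) {
    networks <- sort(unique(unlist(lapply(all_p,
                                          function(pm) c(pm$net_a, pm$net_b)))))
  }
  p_ab <- .pm_oriented(idx, net_a, net_b)
  acc <- p_ab * 0
  total <- 0
  for (z in networks) {
    # weight(a, a) = 1, so for z in {a, b} this reduces to weight(a, b)
    r_z <- .hw_value(weights, net_a, z) * .hw_value(weights, z, net_b)
    if (r_z == 0) next
    if (z == net_a || z == net_b) {
      term <- p_ab                      # identity hop: P_aa = I
    } else {
      term <- .pm_oriented(idx, net_a, z) %*% .pm_oriented(idx, z, net_b)
    }
    acc <- acc + r_z * term
    total <- total + r_z
  }
  if (total == 0) {
    # no homologous intermediates at all: leave the pair untouched
    return(new_prob_matrix(net_a, net_b, p_ab, "cross"))
  }
  q <- acc / total
  # two-hop products of matrices that are not row-stochastic can edge past
  # 1; clamp so the probability contract holds
  tr <- .sp_triplets(q)
  over <- tr$x > 1
  if (any(over)) {
    q <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = pmin(tr$x, 1),
                              dims = dim(q), dimnames = dimnames(q))
  }
  q <- .support_filter(p_ab, q, top_fraction)
  new_prob_matrix(net_a, net_b, q, "cross")
}
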