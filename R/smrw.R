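# Semi-Markov random-walk correspondence scores and pairwise node
# alignment probabilities.
#
# A simultaneous random walk on two networks is a walk on their product
# graph; giving the product state (x, y) a mean holding time equal to the
# node similarity h(x, y) turns it into a semi-Markov walk whose long-run
# occupancy — stationary probability times holding time, renormalized —
# serves as a global correspondence score between x and y. Because the
# walk on an undirected weighted graph is reversible, the stationary
# probability of the product state factorizes into the per-network
# weighted-degree laws, giving a closed form that never materializes the
# dense product graph.

#' Build the random-walk transition model of a network
#'
#' Transition probabilities are weight-proportional over each node's
#' neighbors, and the stationary distribution is the weighted-degree law
#' (detailed balance of a reversible walk on an undirected weighted graph).
#' Isolated nodes get an empty transition row and stationary probability 0.
#'
#' @param network a [ppi_network] with at least one edge
#' @return object of class `transition_model` with fields `network` (name),
#'   `trans` (sparse row-stochastic matrix), `stat` (named stationary
#'   probabilities) and `nodes`
#' @export
build_transition_model <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  d <- Matrix::rowSums(network$adj)
  if (sum(d) == 0) stop("no interactions in network '", network$name, "'")
  inv <- ifelse(d > 0, 1 / d, 0)
  trans <- Matrix::Diagonal(x = inv) %*% network$adj
  dimnames(trans) <- dimnames(network$adj)
  structure(list(network = network$name,
                 trans = methods::as(trans, "CsparseMatrix"),
                 stat = stats::setNames(as.numeric(d / sum(d)),
                                        network$nodes),
                 nodes = network$nodes),
            class = "transition_model")
}

#' Semi-Markov random-walk correspondence scores for a network pair
#'
#' The score of a node pair (x, y) is the long-run fraction of time the
#' simultaneous walk occupies product state (x, y) when that state's mean
#' holding time is the similarity score h(x, y): stationary probability of
#' x times stationary probability of y times h(x, y), renormalized over the
#' similarity support. Pairs involving isolated nodes (stationary
#' probability 0) are excluded from the walk.
#'
#' @param tm_a,tm_b [build_transition_model()] results for the two networks
#' @param sim [similarity_scores] for the (a, b) pair
#' @return object of class `corr_matrix`: fields `net_a`, `net_b`, `m`
#'   (sparse matrix over the support, summing to 1)
#' @export
correspondence_scores <- function(tm_a, tm_b, sim) {
  stopifnot(inherits(tm_a, "transition_model"),
            inherits(tm_b, "transition_model"),
            inherits(sim, "similarity_scores"))
  if (!identical(sim$net_a, tm_a$network) ||
      !identical(sim$net_b, tm_b$network)) {
    stop("similarity table (", sim$net_a, ", ", sim$net_b,
         ") does not match transition models (", tm_a$network, ", ",
         tm_b$network, ")")
  }
  tr <- .sp_triplets(sim$mat)
  x <- tm_a$stat[tr$i] * tm_b$stat[tr$j] * tr$x
  keep <- x > 0
  if (!any(keep)) {
    stop("empty correspondence support: no positive similarity between ",
         "non-isolated nodes of '", tm_a$network, "' and '", tm_b$network, "'")
  }
  m <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep],
                            x = x[keep] / sum(x[keep]),
                            dims = dim(sim$mat), dimnames = dimnames(sim$mat))
  structure(list(net_a = sim$net_a, net_b = sim$net_b, m = m),
            class = "corr_matrix")
}

new_prob_matrix <- function(net_a, net_b, m, stage) {
  structure(list(net_a = net_a, net_b = net_b,
                 m = methods::as(methods::as(m, "generalMatrix"),
                                 "CsparseMatrix"),
                 stage = stage),
            class = "prob_matrix")
}

#' @export
print.prob_matrix <- function(x, ...) {
  cat(sprintf("<prob_matrix %s~%s [%s]: %d x %d, %d nonzero>\n",
              x$net_a, x$net_b, x$stage, nrow(x$m), ncol(x$m),
              Matrix::nnzero(x$m)))
  invisible(x)
}

#' Transposed view of a probability matrix
#' @param pm a `prob_matrix`
#' @return the `prob_matrix` for the reversed network pair
#' @export
pm_transpose <- function(pm) {
  new_prob_matrix(pm$net_b, pm$net_a, Matrix::t(pm$m), pm$stage)
}

#' Pairwise node alignment probabilities from correspondence scores
#'
#' Each correspondence score is normalized in two ways — against all
#' competitors of x in the other network (row) and against all competitors
#' of y (column) — and the two are averaged. This balances the relative
#' importance of x for matching with y and vice versa, and makes the result
#' symmetric with respect to the network pair. Rows or columns with zero
#' total contribute zero to their term.
#'
#' @param corr a [correspondence_scores()] result
#' @return a `prob_matrix` with `stage = "raw"`, entries in \[0, 1\]
#' @export
alignment_probabilities <- function(corr) {
  stopifnot(inherits(corr, "corr_matrix"))
  tr <- .sp_triplets(corr$m)
  if (nrow(tr) == 0L) stop("empty correspondence matrix")
  rs <- Matrix::rowSums(corr$m)
  cs <- Matrix::colSums(corr$m)
  p <- 0.5 * (tr$x / rs[tr$i] + tr$x / cs[tr$j])
  m <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = p, dims = dim(corr$m),
                            dimnames = dimnames(corr$m))
  new_prob_matrix(corr$net_a, corr$net_b, m, "raw")
}
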