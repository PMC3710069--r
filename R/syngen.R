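# Synthetic network families with known orthology.
#
# Families of PPI-like networks are grown independently from a common
# random ancestral network by repeated node duplication with model-specific
# edge rewiring (DMC, DMR) or by crystal-growth attachment (CG). Every node
# carries an ancestral lineage label; nodes sharing a lineage across
# networks are orthologs, which yields a ground-truth alignment for free.
# Cross-network similarity scores are simulated from a background
# distribution plus a location shift ("bias") for ortholog pairs, emulating
# the separation between ortholog and non-ortholog sequence-score
# distributions.

.default_growth_params <- list(
  q_con = 0.35,  # DMC: probability of connecting the duplicate pair
  q_mod = 0.45,  # DMC: probability of rewiring each shared neighbor edge
  q_del = 0.4,   # DMR: probability of deleting each inherited edge
  q_new = 1,     # DMR: expected number of random new edges per duplication
  p_att = 0.4    # CG: attachment probability to each seed neighbor
)

# random connected graph: uniform random spanning tree + extra random edges
.random_connected <- function(n, extra_edges) {
  g <- igraph::sample_tree(n)
  nb <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  added <- 0L
  guard <- 0L
  while (added < extra_edges && guard < 50L * extra_edges) {
    ij <- sample.int(n, 2L)
    guard <- guard + 1L
    if (ij[1L] != ij[2L] && !(ij[2L] %in% nb[[ij[1L]]])) {
      nb[[ij[1L]]] <- c(nb[[ij[1L]]], ij[2L])
      nb[[ij[2L]]] <- c(nb[[ij[2L]]], ij[1L])
      added <- added + 1L
    }
  }
  nb
}

.nb_del <- function(nb, i, j) {
  nb[[i]] <- nb[[i]][nb[[i]] != j]
  nb[[j]] <- nb[[j]][nb[[j]] != i]
  nb
}

.nb_to_network <- function(nb, name) {
  n <- length(nb)
  nodes <- sprintf("p%d", seq_len(n))
  from <- rep.int(seq_len(n), lengths(nb))
  to <- unlist(nb, use.names = FALSE)
  keep <- from < to
  ppi_network(name, data.frame(from = nodes[from[keep]],
                               to = nodes[to[keep]], weight = 1,
                               stringsAsFactors = FALSE),
              nodes = nodes)
}

#' Grow a family of networks from a common ancestor
#'
#' Builds a random connected ancestral network, then grows one descendant
#' network per target size by repeated duplication (DMC or DMR) or
#' crystal-growth attachment (CG), recording each node's ancestral
#' lineage. Nodes sharing a lineage form the ground-truth ortholog
#' classes. CG attachment creates genuinely new nodes, which receive fresh
#' single-network lineages.
#'
#' @param model `"DMC"`, `"DMR"` or `"CG"`
#' @param ancestor_size number of nodes of the ancestral network
#' @param target_sizes integer vector, one descendant network per entry;
#'   every entry must be at least `ancestor_size`
#' @param params named list overriding the model parameters
#'   (`q_con`, `q_mod`, `q_del`, `q_new`, `p_att`,
#'   `ancestor_extra_edges`)
#' @param seed integer seed; identical seeds give identical families
#' @param names optional network names (default `net1`, `net2`, ...)
#' @return object of class `network_family`: fields `networks` (list of
#'   [ppi_network]), `truth` (a [network_alignment] partitioning all
#'   nodes), `lineages` (list of per-network lineage label vectors),
#'   `model`, `params`, `seed`
#' @export
grow_family <- function(model = c("DMC", "DMR", "CG"), ancestor_size,
                        target_sizes, params = list(), seed = NULL,
                        names = NULL) {
  model <- match.arg(model)
  stopifnot(ancestor_size >= 2L, length(target_sizes) >= 1L)
  if (any(target_sizes < ancestor_size)) {
    stop("every target size must be >= the ancestor size (",
         ancestor_size, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(.default_growth_params, params)
  if (is.null(p$ancestor_extra_edges)) {
    p$ancestor_extra_edges <- round(0.5 * ancestor_size)
  }
  if (is.null(names)) names <- sprintf("net%d", seq_along(target_sizes))

  anc <- .random_connected(ancestor_size, p$ancestor_extra_edges)
  networks <- vector("list", length(target_sizes))
  lineages <- vector("list", length(target_sizes))
  for (k in seq_along(target_sizes)) {
    nb <- anc
    lin <- sprintf("L%d", seq_len(ancestor_size))
    fresh <- 0L
    while (length(nb) < target_sizes[[k]]) {
      u <- sample.int(length(nb), 1L)   # source node of this growth step
      nb <- .grow_step_at(nb, model, p, u)
      if (model == "CG") {
        fresh <- fresh + 1L
        lin <- c(lin, sprintf("F_%s_%d", names[[k]], fresh))
      } else {
        lin <- c(lin, lin[[u]])
      }
    }
    networks[[k]] <- .nb_to_network(nb, names[[k]])
    lineages[[k]] <- stats::setNames(lin, networks[[k]]$nodes)
  }

  truth <- .lineage_truth(networks, lineages)
  structure(list(networks = networks, truth = truth, lineages = lineages,
                 model = model, params = p, seed = seed),
            class = "network_family")
}

# .grow_step with the source node chosen by the caller
.grow_step_at <- function(nb, model, params, u) {
  n <- length(nb)
  v <- n + 1L
  if (model == "CG") {
    att <- nb[[u]][stats::runif(length(nb[[u]])) < params$p_att]
    targets <- unique(c(u, att))
    nb[[v]] <- targets
    for (w in targets) nb[[w]] <- c(nb[[w]], v)
    return(nb)
  }
  inherited <- nb[[u]]
  nb[[v]] <- inherited
  for (w in inherited) nb[[w]] <- c(nb[[w]], v)
  if (model == "DMC") {
    for (w in inherited) {
      if (stats::runif(1L) < params$q_mod) {
        drop_from <- if (stats::runif(1L) < 0.5) u else v
        nb <- .nb_del(nb, drop_from, w)
      }
    }
    if (stats::runif(1L) < params$q_con) {
      nb[[u]] <- c(nb[[u]], v)
      nb[[v]] <- c(nb[[v]], u)
    }
  } else {
    for (w in inherited) {
      if (stats::runif(1L) < params$q_del) nb <- .nb_del(nb, v, w)
    }
    n_new <- stats::rbinom(1L, n, min(1, params$q_new / n))
    if (n_new > 0L) {
      pool <- setdiff(seq_len(n), c(v, nb[[v]]))
      new_t <- sample(pool, min(n_new, length(pool)))
      nb[[v]] <- c(nb[[v]], new_t)
      for (w in new_t) nb[[w]] <- c(nb[[w]], v)
    }
  }
  if (length(nb[[v]]) == 0L) {
    nb[[v]] <- u
    nb[[u]] <- c(nb[[u]], v)
  }
  nb
}

# ground-truth alignment: one class per lineage label, spanning networks
.lineage_truth <- function(networks, lineages) {
  rows <- do.call(rbind, lapply(seq_along(networks), function(k) {
    data.frame(net = networks[[k]]$name, node = networks[[k]]$nodes,
               lineage = unname(lineages[[k]]), stringsAsFactors = FALSE)
  }))
  network_alignment(unname(split(rows[c("net", "node")], rows$lineage)))
}

#' Score model for simulated node similarities
#'
#' Non-ortholog (background) scores follow a gamma distribution with the
#' given shape and rate — non-negative and right-tailed like sequence bit
#' scores. Ortholog scores follow the same distribution shifted up by
#' `bias`, so a larger `bias` strictly increases the separation between
#' the two distributions while leaving the background unchanged; at
#' `bias = 0` the two are identical.
#'
#' @param bias non-negative location shift added to ortholog scores
#' @param sparsity expected fraction of cross-network non-ortholog pairs
#'   that receive a background score (all other pairs score 0)
#' @param shape,rate gamma parameters of the background distribution
#' @return object of class `score_model`
#' @export
score_model <- function(bias = 0, sparsity = 0.005, shape = 2, rate = 0.05) {
  stopifnot(bias >= 0, sparsity >= 0, sparsity <= 1, shape > 0, rate > 0)
  structure(list(bias = bias, sparsity = sparsity, shape = shape,
                 rate = rate),
            class = "score_model")
}

#' Simulate cross-network similarity scores for a family
#'
#' Every cross-network ortholog pair (same truth lineage) draws a score
#' from the ortholog distribution (background + `bias`); a random
#' `sparsity` fraction of non-ortholog pairs draws from the background
#' distribution; all other pairs are absent. Collisions keep the larger
#' score.
#'
#' @param family a [grow_family()] result
#' @param sm a [score_model()]
#' @param seed integer seed
#' @return list of [similarity_scores], one per unordered network pair, in
#'   pair order (1,2), (1,3), ..., (n-1,n)
#' @export
simulate_scores <- function(family, sm = score_model(), seed = NULL) {
  stopifnot(inherits(family, "network_family"), inherits(sm, "score_model"))
  if (!is.null(seed)) set.seed(seed)
  nets <- family$networks
  out <- list()
  for (a in seq_along(nets)) {
    for (b in seq_along(nets)) {
      if (a >= b) next
      la <- family$lineages[[a]]; lb <- family$lineages[[b]]
      shared <- intersect(unique(la), unique(lb))
      orth <- do.call(rbind, lapply(shared, function(l) {
        expand.grid(node_a = names(la)[la == l], node_b = names(lb)[lb == l],
                    stringsAsFactors = FALSE)
      }))
      if (is.null(orth)) orth <- data.frame(node_a = character(),
                                            node_b = character())
      orth$score <- stats::rgamma(nrow(orth), sm$shape, sm$rate) + sm$bias
      na <- length(nets[[a]]$nodes); nb_ <- length(nets[[b]]$nodes)
      n_bg <- stats::rbinom(1L, na * nb_, sm$sparsity)
      bg <- data.frame(node_a = character(), node_b = character(),
                       score = numeric())
      if (n_bg > 0L) {
        idx <- sample.int(na * nb_, n_bg)
        bg <- data.frame(
          node_a = nets[[a]]$nodes[(idx - 1L) %% na + 1L],
          node_b = nets[[b]]$nodes[(idx - 1L) %/% na + 1L],
          score = stats::rgamma(n_bg, sm$shape, sm$rate),
          stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- similarity_scores(nets[[a]], nets[[b]],
                                                   rbind(orth, bg))
    }
  }
  out
}

#' Resample overlapping subnetworks from one parent network
#'
#' Emulates building a family of related networks by snowball-sampling a
#' large PPI network: each replicate starts from a randomly chosen
#' high-degree seed node (top decile of weighted degree) and repeatedly
#' inserts a random `growth_fraction` of the current node set's outside
#' neighbors, with induced edges, until the replicate exceeds `min_size`
#' nodes. Resampled nodes that descend from the same parent node form the
#' ground-truth classes.
#'
#' @param parent a [ppi_network]
#' @param count number of replicates
#' @param min_size growth stops once the replicate has more nodes than this
#' @param growth_fraction fraction of outside neighbors inserted per round
#' @param seed integer seed
#' @return a `network_family` (model `"resample"`)
#' @export
resample_subnetworks <- function(parent, count, min_size = 600,
                                 growth_fraction = 0.2, seed = NULL) {
  stopifnot(inherits(parent, "ppi_network"), count >= 1L,
            growth_fraction > 0, growth_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  wd <- weighted_degree(parent)
  hubs <- which(wd >= stats::quantile(wd, 0.9))
  n <- length(parent$nodes)
  networks <- vector("list", count)
  lineages <- vector("list", count)
  for (k in seq_len(count)) {
    cur <- sample(hubs, 1L)
    in_set <- logical(n)
    in_set[cur] <- TRUE
    while (sum(in_set) <= min_size) {
      outside <- setdiff(
        unique(methods::as(parent$adj[which(in_set), , drop = FALSE],
                           "TsparseMatrix")@j + 1L),
        which(in_set))
      if (length(outside) == 0L) {
        stop("growth stalled at ", sum(in_set), " nodes before reaching ",
             min_size, " (parent component too small)")
      }
      take <- max(1L, round(growth_fraction * length(outside)))
      in_set[sample(outside, min(take, length(outside)))] <- TRUE
    }
    keep <- which(in_set)
    sub <- parent$adj[keep, keep, drop = FALSE]
    tr <- .sp_triplets(sub)
    up <- tr$i < tr$j
    name <- sprintf("rep%d", k)
    networks[[k]] <- ppi_network(
      name,
      data.frame(from = parent$nodes[keep][tr$i[up]],
                 to = parent$nodes[keep][tr$j[up]],
                 weight = tr$x[up], stringsAsFactors = FALSE),
      nodes = parent$nodes[keep])
    lineages[[k]] <- stats::setNames(parent$nodes[keep],
                                     parent$nodes[keep])
  }
  truth <- .lineage_truth(networks, lineages)
  structure(list(networks = networks, truth = truth, lineages = lineages,
                 model = "resample",
                 params = list(min_size = min_size,
                               growth_fraction = growth_fraction),
                 seed = seed),
            class = "network_family")
}

#' Truth-derived annotation map of a family
#'
#' The ancestral lineage labels double as functional-group annotations, so
#' the alignment of a synthetic family can be scored with the standard
#' annotation-based measures. Nodes created after the networks diverged
#' (crystal-growth insertions, which belong to no ancestral family) are
#' left unannotated by default, mirroring unannotated proteins in real
#' PPI data; the evaluation protocol removes them before the accuracy
#' measures.
#'
#' @param family a `network_family`
#' @param include_fresh also annotate post-divergence nodes with their
#'   (single-network) fresh lineage labels
#' @return named character vector, `net::node` -> functional group
#' @export
family_annotations <- function(family, include_fresh = FALSE) {
  out <- unlist(lapply(seq_along(family$networks), function(k) {
    lin <- family$lineages[[k]]
    stats::setNames(unname(lin),
                    node_key(family$networks[[k]]$name, names(lin)))
  }))
  if (!include_fresh) out <- out[!startsWith(out, "F_")]
  out
}

#' Write a family (and optional scores) to a directory
#'
#' Writes one edge-list file per network (`<name>.tsv`), one similarity
#' file per network pair (`sim_<a>_<b>.tsv`), the truth cluster file
#' (`truth.clusters`) and the annotation file (`annotations.tsv`,
#' namespaced node tokens with lineage labels as groups).
#'
#' @param family a `network_family`
#' @param sims optional list of [similarity_scores] (from
#'   [simulate_scores()])
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_family <- function(family, sims = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (net in family$networks) {
    f <- file.path(dir, paste0(net$name, ".tsv"))
    write_network(net, f)
    files <- c(files, f)
  }
  for (sim in sims) {
    f <- file.path(dir, sprintf("sim_%s_%s.tsv", sim$net_a, sim$net_b))
    tr <- .sp_triplets(sim$mat)
    writeLines(sprintf("%s\t%s\t%s", rownames(sim$mat)[tr$i],
                       colnames(sim$mat)[tr$j],
                       formatC(tr$x, digits = 15, format = "g")), f)
    files <- c(files, f)
  }
  f <- file.path(dir, "truth.clusters")
  write_alignment(family$truth, f)
  files <- c(files, f)
  ann <- family_annotations(family)
  f <- file.path(dir, "annotations.tsv")
  writeLines(sprintf("%s\t%s", names(ann), unname(ann)), f)
  invisible(c(files, f))
}
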