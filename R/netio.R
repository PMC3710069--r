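# File formats and in-memory containers shared by the whole pipeline.
#
# Node identifiers are opaque strings, unique within a network. They are
# namespaced as "net::node" only at the input/output boundary (alignment and
# annotation files); internally every structure keeps (network, node) pairs
# distinct, so identical IDs in different networks never collide.

NODE_SEP <- "::"

node_key <- function(net, node) paste(net, node, sep = NODE_SEP)

pair_key <- function(a, b) paste(a, b, sep = "|")

# triplet view of any Matrix sparse class; the generalMatrix coercion
# materializes implicit diagonals of triangular/symmetric storage
.sp_triplets <- function(m) {
  Matrix::summary(methods::as(methods::as(m, "generalMatrix"),
                              "TsparseMatrix"))
}

#' Construct a PPI network
#'
#' A network is a set of proteins (nodes) and a set of weighted undirected
#' edges representing their interactions. Self-loops and duplicate edges are
#' not allowed; all weights must be strictly positive.
#'
#' @param name short label, unique within a run; must not contain `"|"` or
#'   `"::"` (reserved as separators in on-disk formats).
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Duplicate rows for the same unordered pair are resolved by
#'   keeping the maximum weight.
#' @param nodes optional character vector of node IDs; defaults to the IDs
#'   seen in `edges`. Extra IDs declare isolated nodes.
#' @return an object of class `ppi_network` with fields `name`, `nodes`, and
#'   `adj`, a symmetric sparse adjacency matrix of interaction weights.
#' @export
ppi_network <- function(name, edges, nodes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("\\|", name) || grepl(NODE_SEP, name, fixed = TRUE)) {
    stop("network name must not contain '|' or '", NODE_SEP, "': ", name)
  }
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    if (is.null(edges$weight)) edges$weight <- 1
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
      stop("all edge weights must be positive and finite")
    }
    loops <- edges$from == edges$to
    if (any(loops)) stop("self-loops are not allowed in ppi_network()")
    # canonical unordered orientation, then dedupe by maximum weight
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    ek <- paste(a, b, sep = "\r")
    w <- tapply(edges$weight, ek, max)
    keep <- !duplicated(ek)
    edges <- data.frame(from = a[keep], to = b[keep],
                        weight = as.numeric(w[ek[keep]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node IDs in 'nodes'")
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  if (nrow(edges) > 0L) {
    i <- idx[edges$from]; j <- idx[edges$to]
    adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                                x = c(edges$weight, edges$weight),
                                dims = c(n, n),
                                dimnames = list(nodes, nodes))
  } else {
    adj <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n),
                                dimnames = list(nodes, nodes))
  }
  structure(list(name = name, nodes = nodes, adj = adj),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), n_edges(x)))
  invisible(x)
}

#' Number of edges of a network
#' @param net a `ppi_network`
#' @return integer edge count
#' @export
n_edges <- function(net) as.integer(Matrix::nnzero(net$adj) / 2L)

#' Weighted node degrees
#' @param net a `ppi_network`
#' @return named numeric vector of weighted degrees (sum of incident weights)
#' @export
weighted_degree <- function(net) {
  stats::setNames(as.numeric(Matrix::rowSums(net$adj)), net$nodes)
}

#' Edge list of a network
#' @param net a `ppi_network`
#' @return data frame with columns `from`, `to`, `weight`, each unordered
#'   edge once with `from <= to`
#' @export
network_edges <- function(net) {
  tr <- .sp_triplets(net$adj)
  keep <- tr$i < tr$j
  data.frame(from = net$nodes[tr$i[keep]], to = net$nodes[tr$j[keep]],
             weight = tr$x[keep], stringsAsFactors = FALSE)
}

#' Read a network from an edge-list file
#'
#' Each non-comment line is `nodeA nodeB [weight]`, whitespace- or
#' tab-delimited; a missing weight defaults to 1. Lines starting with `#`
#' are ignored. Duplicate edges keep the maximum weight; self-loops are
#' silently dropped (a message reports how many).
#'
#' @param path edge-list file
#' @param name network label
#' @return a [ppi_network]
#' @export
read_network <- function(path, name) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge line %d in '%s': expected 'nodeA nodeB [weight]'",
                 ln[bad[1L]], path))
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  weight <- rep(1, length(toks))
  has_w <- nf == 3L
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(toks[has_w], `[[`, "", 3L)))
    if (anyNA(w)) {
      stop(sprintf("malformed weight on line %d in '%s'",
                   ln[has_w][which(is.na(w))[1L]], path))
    }
    if (any(w <= 0)) {
      stop(sprintf("non-positive weight on line %d in '%s'",
                   ln[has_w][which(w <= 0)[1L]], path))
    }
    weight[has_w] <- w
  }
  loops <- from == to
  if (any(loops)) {
    message(sprintf("read_network: dropped %d self-loop(s) in '%s'",
                    sum(loops), path))
  }
  ppi_network(name, data.frame(from = from[!loops], to = to[!loops],
                               weight = weight[!loops],
                               stringsAsFactors = FALSE),
              nodes = sort(unique(c(from, to))))
}

#' Write a network as an edge-list file
#'
#' Inverse of [read_network()]: the result reads back to an equal network
#' (up to node and edge order). Isolated nodes are recorded as comment
#' lines so the round trip preserves them.
#'
#' @param net a [ppi_network]
#' @param path output file
#' @export
write_network <- function(net, path) {
  ed <- network_edges(net)
  con <- file(path, "w")
  on.exit(close(con))
  iso <- setdiff(net$nodes, unique(c(ed$from, ed$to)))
  if (length(iso)) writeLines(paste("#node", iso), con)
  if (nrow(ed)) {
    writeLines(sprintf("%s\t%s\t%s", ed$from, ed$to,
                       formatC(ed$weight, digits = 15, format = "g")), con)
  }
  invisible(NULL)
}

#' Construct a cross-network similarity score table
#'
#' Holds the sparse node-similarity scores h(x, y) (typically BLAST bit
#' scores) for one ordered network pair. Only strictly positive scores are
#' stored.
#'
#' @param net_a,net_b the two `ppi_network`s
#' @param pairs data frame with columns `node_a`, `node_b`, `score`
#' @return object of class `similarity_scores` with fields `net_a`, `net_b`
#'   (names) and `mat`, a sparse |V_a| x |V_b| score matrix
#' @export
similarity_scores <- function(net_a, net_b, pairs) {
  stopifnot(inherits(net_a, "ppi_network"), inherits(net_b, "ppi_network"))
  pairs <- as.data.frame(pairs)
  na <- length(net_a$nodes); nb <- length(net_b$nodes)
  if (nrow(pairs)) {
    pairs$node_a <- as.character(pairs$node_a)
    pairs$node_b <- as.character(pairs$node_b)
    unknown_a <- setdiff(unique(pairs$node_a), net_a$nodes)
    if (length(unknown_a)) {
      stop(sprintf("similarity refers to node '%s' absent from network '%s'",
                   unknown_a[1L], net_a$name))
    }
    unknown_b <- setdiff(unique(pairs$node_b), net_b$nodes)
    if (length(unknown_b)) {
      stop(sprintf("similarity refers to node '%s' absent from network '%s'",
                   unknown_b[1L], net_b$name))
    }
    pairs <- pairs[is.finite(pairs$score) & pairs$score > 0, , drop = FALSE]
  }
  ia <- match(pairs$node_a, net_a$nodes)
  ib <- match(pairs$node_b, net_b$nodes)
  # duplicate pairs resolved by maximum, mirroring edge-weight semantics
  mat <- Matrix::sparseMatrix(i = ia, j = ib, x = pairs$score,
                              dims = c(na, nb),
                              dimnames = list(net_a$nodes, net_b$nodes),
                              use.last.ij = FALSE)
  if (nrow(pairs) && anyDuplicated(paste(ia, ib))) {
    key <- paste(ia, ib)
    mx <- tapply(pairs$score, key, max)
    keep <- !duplicated(key)
    mat <- Matrix::sparseMatrix(i = ia[keep], j = ib[keep],
                                x = as.numeric(mx[key[keep]]),
                                dims = c(na, nb),
                                dimnames = list(net_a$nodes, net_b$nodes))
  }
  structure(list(net_a = net_a$name, net_b = net_b$name, mat = mat),
            class = "similarity_scores")
}

#' Transposed view of a similarity table
#' @param sim a `similarity_scores`
#' @return the `similarity_scores` for the reversed network pair
#' @export
sim_transpose <- function(sim) {
  structure(list(net_a = sim$net_b, net_b = sim$net_a,
                 mat = Matrix::t(sim$mat)),
            class = "similarity_scores")
}

#' Read cross-network similarity scores
#'
#' Lines are `nodeA nodeB score`; `#` comments are ignored. Zero scores are
#' dropped; negative scores are an error, as is a node ID absent from the
#' corresponding network.
#'
#' @param path score file
#' @param net_a,net_b the networks the first/second column refers to
#' @return a [similarity_scores]
#' @export
read_similarity <- function(path, net_a, net_b) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed similarity line %d in '%s': expected 'nodeA nodeB score'",
                 ln[bad[1L]], path))
  }
  score <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
  if (anyNA(score)) {
    stop(sprintf("malformed score on line %d in '%s'",
                 ln[which(is.na(score))[1L]], path))
  }
  if (any(score < 0)) {
    stop(sprintf("negative score on line %d in '%s'",
                 ln[which(score < 0)[1L]], path))
  }
  similarity_scores(net_a, net_b,
                    data.frame(node_a = vapply(toks, `[[`, "", 1L),
                               node_b = vapply(toks, `[[`, "", 2L),
                               score = score, stringsAsFactors = FALSE))
}

#' Construct a multiple network alignment
#'
#' An alignment is a set of pairwise-disjoint equivalence classes; each
#' class is a set of (network, node) pairs regarded as putative orthologs.
#'
#' @param classes list of data frames, each with columns `net` and `node`
#' @param provenance optional data frame logging how the alignment was built
#' @return object of class `network_alignment`
#' @export
network_alignment <- function(classes = list(), provenance = NULL) {
  classes <- lapply(classes, function(cl) {
    cl <- as.data.frame(cl)
    data.frame(net = as.character(cl$net), node = as.character(cl$node),
               stringsAsFactors = FALSE)
  })
  keys <- unlist(lapply(classes, function(cl) node_key(cl$net, cl$node)))
  if (anyDuplicated(keys)) {
    stop("alignment classes are not disjoint: ",
         keys[duplicated(keys)][1L])
  }
  structure(list(classes = classes, provenance = provenance),
            class = "network_alignment")
}

#' @export
print.network_alignment <- function(x, ...) {
  sizes <- vapply(x$classes, nrow, 0L)
  cat(sprintf("<network_alignment: %d classes, %d aligned nodes>\n",
              length(x$classes), sum(sizes)))
  invisible(x)
}

#' Number of aligned nodes in an alignment
#' @param alignment a `network_alignment`
#' @return integer total member count over all classes
#' @export
n_aligned_nodes <- function(alignment) {
  sum(vapply(alignment$classes, nrow, 0L))
}

.class_line <- function(cl) {
  toks <- sort(node_key(cl$net, cl$node))
  paste(toks, collapse = "\t")
}

#' Write an alignment cluster file
#'
#' One line per equivalence class: tab-separated `net::node` tokens.
#' Classes are ordered by descending size, then lexicographically, so the
#' output is deterministic; [read_alignment()] restores the same alignment.
#'
#' @param alignment a [network_alignment]
#' @param path output file
#' @export
write_alignment <- function(alignment, path) {
  lines <- vapply(alignment$classes, .class_line, "")
  sizes <- vapply(alignment$classes, nrow, 0L)
  ord <- order(-sizes, lines)
  writeLines(lines[ord], path)
  invisible(NULL)
}

#' Read an alignment cluster file
#' @param path cluster file written by [write_alignment()]
#' @return a [network_alignment]
#' @export
read_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  classes <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\t")[[1L]]
    parts <- strsplit(toks, NODE_SEP, fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed alignment token: ", toks[bad][1L])
    data.frame(net = vapply(parts, `[[`, "", 1L),
               node = vapply(parts, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  })
  network_alignment(classes)
}

#' Read a node annotation file
#'
#' Each line maps a node to one functional group: `node<TAB>group`. The
#' node token may be namespaced (`net::node`); a bare token is expanded to
#' every network (in `networks`) that contains that node ID. Nodes absent
#' from the file are unannotated.
#'
#' @param path annotation file
#' @param networks optional list of `ppi_network`s used to expand bare
#'   node tokens
#' @return named character vector: `net::node` key -> functional group
#' @export
read_annotations <- function(path, networks = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed annotation line %d in '%s'",
                 which(keep)[bad[1L]], path))
  }
  node <- vapply(toks, `[[`, "", 1L)
  grp <- vapply(toks, `[[`, "", 2L)
  namespaced <- grepl(NODE_SEP, node, fixed = TRUE)
  out <- character()
  if (any(namespaced)) {
    out <- stats::setNames(grp[namespaced], node[namespaced])
  }
  if (any(!namespaced)) {
    if (is.null(networks)) {
      stop("bare node IDs in '", path,
           "' need 'networks' to resolve which network they belong to")
    }
    for (net in networks) {
      hit <- !namespaced & node %in% net$nodes
      if (any(hit)) {
        out <- c(out, stats::setNames(grp[hit], node_key(net$name, node[hit])))
      }
    }
  }
  out[!duplicated(names(out))]
}

#' Run configuration
#'
#' Bundles the tunable parameters of the alignment pipeline.
#'
#' @param alpha balance of the intra-network consistency transformation in
#'   \[0, 1\]: weight kept on the original pairwise alignment probability
#'   versus the neighborhood term. Default 0.9.
#' @param gamma coherence scaling factor in (0, 1\]: a candidate node joins
#'   an existing class only if its coherence is at least `gamma` times the
#'   average coherence of the class members from the same network.
#'   Default 0.8.
#' @param max_per_net cap on the number of nodes any one network may
#'   contribute to a single equivalence class. Default 10.
#' @param top_fraction sparsity-filter quantile in (0, 1\]: after each
#'   consistency transformation, entries outside the original support are
#'   kept only if they rank in this top fraction of transformed values.
#'   Default 0.01 (top 1 percent).
#' @param seed integer seed for the stochastic components (the synthetic
#'   generator); the aligner itself is deterministic.
#' @param homology_normalizer denominator of the network homology weight:
#'   `"min_size"` (smaller network's node count, default) or
#'   `"matching_size"` (cardinality of the maximum-weight matching).
#' @param ci_count conserved-interaction counting scope: `"per_pair"`
#'   counts each conserved edge once per network pair (default),
#'   `"global"` once over all network pairs.
#' @return object of class `run_config`
#' @export
run_config <- function(alpha = 0.9, gamma = 0.8, max_per_net = 10L,
                       top_fraction = 0.01, seed = 1L,
                       homology_normalizer = c("min_size", "matching_size"),
                       ci_count = c("per_pair", "global")) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(gamma), length(gamma) == 1L, gamma > 0, gamma <= 1,
            is.numeric(max_per_net), length(max_per_net) == 1L,
            max_per_net >= 1,
            is.numeric(top_fraction), length(top_fraction) == 1L,
            top_fraction > 0, top_fraction <= 1)
  structure(list(alpha = alpha, gamma = gamma,
                 max_per_net = as.integer(max_per_net),
                 top_fraction = top_fraction, seed = as.integer(seed),
                 homology_normalizer = match.arg(homology_normalizer),
                 ci_count = match.arg(ci_count)),
            class = "run_config")
}

#' Read a run configuration from a YAML-style key/value file
#'
#' Recognized keys are the arguments of [run_config()]; unknown keys are an
#' error. Values given in `overrides` (e.g. parsed CLI flags) win over the
#' file.
#'
#' @param path YAML file, or `NULL` for defaults
#' @param overrides named list of parameter overrides
#' @return a [run_config]
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (requireNamespace("yaml", quietly = TRUE)) {
      vals <- yaml::read_yaml(path)
    } else {
      lines <- readLines(path)
      lines <- lines[!grepl("^\\s*(#|$)", lines)]
      kv <- strsplit(lines, ":", fixed = TRUE)
      vals <- stats::setNames(
        lapply(kv, function(p) utils::type.convert(trimws(p[[2L]]),
                                                   as.is = TRUE)),
        trimws(vapply(kv, `[[`, "", 1L)))
    }
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
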