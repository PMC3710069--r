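# Evaluation measures for multiple network alignments.
#
# Accuracy measures (SPE, CN, MNE, sensitivity) are computed on a filtered
# alignment: unannotated nodes are removed from every class and classes
# reduced to a single node are dropped. Conservation (CI/COI) and coverage
# are computed on the unfiltered alignment.

.class_labels <- function(cl, ann) {
  unname(ann[node_key(cl$net, cl$node)])
}

# a class is correct when every member is annotated and all labels agree
.class_correct <- function(cl, ann) {
  lab <- .class_labels(cl, ann)
  !anyNA(lab) && length(unique(lab)) == 1L
}

#' Filter an alignment for accuracy evaluation
#'
#' Removes unannotated nodes from every equivalence class, then removes
#' classes containing only a single node.
#'
#' @param alignment a [network_alignment]
#' @param ann annotation map from [read_annotations()] (named character
#'   vector, `net::node` -> functional group)
#' @return the filtered [network_alignment]
#' @export
filter_for_eval <- function(alignment, ann) {
  classes <- lapply(alignment$classes, function(cl) {
    cl[node_key(cl$net, cl$node) %in% names(ann), , drop = FALSE]
  })
  network_alignment(classes[vapply(classes, nrow, 0L) >= 2L])
}

#' Specificity and correct-node count
#'
#' A class is correct when all of its members belong to the same
#' functional group. Specificity (SPE) is the percentage of correct
#' classes; CN is the total number of nodes in correct classes.
#'
#' @param alignment a filtered [network_alignment] (see [filter_for_eval()])
#' @param ann annotation map
#' @return list with `spe` (percentage) and `cn` (count)
#' @export
specificity_cn <- function(alignment, ann) {
  k <- length(alignment$classes)
  if (k == 0L) {
    warning("empty alignment: specificity is undefined, reporting 0")
    return(list(spe = 0, cn = 0L))
  }
  correct <- vapply(alignment$classes, .class_correct, TRUE, ann = ann)
  list(spe = 100 * sum(correct) / k,
       cn = sum(vapply(alignment$classes[correct], nrow, 0L)))
}

#' Mean normalized entropy of the equivalence classes
#'
#' For a class whose members split into d distinct functional groups with
#' fractions p_i, the normalized entropy is
#' `H = -(1 / log d) * sum(p_i * log p_i)` (0 for a pure class, 1 for a
#' uniform mixture). Returns the mean over classes, in \[0, 1\]; the
#' percentage rendering used in benchmark tables is 100 times this value.
#'
#' @param alignment a filtered [network_alignment]
#' @param ann annotation map
#' @return mean normalized entropy in \[0, 1\] (0 for an empty alignment)
#' @export
mean_normalized_entropy <- function(alignment, ann) {
  if (length(alignment$classes) == 0L) return(0)
  h <- vapply(alignment$classes, function(cl) {
    lab <- .class_labels(cl, ann)
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0L) return(0)
    p <- as.numeric(table(lab)) / length(lab)
    d <- length(p)
    if (d == 1L) return(0)
    -sum(p * log(p)) / log(d)
  }, 0)
  mean(h)
}

# per-network class-pair incidence of edges: for network `net` return the
# multiset of class-pair keys its edges connect (endpoints in two distinct
# classes of the alignment)
.edge_class_pairs <- function(net, class_of) {
  ed <- network_edges(net)
  if (nrow(ed) == 0L) return(character())
  c1 <- class_of[node_key(net$name, ed$from)]
  c2 <- class_of[node_key(net$name, ed$to)]
  keep <- !is.na(c1) & !is.na(c2) & c1 != c2
  if (!any(keep)) return(character())
  paste(pmin(c1[keep], c2[keep]), pmax(c1[keep], c2[keep]))
}

#' Conserved interactions between equivalence classes
#'
#' An edge of network u whose endpoints fall in two distinct equivalence
#' classes (C1, C2) is conserved with respect to network v when v has at
#' least one edge between the same class pair. CI counts conserved edges;
#' with `scope = "per_pair"` (default) each conserved edge of the first
#' network of every unordered network pair counts once per pair, with
#' `scope = "global"` each edge counts once if it is conserved in any
#' other network. COI is the same count restricted to class pairs in which
#' both classes are correct under the annotation (`NA` when `ann` is
#' missing). Edges internal to a single class are not counted.
#'
#' @param alignment a [network_alignment] (unfiltered)
#' @param networks list of the [ppi_network]s in the run
#' @param ann optional annotation map (needed for COI)
#' @param scope counting convention, `"per_pair"` or `"global"`
#' @return list with `ci` and `coi` counts
#' @export
conserved_interactions <- function(alignment, networks, ann = NULL,
                                   scope = c("per_pair", "global")) {
  scope <- match.arg(scope)
  nclass <- length(alignment$classes)
  class_of <- integer()
  if (nclass > 0L) {
    keys <- unlist(lapply(seq_len(nclass), function(i) {
      cl <- alignment$classes[[i]]
      stats::setNames(rep(i, nrow(cl)), node_key(cl$net, cl$node))
    }))
    class_of <- stats::setNames(as.integer(keys), names(keys))
  }
  inc <- lapply(networks, .edge_class_pairs, class_of = class_of)
  sets <- lapply(inc, unique)
  nn <- length(networks)

  correct_pair <- NULL
  if (!is.null(ann) && nclass > 0L) {
    ok <- vapply(alignment$classes, .class_correct, TRUE, ann = ann)
    correct_pair <- function(keys) {
      if (length(keys) == 0L) return(logical())
      ij <- strsplit(keys, " ", fixed = TRUE)
      ok[as.integer(vapply(ij, `[[`, "", 1L))] &
        ok[as.integer(vapply(ij, `[[`, "", 2L))]
    }
  }

  ci <- 0L; coi <- if (is.null(correct_pair)) NA_integer_ else 0L
  if (scope == "per_pair") {
    for (u in seq_len(nn)) {
      for (v in seq_len(nn)) {
        if (u >= v) next
        hit <- inc[[u]] %in% sets[[v]]
        ci <- ci + sum(hit)
        if (!is.null(correct_pair)) {
          coi <- coi + sum(hit & correct_pair(inc[[u]]))
        }
      }
    }
  } else {
    for (u in seq_len(nn)) {
      others <- unique(unlist(sets[-u]))
      hit <- inc[[u]] %in% others
      ci <- ci + sum(hit)
      if (!is.null(correct_pair)) {
        coi <- coi + sum(hit & correct_pair(inc[[u]]))
      }
    }
  }
  list(ci = as.integer(ci), coi = coi)
}

#' Coverage histograms of an alignment
#'
#' Classes and aligned nodes are binned by the number of distinct networks
#' a class spans.
#'
#' @param alignment a [network_alignment]
#' @param n_networks total number of networks in the run
#' @return list with `class_coverage` and `node_coverage`, named integer
#'   vectors over k = 1..n_networks
#' @export
coverage <- function(alignment, n_networks) {
  span <- vapply(alignment$classes, function(cl) length(unique(cl$net)), 0L)
  size <- vapply(alignment$classes, nrow, 0L)
  ks <- seq_len(n_networks)
  list(class_coverage = stats::setNames(
         vapply(ks, function(k) sum(span == k), 0L), ks),
       node_coverage = stats::setNames(
         vapply(ks, function(k) sum(size[span == k]), 0L), ks))
}

#' Sensitivity of an alignment
#'
#' The percentage of nodes (in the filtered alignment) that sit in a
#' correct equivalence class: `100 * CN / total aligned nodes`.
#'
#' @param alignment a filtered [network_alignment]
#' @param ann annotation map
#' @return percentage in \[0, 100\]
#' @export
sensitivity <- function(alignment, ann) {
  total <- n_aligned_nodes(alignment)
  if (total == 0L) {
    warning("empty alignment: sensitivity is undefined, reporting 0")
    return(0)
  }
  100 * specificity_cn(alignment, ann)$cn / total
}

#' Full evaluation report for an alignment
#'
#' Computes SPE, CN, MNE and sensitivity on the filtered alignment (see
#' [filter_for_eval()]) and CI/COI and coverage on the unfiltered one.
#'
#' @param alignment a [network_alignment]
#' @param ann annotation map
#' @param networks list of [ppi_network]s (needed for CI/COI; optional)
#' @param truth optional reference [network_alignment] for pair accuracy
#' @param require_all_species restrict the accuracy measures to classes
#'   containing at least one node from every network
#' @param config a [run_config()] (uses `ci_count`)
#' @return list of class `metrics_report` with fields `spe`, `cn`, `mne`,
#'   `mne_x100`, `sensitivity`, `ci`, `coi`, `class_coverage`,
#'   `node_coverage`, `n_classes`, `n_aligned_nodes`, and `pair_accuracy`
#'   when `truth` is given
#' @export
evaluate_alignment <- function(alignment, ann, networks = NULL, truth = NULL,
                               require_all_species = FALSE,
                               config = run_config()) {
  n_networks <- if (!is.null(networks)) length(networks) else
    length(unique(unlist(lapply(alignment$classes, function(cl) cl$net))))
  filt <- filter_for_eval(alignment, ann)
  if (require_all_species) {
    span <- vapply(filt$classes, function(cl) length(unique(cl$net)), 0L)
    filt <- network_alignment(filt$classes[span == n_networks])
  }
  sc <- suppressWarnings(specificity_cn(filt, ann))
  mne <- mean_normalized_entropy(filt, ann)
  cons <- if (!is.null(networks)) {
    conserved_interactions(alignment, networks, ann, scope = config$ci_count)
  } else list(ci = NA_integer_, coi = NA_integer_)
  cov <- coverage(alignment, n_networks)
  rep <- list(spe = sc$spe, cn = sc$cn, mne = mne, mne_x100 = 100 * mne,
              sensitivity = if (n_aligned_nodes(filt) > 0)
                100 * sc$cn / n_aligned_nodes(filt) else 0,
              ci = cons$ci, coi = cons$coi,
              class_coverage = cov$class_coverage,
              node_coverage = cov$node_coverage,
              n_classes = length(alignment$classes),
              n_aligned_nodes = n_aligned_nodes(alignment))
  if (!is.null(truth)) rep$pair_accuracy <- pair_accuracy(alignment, truth)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SPE %.2f%%  CN %d  MNE %.4f (x100: %.2f)  SEN %.2f%%\n",
              x$spe, x$cn, x$mne, x$mne_x100, x$sensitivity))
  if (!is.na(x$ci)) cat(sprintf("CI %d  COI %s\n", x$ci,
                                ifelse(is.na(x$coi), "NA", x$coi)))
  if (!is.null(x$pair_accuracy)) {
    cat(sprintf("pair accuracy %.4f\n", x$pair_accuracy))
  }
  cat("class coverage:", paste(names(x$class_coverage), x$class_coverage,
                               sep = ":", collapse = " "), "\n")
  invisible(x)
}
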