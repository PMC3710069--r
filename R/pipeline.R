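# End-to-end pipeline: transition models -> SMRW correspondence scores ->
# pairwise alignment probabilities -> intra-network consistency ->
# homology weights -> cross-network consistency -> greedy MEA alignment.

# find the similarity table for the ordered pair (a, b) in a list,
# transposing if it was supplied the other way round
.sim_for <- function(sims, a, b) {
  for (s in sims) {
    if (s$net_a == a && s$net_b == b) return(s)
    if (s$net_a == b && s$net_b == a) return(sim_transpose(s))
  }
  stop("missing similarity table for network pair (", a, ", ", b, ")")
}

#' Align multiple networks
#'
#' Runs the full probabilistic alignment pipeline on a set of networks and
#' their pairwise similarity tables. Both consistency transformations can
#' be ablated; with `skip_cross` (or only two networks) the cross-network
#' transformation is the identity.
#'
#' @param networks list of [ppi_network]s (at least two, distinct names)
#' @param sims list of [similarity_scores], one per unordered network pair
#' @param config a [run_config()]
#' @param skip_intra,skip_cross ablate the corresponding consistency
#'   transformation
#' @param log_provenance record per-candidate decisions in the alignment
#' @param verbose print per-stage progress to standard error
#' @return list of class `alignment_run`: `alignment` (a
#'   [network_alignment]), `probs` (final `prob_matrix` list), `weights`
#'   (homology weights; `NULL` when the cross stage is skipped) and
#'   `manifest` (config echo, stage timings, input summary)
#' @export
align_networks <- function(networks, sims, config = run_config(),
                           skip_intra = FALSE, skip_cross = FALSE,
                           log_provenance = FALSE, verbose = FALSE) {
  nms <- vapply(networks, function(x) x$name, "")
  if (length(networks) < 2L) stop("need at least two networks")
  if (anyDuplicated(nms)) stop("duplicate network names: ",
                               nms[duplicated(nms)][1L])
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()

  tms <- lapply(networks, build_transition_model)
  names(tms) <- nms
  timings["transition_models"] <- tic() - t0

  t0 <- tic()
  probs <- list()
  for (a in seq_along(nms)) {
    for (b in seq_along(nms)) {
      if (a >= b) next
      sim <- .sim_for(sims, nms[[a]], nms[[b]])
      corr <- correspondence_scores(tms[[a]], tms[[b]], sim)
      probs[[length(probs) + 1L]] <- alignment_probabilities(corr)
    }
  }
  say("computed SMRW probabilities for %d pairs", length(probs))
  timings["smrw"] <- tic() - t0

  if (!skip_intra) {
    t0 <- tic()
    probs <- lapply(probs, function(pm) {
      intra_transform(pm, tms[[pm$net_a]], tms[[pm$net_b]],
                      alpha = config$alpha,
                      top_fraction = config$top_fraction)
    })
    say("intra-network consistency done")
    timings["intra"] <- tic() - t0
  }

  weights <- NULL
  if (!skip_cross) {
    t0 <- tic()
    weights <- lapply(probs, homology_weight,
                      normalizer = config$homology_normalizer)
    timings["homology_weights"] <- tic() - t0
    t0 <- tic()
    probs <- lapply(probs, function(pm) {
      cross_transform(probs, weights, pm$net_a, pm$net_b, networks = nms,
                      top_fraction = config$top_fraction)
    })
    say("cross-network consistency done")
    timings["cross"] <- tic() - t0
  }

  t0 <- tic()
  alignment <- greedy_mea_align(probs, config,
                                log_provenance = log_provenance)
  timings["greedy"] <- tic() - t0
  say("greedy MEA alignment: %d classes, %d nodes",
      length(alignment$classes), n_aligned_nodes(alignment))

  manifest <- list(
    networks = data.frame(name = nms,
                          nodes = vapply(networks,
                                         function(x) length(x$nodes), 0L),
                          edges = vapply(networks, n_edges, 0L)),
    config = unclass(config),
    skip_intra = skip_intra, skip_cross = skip_cross,
    timings_s = as.list(timings),
    package_version = as.character(utils::packageVersion("smrwalign")))
  structure(list(alignment = alignment, probs = probs, weights = weights,
                 manifest = manifest),
            class = "alignment_run")
}

#' @export
print.alignment_run <- function(x, ...) {
  print(x$alignment)
  cat("stages:", paste(names(x$manifest$timings_s),
                       sprintf("%.2fs", unlist(x$manifest$timings_s)),
                       collapse = "  "), "\n")
  invisible(x)
}
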