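#' Contact matrix to interaction-graph edge sets
#'
#' Runs the full Hi-C front end: observed/expected scoring, per-chromosome
#' Weibull significance for intra-chromosomal pairs, neighbor-consistent
#' trans calls, and assembly with genomic adjacency and optional
#' structural-variant junctions.
#'
#' @param contacts a `contact_matrix` (assumed already normalized; use
#'   [vc_sqrt_normalize()] first for raw counts if desired).
#' @param alpha Weibull survival p-value cutoff (default 1e-5).
#' @param sv_pairs optional `data.frame` of junction bin pairs (`i`, `j`).
#' @param include_inter call trans pairs as well (default TRUE).
#' @param fit_on what the intra Weibull null is fitted to; see
#'   [significant_intra()].
#' @return an `interaction_graph`.
#' @export
contacts_to_graph <- function(contacts, alpha = 1e-5, sv_pairs = NULL,
                              include_inter = TRUE,
                              fit_on = c("oe_ratio", "contact")) {
  stopifnot(inherits(contacts, "contact_matrix"))
  intra <- significant_intra(contacts, alpha = alpha,
                             fit_on = match.arg(fit_on))
  inter <- if (include_inter)
    tryCatch(significant_inter(contacts, alpha = alpha),
             warning = function(w) data.frame(i = integer(), j = integer()),
             error = function(e) data.frame(i = integer(), j = integer()))
  else data.frame(i = integer(), j = integer())
  build_graph(contacts$bins, intra_pairs = intra, inter_pairs = inter,
              sv_pairs = sv_pairs)
}

#' End-to-end state inference from signals and contacts
#'
#' Convenience wrapper chaining [contacts_to_graph()] and [spin_fit()],
#' then speckle-ranking the states so that label 1 is most lamina-like and
#' label k most speckle-like.
#'
#' @param signals a `signal_matrix`.
#' @param contacts a `contact_matrix` on the same bins.
#' @param k number of states.
#' @param alpha Hi-C significance cutoff.
#' @param sv_pairs optional junction pairs.
#' @param speckle_channel channel used for ranking (default: first
#'   channel).
#' @param seed integer seed.
#' @param ... passed to [spin_fit()].
#' @return list with `graph` and the ranked `fit` (a `spin_fit`).
#' @export
spin_pipeline <- function(signals, contacts, k, alpha = 1e-5,
                          sv_pairs = NULL,
                          speckle_channel = signals$channels[1],
                          seed = 1, ...) {
  stopifnot(inherits(signals, "signal_matrix"))
  contacts$bins <- mask_bins(contacts$bins, signals$mask)
  graph <- contacts_to_graph(contacts, alpha = alpha, sv_pairs = sv_pairs)
  fit <- spin_fit(signals, graph, k = k, seed = seed, ...)
  fit <- relabel_states(fit, rank_states(fit$model, speckle_channel))
  list(graph = graph, fit = fit)
}
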