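# Internal constructor shared by build_subnetworks() and the rm_sub variant.
new_subnetwork_set <- function(nodes, ap, v, edges, w) {
  structure(list(m = ncol(ap), nodes = nodes, ap = ap, v = v,
                 edges = edges, w = w),
            class = "subnetwork_set")
}

#' Build active PPI sub-networks from an activity model
#'
#' One sub-network per expression sample point. An interaction (v, u)
#' enters sub-network i if and only if both endpoints are actively
#' expressed there (activity probability > 0); its weight is the product
#' `Ap_i(v) * Ap_i(u)`, the joint activity probability. A node belongs to
#' sub-network i iff it is active there, so active-but-isolated proteins
#' remain eligible as expansion seeds. Proteins absent from the expression
#' data are treated as never active: they stay in the whole network but in
#' no sub-network.
#'
#' @param ppi a [ppi_network()] object.
#' @param activity an [activity_model()] built from the matching expression
#'   data.
#' @return An object of class `subnetwork_set` with `m` (number of
#'   sub-networks), `nodes`, `ap` (nodes x m activity matrix, 0 for missing
#'   genes), and per-sub-network lists `v` (node sets), `edges` (two-column
#'   character matrices) and `w` (joint activity edge weights).
#' @export
build_subnetworks <- function(ppi, activity) {
  stopifnot(inherits(ppi, "ppi_network"), inherits(activity, "activity_model"))
  nodes <- ppi$nodes
  m <- activity$n_samples
  ap <- matrix(0, nrow = length(nodes), ncol = m,
               dimnames = list(nodes, colnames(activity$ap)))
  common <- intersect(nodes, activity$genes)
  ap[common, ] <- activity$ap[common, , drop = FALSE]
  iu <- match(ppi$edges[, 1L], nodes)
  iv <- match(ppi$edges[, 2L], nodes)
  v_list <- vector("list", m)
  e_list <- vector("list", m)
  w_list <- vector("list", m)
  for (i in seq_len(m)) {
    apu <- ap[iu, i]
    apv <- ap[iv, i]
    keep <- apu > 0 & apv > 0
    v_list[[i]] <- nodes[ap[, i] > 0]
    e_list[[i]] <- ppi$edges[keep, , drop = FALSE]
    w_list[[i]] <- unname(apu[keep] * apv[keep])
  }
  new_subnetwork_set(nodes, ap, v_list, e_list, w_list)
}

# Single pseudo-sub-network over the whole graph with activity fixed to 1:
# used by the rm_sub pipeline variant, where seed expansion runs on the
# whole network and the activity factor drops out of the weight matrix.
whole_network_subnets <- function(ppi) {
  nodes <- ppi$nodes
  ap <- matrix(1, nrow = length(nodes), ncol = 1L,
               dimnames = list(nodes, "s1"))
  new_subnetwork_set(nodes, ap, list(nodes), list(ppi$edges),
                     list(rep(1, nrow(ppi$edges))))
}

#' @export
print.subnetwork_set <- function(x, ...) {
  sizes <- vapply(x$edges, nrow, integer(1L))
  cat(sprintf("<subnetwork_set> %d sub-networks over %d proteins; edges per sub-network: %s\n",
              x$m, length(x$nodes),
              paste(range(sizes), collapse = "-")))
  invisible(x)
}
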