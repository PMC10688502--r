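#' GO annotation overlap weight
#'
#' Weight of an interaction from the GO terms of its endpoints:
#' `|GO_v intersect GO_u|^2 / (|GO_v| * |GO_u|)`, which is 1 for identical
#' non-empty sets, 0 for disjoint sets, and defined as 0 when either set is
#' empty (no annotation, no evidence).
#'
#' @param go_v,go_u character vectors of GO term IDs.
#' @return Numeric weight in \[0, 1\].
#' @export
go_weight <- function(go_v, go_u) {
  nv <- length(unique(go_v))
  nu <- length(unique(go_u))
  if (nv == 0L || nu == 0L) return(0)
  length(intersect(go_v, go_u))^2 / (nv * nu)
}

#' Pearson correlation of two expression profiles
#'
#' Sample Pearson correlation of the averaged per-sample expression series
#' of two genes. Defined as 0 when either series has zero variance (a
#' constant profile carries no co-expression information).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("expression vectors must have equal length")
  if (length(x) < 2L) stop("need at least 2 sample points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Co-expression edge weight
#'
#' The Pearson correlation rescaled from \[-1, 1\] to \[0, 1\]:
#' `(PCC + 1) / 2`. Zero-variance profiles (PCC defined as 0) therefore get
#' the no-information midpoint 0.5.
#'
#' @inheritParams pcc
#' @return Numeric weight in \[0, 1\].
#' @export
gene_weight <- function(x, y) (pcc(x, y) + 1) / 2

#' Protein complex membership edge weight
#'
#' `PC_v * PC_u / PC_max^2`, where `PC_v` counts the complexes containing
#' protein v and `PC_max` is the largest such count over the network.
#' Defined as 0 when no complexes are supplied.
#'
#' @param pc_v,pc_u complex-membership counts of the two endpoints.
#' @param pc_max maximum membership count over all network proteins.
#' @return Numeric weight in \[0, 1\].
#' @export
complex_weight <- function(pc_v, pc_u, pc_max) {
  if (pc_max == 0) return(0)
  pc_v * pc_u / pc_max^2
}

#' Select and score subcellular compartments
#'
#' Computes, per compartment, the essential-protein proportion
#' `EPI_c = (#essentials in c) / (#proteins in c)`; selects the compartments
#' whose EPI strictly exceeds the dataset-level proportion
#' `EPthre = ep / p`; and scores each selected compartment by its protein
#' count relative to the largest selected compartment,
#' `SCS_c = NSC_c / NSC_max`.
#'
#' The threshold reference is configurable: by default (`reference =
#' "self"`) `ep` and `p` are the essential and total protein counts of the
#' supplied dataset; `reference = "pair"` pins them to external counts via
#' `ep`/`p` (mirroring the original use of one reference dataset for all
#' species); `reference = "fixed"` pins the selected set directly via
#' `fixed_set`. `select_all = TRUE` keeps every compartment (used by the
#' `all_subcellular` pipeline variant) while still scoring by protein
#' counts.
#'
#' @param subcellular named list: protein ID -> compartment names.
#' @param essentials character vector of essential protein IDs.
#' @param proteins character vector: the protein universe (network nodes).
#' @param reference `"self"`, `"pair"` or `"fixed"`.
#' @param ep,p external essential/total protein counts for
#'   `reference = "pair"`.
#' @param fixed_set character vector of compartment names for
#'   `reference = "fixed"`.
#' @param select_all keep all compartments regardless of EPI.
#' @return An object of class `subcellular_scoring` with `epi`,
#'   `ep_threshold`, `selected` and `scs`.
#' @export
subcellular_scoring <- function(subcellular, essentials, proteins,
                                reference = c("self", "pair", "fixed"),
                                ep = NULL, p = NULL, fixed_set = NULL,
                                select_all = FALSE) {
  reference <- match.arg(reference)
  subcellular <- subcellular[intersect(names(subcellular), proteins)]
  prot <- rep(names(subcellular), lengths(subcellular))
  comp <- unlist(subcellular, use.names = FALSE)
  compartments <- sort_ids(unique(comp))
  n_prot <- vapply(compartments, function(cc) length(unique(prot[comp == cc])), integer(1L))
  ess <- intersect(essentials, proteins)
  n_ess <- vapply(compartments, function(cc) sum(unique(prot[comp == cc]) %in% ess), integer(1L))
  epi <- ifelse(n_prot > 0L, n_ess / n_prot, NA_real_)
  names(epi) <- compartments

  if (reference == "pair") {
    stopifnot(!is.null(ep), !is.null(p), p > 0)
    thr <- ep / p
  } else {
    thr <- if (length(proteins)) length(ess) / length(proteins) else 0
  }

  selected <- if (select_all) compartments
              else if (reference == "fixed") {
                stopifnot(!is.null(fixed_set))
                intersect(compartments, fixed_set)
              } else compartments[!is.na(epi) & epi > thr]
  if (!length(selected))
    warning("subcellular_scoring: no compartment selected (degenerate data)")
  scs <- numeric(0)
  if (length(selected)) {
    nsc <- n_prot[match(selected, compartments)]
    scs <- stats::setNames(nsc / max(nsc), selected)
  }
  structure(list(epi = epi, ep_threshold = thr, selected = selected, scs = scs),
            class = "subcellular_scoring")
}

#' @export
print.subcellular_scoring <- function(x, ...) {
  cat(sprintf("<subcellular_scoring> %d compartment(s), threshold %.4f, selected: %s\n",
              length(x$epi), x$ep_threshold,
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Subcellular localization node weights
#'
#' Each protein is scored by the sum of the compartment scores of the
#' selected compartments it localizes to, normalized by the network-wide
#' maximum: `SW_v = SSC_v / SSC_max`. Proteins outside every selected
#' compartment get 0. If no compartment was selected at all (degenerate
#' data), every protein falls back to weight 1 with a warning, so node
#' scores are not annihilated.
#'
#' @param scoring a [subcellular_scoring()] object.
#' @param subcellular named list: protein ID -> compartment names.
#' @param proteins character vector of network protein IDs.
#' @return Named numeric vector of weights in \[0, 1\] over `proteins`.
#' @export
subcellular_weight <- function(scoring, subcellular, proteins) {
  stopifnot(inherits(scoring, "subcellular_scoring"))
  if (!length(scoring$selected)) {
    warning("subcellular_weight: empty compartment selection; falling back to weight 1")
    return(stats::setNames(rep(1, length(proteins)), proteins))
  }
  ssc <- vapply(proteins, function(v) {
    comps <- subcellular[[v]]
    if (is.null(comps)) return(0)
    sum(scoring$scs[intersect(comps, scoring$selected)])
  }, numeric(1L))
  mx <- max(ssc)
  if (mx == 0) return(stats::setNames(rep(0, length(proteins)), proteins))
  stats::setNames(ssc / mx, proteins)
}

#' Exponent presets for the biological weight ablation
#'
#' The eight exponents switch the biological data sources on (1) or off (0)
#' in the node score (positions 1-4: GO, co-expression, complex,
#' subcellular) and in the per-sub-network weight matrix (positions 5-8:
#' GO, activity, complex, subcellular). A factor with exponent 0 is
#' replaced by the constant 1, removing that data source entirely.
#' `"all_ones"` is the unablated method; `"yeast_best"` drops the complex
#' factor from the weight matrix; `"fly_best"` drops the subcellular factor
#' from the node score.
#'
#' @param preset one of `"all_ones"`, `"yeast_best"`, `"fly_best"`, or a
#'   numeric vector of eight 0/1 exponents (returned validated).
#' @return Integer vector of length 8 with values in \{0, 1\}.
#' @export
alpha_preset <- function(preset = "all_ones") {
  if (is.numeric(preset)) {
    a <- as.integer(preset)
    if (length(a) != 8L || !all(a %in% c(0L, 1L)))
      stop("alpha must be eight exponents, each 0 or 1")
    return(a)
  }
  switch(match.arg(preset, c("all_ones", "yeast_best", "fly_best")),
         all_ones = rep(1L, 8L),
         yeast_best = c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L),
         fly_best = c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L))
}

# Ablated factor: exponent 0 deletes the data source (constant 1), even
# when the base is 0; exponent 1 keeps it.
pow_alpha <- function(x, a) if (a == 0L) rep(1, length(x)) else x

#' Combined whole-network edge weight
#'
#' `GOW^a1 * GW^a2 * PCW^a3`, with the convention that a factor whose
#' exponent is 0 is replaced by the constant 1 (even when the factor itself
#' is 0), so an ablated data source drops out instead of zeroing the
#' product.
#'
#' @param gow,gw,pcw GO, co-expression and complex weights of the edge
#'   (vectorized).
#' @param alpha exponent vector, see [alpha_preset()].
#' @return Numeric edge weight(s) in \[0, 1\].
#' @export
edge_weight <- function(gow, gw, pcw, alpha = alpha_preset()) {
  alpha <- alpha_preset(alpha)
  pow_alpha(gow, alpha[1L]) * pow_alpha(gw, alpha[2L]) * pow_alpha(pcw, alpha[3L])
}

#' Build the full biological weight model
#'
#' Computes, for a network plus expression and annotation data: the
#' per-edge GO overlap (GOW), co-expression (GW) and complex (PCW) weights;
#' the subcellular compartment selection and node weights (SW); the
#' combined whole-network edge weights `W = GOW^a1 * GW^a2 * PCW^a3`; the
#' initial node scores `score_initial_v = (sum of incident W) * SW_v^a4`;
#' and the per-sub-network weight matrix
#' `Wmatrix_i(v,u) = GOW^a5 * (Ap_i(v) Ap_i(u))^a6 * PCW^a7 * (SW_v SW_u)^a8`
#' over the edges of each active sub-network (note the deliberate absence
#' of the co-expression factor there). Genes without expression data get
#' the no-information co-expression weight 0.5.
#'
#' @param ppi a [ppi_network()] object.
#' @param avg an [average_expression()] result (or `NULL`: all GW = 0.5).
#' @param bundle an [annotation_bundle()].
#' @param subnets a [build_subnetworks()] result for the same network.
#' @param alpha exponent vector or preset name, see [alpha_preset()].
#' @param scoring optional precomputed [subcellular_scoring()]; built from
#'   the bundle with the given `reference` settings otherwise.
#' @param reference,ep,p,fixed_set,select_all passed to
#'   [subcellular_scoring()].
#' @return An object of class `weight_model` with per-edge vectors `gow`,
#'   `gw`, `pcw`, `w_edge` (aligned with `ppi$edges`), node vectors `sw`,
#'   `pc`, `score_initial`, the per-sub-network `wmatrix` list (aligned
#'   with `subnets$edges`), `alpha` and the `scoring` object.
#' @export
build_weight_model <- function(ppi, avg, bundle, subnets,
                               alpha = alpha_preset(), scoring = NULL,
                               reference = "self", ep = NULL, p = NULL,
                               fixed_set = NULL, select_all = FALSE) {
  stopifnot(inherits(ppi, "ppi_network"), inherits(bundle, "annotation_bundle"),
            inherits(subnets, "subnetwork_set"))
  alpha <- alpha_preset(alpha)
  nodes <- ppi$nodes
  eu <- ppi$edges[, 1L]
  ev <- ppi$edges[, 2L]
  n_edge <- length(eu)

  gow <- vapply(seq_len(n_edge), function(k)
    go_weight(bundle$go_terms[[eu[k]]], bundle$go_terms[[ev[k]]]), numeric(1L))

  gw <- rep(0.5, n_edge)
  if (!is.null(avg)) {
    stopifnot(inherits(avg, "averaged_expression"))
    ge <- avg$ge
    has <- eu %in% rownames(ge) & ev %in% rownames(ge)
    gw[has] <- vapply(which(has), function(k)
      gene_weight(ge[eu[k], ], ge[ev[k], ]), numeric(1L))
  }

  pc <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (length(bundle$complexes)) {
    members <- unlist(bundle$complexes, use.names = FALSE)
    members <- members[members %in% nodes]
    tab <- table(members)
    pc[names(tab)] <- as.integer(tab)
  }
  pc_max <- if (length(pc)) max(pc) else 0L
  pcw <- if (pc_max == 0L) rep(0, n_edge) else unname(pc[eu] * pc[ev]) / pc_max^2

  if (is.null(scoring))
    scoring <- subcellular_scoring(bundle$subcellular, bundle$essentials, nodes,
                                   reference = reference, ep = ep, p = p,
                                   fixed_set = fixed_set, select_all = select_all)
  sw <- subcellular_weight(scoring, bundle$subcellular, nodes)

  w_edge <- edge_weight(gow, gw, pcw, alpha)

  edge_sum <- stats::setNames(rep(0, length(nodes)), nodes)
  acc_u <- tapply(w_edge, factor(eu, levels = nodes), sum)
  acc_v <- tapply(w_edge, factor(ev, levels = nodes), sum)
  edge_sum <- edge_sum + ifelse(is.na(acc_u), 0, acc_u) + ifelse(is.na(acc_v), 0, acc_v)
  score_initial <- unname(edge_sum) * pow_alpha(unname(sw), alpha[4L])
  names(score_initial) <- nodes

  key_all <- paste(eu, ev, sep = "\r")
  wmatrix <- vector("list", subnets$m)
  for (i in seq_len(subnets$m)) {
    e_i <- subnets$edges[[i]]
    if (!nrow(e_i)) { wmatrix[[i]] <- numeric(0); next }
    idx <- match(paste(e_i[, 1L], e_i[, 2L], sep = "\r"), key_all)
    swp <- unname(sw[e_i[, 1L]] * sw[e_i[, 2L]])
    wmatrix[[i]] <- pow_alpha(gow[idx], alpha[5L]) *
      pow_alpha(subnets$w[[i]], alpha[6L]) *
      pow_alpha(pcw[idx], alpha[7L]) *
      pow_alpha(swp, alpha[8L])
  }

  structure(
    list(edges = ppi$edges, gow = gow, gw = gw, pcw = pcw, pc = pc,
         sw = sw, w_edge = w_edge, score_initial = score_initial,
         wmatrix = wmatrix, alpha = alpha, scoring = scoring),
    class = "weight_model"
  )
}

#' Look up one weight-matrix entry
#'
#' @param model a [build_weight_model()] result.
#' @param subnets the matching [build_subnetworks()] result.
#' @param i sub-network index.
#' @param v,u endpoint protein IDs; the edge must belong to sub-network `i`.
#' @return The `Wmatrix_i(v, u)` value.
#' @export
wmatrix_entry <- function(model, subnets, i, v, u) {
  stopifnot(inherits(model, "weight_model"), inherits(subnets, "subnetwork_set"))
  a <- min(v, u); b <- max(v, u)
  e_i <- subnets$edges[[i]]
  k <- which(e_i[, 1L] == a & e_i[, 2L] == b)
  if (!length(k)) stop(sprintf("edge (%s, %s) is not in sub-network %d", v, u, i))
  model$wmatrix[[i]][k]
}

#' Initial node score of one protein
#'
#' Convenience accessor for `score_initial_v`, the whole-network
#' essentiality score: the sum of the combined weights of the incident
#' edges times the subcellular weight (isolated nodes score 0).
#'
#' @param model a [build_weight_model()] result.
#' @param v protein ID.
#' @return Numeric score (>= 0).
#' @export
node_score_initial <- function(model, v) {
  stopifnot(inherits(model, "weight_model"))
  if (!v %in% names(model$score_initial)) stop("unknown protein: ", v)
  unname(model$score_initial[[v]])
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("<weight_model> %d edges, alpha = (%s); mean score_initial = %.4g\n",
              nrow(x$edges), paste(x$alpha, collapse = ","),
              mean(x$score_initial)))
  invisible(x)
}
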