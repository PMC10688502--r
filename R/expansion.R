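#' Configuration for a seed-expansion run
#'
#' Exactly one of `n` (absolute output length) or `n_fraction` (fraction of
#' the network size, resolved as `floor(n_fraction * |V|)`) determines the
#' length of the ranked output; the default fraction 1/4 matches the
#' yeast-style setting, 1/10 the fly-style one.
#'
#' @param n output length, a positive integer, or `NULL`.
#' @param n_fraction fraction of network nodes to output (used when `n` is
#'   `NULL`; default 1/4).
#' @param rng_seed integer seed driving the random seed draws.
#' @param max_iterations safety cap on expansion iterations (default
#'   `10 * |V| + 100`, resolved at run time).
#' @param correction run the error-correction mechanism (default `TRUE`).
#' @param strict_sync if `TRUE`, initial seeds are propagated into every
#'   sub-network set they belong to; by default each seed starts only in
#'   its own sub-network's set (later additions always propagate).
#' @param seeds optional explicit seed proteins (one per sub-network, in
#'   sub-network order), bypassing the random draw.
#' @return An object of class `expansion_config`.
#' @export
expansion_config <- function(n = NULL, n_fraction = NULL, rng_seed = 1L,
                             max_iterations = NULL, correction = TRUE,
                             strict_sync = FALSE, seeds = NULL) {
  if (!is.null(n) && !is.null(n_fraction))
    stop("supply exactly one of `n` and `n_fraction`")
  if (is.null(n) && is.null(n_fraction)) n_fraction <- 1 / 4
  if (!is.null(n)) stopifnot(n >= 1)
  structure(list(n = n, n_fraction = n_fraction, rng_seed = as.integer(rng_seed),
                 max_iterations = max_iterations, correction = isTRUE(correction),
                 strict_sync = isTRUE(strict_sync), seeds = seeds),
            class = "expansion_config")
}

#' Neighbor frontier of a node set
#'
#' The union of the neighbor sets of `node_set`, minus `exclude`. With the
#' whole network and `exclude` equal to the predicted set K this is the
#' whole-network frontier used by error correction; with a sub-network's
#' adjacency and the same exclusion it is that sub-network's expansion
#' frontier.
#'
#' @param graph a [ppi_network()] object or a named adjacency list.
#' @param node_set character vector of node IDs (must be graph nodes).
#' @param exclude character vector of node IDs removed from the result
#'   (default `node_set` itself).
#' @return Sorted character vector of frontier node IDs.
#' @export
neighbor_frontier <- function(graph, node_set, exclude = node_set) {
  adj <- if (inherits(graph, "ppi_network")) graph$adjacency else graph
  stopifnot(all(node_set %in% names(adj)))
  nb <- unique(unlist(adj[node_set], use.names = FALSE))
  sort_ids(setdiff(nb, exclude))
}

# --- internal engine ---------------------------------------------------------
# The expansion state is an environment holding integer-indexed structures:
# node IDs are mapped onto their rank in the radix-sorted node vector, so
# "lexicographically smallest ID" tie-breaking is just the smallest index.
# Frontiers are maintained incrementally via neighbor-in-K counts.

build_sub_adjacency <- function(edges, w, nV, idx_of) {
  adj <- vector("list", nV)
  wts <- vector("list", nV)
  for (k in seq_len(nV)) { adj[[k]] <- integer(0); wts[[k]] <- numeric(0) }
  if (nrow(edges)) {
    iu <- idx_of[edges[, 1L]]
    iv <- idx_of[edges[, 2L]]
    ends1 <- c(iu, iv); ends2 <- c(iv, iu); ww <- c(w, w)
    o <- order(ends1, ends2)
    ends1 <- ends1[o]; ends2 <- ends2[o]; ww <- ww[o]
    sp_n <- split(ends2, ends1)
    sp_w <- split(ww, ends1)
    at <- as.integer(names(sp_n))
    adj[at] <- sp_n
    wts[at] <- sp_w
  }
  list(adj = adj, w = wts)
}

#' Initialize the expansion state with random seeds
#'
#' Draws one uniformly random protein from each non-empty sub-network
#' (ascending sub-network order, single seeded RNG stream), rejecting
#' proteins already chosen for another sub-network so that the initial
#' per-sub-network sets are pairwise disjoint. A sub-network whose nodes
#' are all taken contributes no seed (with a warning). The predicted set K
#' is the union of the seeds, ordered by sub-network index.
#'
#' @param ppi a [ppi_network()] object.
#' @param subnets a [build_subnetworks()] result.
#' @param weights a [build_weight_model()] result for the same inputs.
#' @param config an [expansion_config()].
#' @return An environment of class `expansion_state`; inspect it with
#'   [expansion_k()] or advance it with [expansion_step()] and
#'   [error_correction_step()].
#' @export
init_seeds <- function(ppi, subnets, weights, config = expansion_config()) {
  stopifnot(inherits(ppi, "ppi_network"), inherits(subnets, "subnetwork_set"),
            inherits(weights, "weight_model"), inherits(config, "expansion_config"))
  ids <- ppi$nodes
  nV <- length(ids)
  idx_of <- stats::setNames(seq_len(nV), ids)
  m <- subnets$m

  st <- new.env(parent = emptyenv())
  st$ids <- ids
  st$nV <- nV
  st$idx_of <- idx_of
  st$m <- m
  st$adj <- lapply(ppi$adjacency[ids], function(x) unname(idx_of[x]))
  st$score_initial <- unname(weights$score_initial[ids])
  sub <- lapply(seq_len(m), function(i)
    build_sub_adjacency(subnets$edges[[i]], weights$wmatrix[[i]], nV, idx_of))
  st$sub_adj <- lapply(sub, `[[`, "adj")
  st$sub_w <- lapply(sub, `[[`, "w")
  st$v_in_sub <- matrix(FALSE, nrow = m, ncol = nV)
  for (i in seq_len(m)) st$v_in_sub[i, idx_of[subnets$v[[i]]]] <- TRUE
  st$in_k <- logical(nV)
  st$in_ki <- matrix(FALSE, nrow = m, ncol = nV)
  st$cnt_sub <- matrix(0L, nrow = m, ncol = nV)
  st$cnt_whole <- integer(nV)
  st$removed <- logical(nV)
  st$k_order <- integer(0)
  st$provenance <- character(0)
  st$step_of <- integer(0)
  st$step_counter <- 0L
  st$strict_sync <- config$strict_sync
  class(st) <- "expansion_state"

  non_empty <- which(vapply(seq_len(m), function(i) any(st$v_in_sub[i, ]), logical(1L)))
  if (!length(non_empty)) stop("cannot start: every sub-network is empty")

  seeds <- integer(0)
  seed_sub <- integer(0)
  if (!is.null(config$seeds)) {
    for (j in seq_along(config$seeds)) {
      i <- non_empty[j]
      v <- idx_of[[config$seeds[[j]]]]
      stopifnot(st$v_in_sub[i, v], !(v %in% seeds))
      seeds <- c(seeds, v); seed_sub <- c(seed_sub, i)
    }
  } else {
    with_rng_seed(config$rng_seed, {
      for (i in non_empty) {
        cand <- which(st$v_in_sub[i, ])
        cand <- cand[!(cand %in% seeds)]
        if (!length(cand)) {
          warning(sprintf("sub-network %d skipped: all its proteins already seed others", i))
          next
        }
        seeds <- c(seeds, cand[sample.int(length(cand), 1L)])
        seed_sub <- c(seed_sub, i)
      }
    })
  }

  for (j in seq_along(seeds)) {
    v <- seeds[j]
    st$k_order <- c(st$k_order, v)
    st$provenance <- c(st$provenance, "seed")
    st$step_of <- c(st$step_of, 0L)
    st$in_k[v] <- TRUE
    nb <- st$adj[[v]]
    st$cnt_whole[nb] <- st$cnt_whole[nb] + 1L
    subs <- if (config$strict_sync) which(st$v_in_sub[, v]) else seed_sub[j]
    for (i in subs) {
      st$in_ki[i, v] <- TRUE
      snb <- st$sub_adj[[i]][[v]]
      if (length(snb)) st$cnt_sub[i, snb] <- st$cnt_sub[i, snb] + 1L
    }
  }
  st$seed_ids <- ids[seeds]
  st
}

#' Current predicted set of an expansion state
#'
#' @param state an [init_seeds()] state.
#' @return Character vector of protein IDs in addition (rank) order.
#' @export
expansion_k <- function(state) state$ids[state$k_order]

#' @export
print.expansion_state <- function(x, ...) {
  cat(sprintf("<expansion_state> |K| = %d (%d removed), %d sub-networks over %d proteins\n",
              length(x$k_order), sum(x$removed), x$m, x$nV))
  invisible(x)
}

# Append node v (integer index) to K and propagate into every sub-network
# set whose node universe contains it.
add_node <- function(state, v, mechanism) {
  state$step_counter <- state$step_counter + 1L
  state$k_order <- c(state$k_order, v)
  state$provenance <- c(state$provenance, mechanism)
  state$step_of <- c(state$step_of, state$step_counter)
  state$in_k[v] <- TRUE
  nb <- state$adj[[v]]
  state$cnt_whole[nb] <- state$cnt_whole[nb] + 1L
  for (i in which(state$v_in_sub[, v])) {
    state$in_ki[i, v] <- TRUE
    snb <- state$sub_adj[[i]][[v]]
    if (length(snb)) state$cnt_sub[i, snb] <- state$cnt_sub[i, snb] + 1L
  }
  invisible(state)
}

# Remove node v from K and from every sub-network set holding it, and mark
# it in the permanent removed ledger (a node can be removed only once).
drop_node <- function(state, v) {
  pos <- match(v, state$k_order)
  state$k_order <- state$k_order[-pos]
  state$provenance <- state$provenance[-pos]
  state$step_of <- state$step_of[-pos]
  state$in_k[v] <- FALSE
  nb <- state$adj[[v]]
  state$cnt_whole[nb] <- state$cnt_whole[nb] - 1L
  for (i in which(state$in_ki[, v])) {
    state$in_ki[i, v] <- FALSE
    snb <- state$sub_adj[[i]][[v]]
    if (length(snb)) state$cnt_sub[i, snb] <- state$cnt_sub[i, snb] - 1L
  }
  state$removed[v] <- TRUE
  invisible(state)
}

#' Expansion score of a frontier candidate
#'
#' Sum of the sub-network weight-matrix entries between the candidate and
#' its sub-network-i neighbors that are already in the predicted set K;
#' pairs without an edge in sub-network i contribute nothing.
#'
#' @param state an [init_seeds()] state.
#' @param candidate protein ID.
#' @param i sub-network index.
#' @return Numeric score (>= 0).
#' @export
score_w <- function(state, candidate, i) {
  v <- state$idx_of[[candidate]]
  nb <- state$sub_adj[[i]][[v]]
  if (!length(nb)) return(0)
  sum(state$sub_w[[i]][[v]][state$in_k[nb]])
}

# Integer-index version used in the hot loop.
score_w_idx <- function(state, v, i) {
  nb <- state$sub_adj[[i]][[v]]
  if (!length(nb)) return(0)
  sum(state$sub_w[[i]][[v]][state$in_k[nb]])
}

#' Select the next expansion node across all sub-networks
#'
#' Two-step maximization: within each sub-network, the frontier candidate
#' with the largest positive [score_w()] (ties broken by lexicographically
#' smallest protein ID); then the global maximum over sub-networks (ties
#' broken by smallest ID, then smallest sub-network index). Returns `NULL`
#' when every sub-network frontier is empty or no frontier candidate has a
#' positive connection score -- a zero-score node is not considered
#' connected to the predicted set and can enter it only through error
#' correction.
#'
#' @param state an [init_seeds()] state.
#' @return `NULL`, or a list with `node` (protein ID), `index`
#'   (sub-network) and `score`.
#' @export
select_expansion_node <- function(state) {
  best_score <- -Inf
  best_node <- NA_integer_
  best_sub <- NA_integer_
  for (i in seq_len(state$m)) {
    f <- which(state$cnt_sub[i, ] > 0L & !state$in_k)
    if (!length(f)) next
    sc <- vapply(f, score_w_idx, numeric(1L), state = state, i = i)
    mx <- max(sc)
    if (mx <= 0) next
    node <- min(f[sc == mx])
    if (mx > best_score || (mx == best_score && node < best_node)) {
      best_score <- mx; best_node <- node; best_sub <- i
    }
  }
  if (is.na(best_sub)) return(NULL)
  list(node = state$ids[best_node], index = best_sub, score = best_score)
}

#' Perform one sub-network expansion step
#'
#' Adds the node chosen by [select_expansion_node()] to K and to every
#' sub-network set whose node universe contains it.
#'
#' @param state an [init_seeds()] state (modified in place).
#' @return `TRUE` if a node was added, `FALSE` if no candidate existed.
#' @export
expansion_step <- function(state) {
  sel <- select_expansion_node(state)
  if (is.null(sel)) return(FALSE)
  v <- state$idx_of[[sel$node]]
  if (state$in_k[v]) return(FALSE)  # cannot occur: frontier excludes K
  add_node(state, v, "expansion")
  TRUE
}

#' Perform one error-correction step
#'
#' Whole-network correction based on the initial node scores: find the
#' member of K with the smallest `score_initial` (`min_initial_node`) and
#' the whole-network frontier protein with the largest `score_initial`
#' (`max_initial_node`), ties broken by lexicographically smallest ID. If
#' the frontier maximum strictly exceeds the K minimum, the frontier node
#' is appended to K; the minimum node is then removed -- but only if it has
#' never been removed before (each protein can be removed at most once; a
#' re-added protein is immune).
#'
#' @param state an [init_seeds()] state (modified in place).
#' @return `TRUE` if the state changed, `FALSE` otherwise.
#' @export
error_correction_step <- function(state) {
  if (!length(state$k_order)) return(FALSE)
  k <- state$k_order
  sc_k <- state$score_initial[k]
  min_node <- k[order(sc_k, k)[1L]]
  frontier <- which(state$cnt_whole > 0L & !state$in_k)
  if (!length(frontier)) return(FALSE)
  sc_f <- state$score_initial[frontier]
  max_node <- frontier[order(-sc_f, frontier)[1L]]
  if (state$score_initial[max_node] > state$score_initial[min_node]) {
    add_node(state, max_node, "correction")
    if (!state$removed[min_node]) drop_node(state, min_node)
    TRUE
  } else FALSE
}

#' Run the full seed expansion
#'
#' Alternates one sub-network expansion step and one error-correction step
#' until the predicted set K reaches the target length n (the set length is
#' checked after every individual addition, so the output length is exactly
#' n whenever the graph admits it). If neither mechanism can change the
#' state before K reaches n, the run terminates early with a warning and a
#' shorter ranking.
#'
#' @param ppi a [ppi_network()] object.
#' @param subnets a [build_subnetworks()] result.
#' @param weights a [build_weight_model()] result.
#' @param config an [expansion_config()].
#' @return An object of class `ranked_prediction`: a data frame with
#'   columns `rank`, `protein`, `provenance` (`seed`, `expansion` or
#'   `correction`) and `step`, with attributes `seeds`, `removed`,
#'   `truncated` and `n`.
#' @export
run_expansion <- function(ppi, subnets, weights, config = expansion_config()) {
  n <- resolve_n(config, length(ppi$nodes))
  state <- init_seeds(ppi, subnets, weights, config)
  max_iter <- if (is.null(config$max_iterations)) 10L * state$nV + 100L
              else config$max_iterations
  truncated <- FALSE
  it <- 0L
  while (length(state$k_order) < n) {
    it <- it + 1L
    if (it > max_iter)
      stop("expansion aborted: iteration cap exceeded")
    progressed <- expansion_step(state)
    if (length(state$k_order) >= n) break
    if (config$correction)
      progressed <- error_correction_step(state) || progressed
    if (!progressed) {
      warning(sprintf("expansion stalled at |K| = %d < n = %d; ranking truncated",
                      length(state$k_order), n))
      truncated <- TRUE
      break
    }
  }
  keep <- seq_len(min(n, length(state$k_order)))
  ranked_prediction(
    protein = state$ids[state$k_order][keep],
    provenance = state$provenance[keep],
    step = state$step_of[keep],
    seeds = state$seed_ids,
    removed = state$ids[state$removed],
    truncated = truncated,
    n = n
  )
}

resolve_n <- function(config, nV) {
  n <- if (!is.null(config$n)) as.integer(config$n)
       else max(1L, as.integer(floor(config$n_fraction * nV)))
  if (n > nV) stop(sprintf("requested output length %d exceeds network size %d", n, nV))
  n
}

# Ranked prediction container shared by the expansion and the
# score-only pipeline variants.
ranked_prediction <- function(protein, provenance, step, seeds = character(),
                              removed = character(), truncated = FALSE, n = length(protein)) {
  stopifnot(!anyDuplicated(protein))
  structure(
    data.frame(rank = seq_along(protein), protein = protein,
               provenance = provenance, step = step,
               stringsAsFactors = FALSE),
    seeds = seeds, removed = removed, truncated = truncated, n = n,
    class = c("ranked_prediction", "data.frame")
  )
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(sprintf("<ranked_prediction> %d proteins (%d seeds, %d removed during correction)%s\n",
              nrow(x), length(attr(x, "seeds")), length(attr(x, "removed")),
              if (isTRUE(attr(x, "truncated"))) " [truncated]" else ""))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Write a ranked prediction as TSV
#'
#' @param prediction a `ranked_prediction`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(prediction, path) {
  utils::write.table(as.data.frame(prediction), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
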