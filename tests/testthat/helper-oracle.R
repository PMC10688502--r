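# Independent brute-force reference for the seed-expansion procedure.
# Character-set based, no incremental caches: every frontier and every
# candidate score is recomputed from the raw edge tables at every
# iteration. Shares only the weight-model inputs with the implementation.

oracle_neighbors <- function(edges, v) {
  unique(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L]))
}

oracle_wmatrix <- function(subnets, weights, i, a, b) {
  e <- subnets$edges[[i]]
  k <- which((e[, 1L] == a & e[, 2L] == b) | (e[, 1L] == b & e[, 2L] == a))
  if (!length(k)) 0 else weights$wmatrix[[i]][k]
}

oracle_expansion <- function(ppi, subnets, weights, seeds, n,
                             correction = TRUE) {
  nodes <- sort(unique(c(ppi$edges[, 1L], ppi$edges[, 2L])), method = "radix")
  lexrank <- stats::setNames(seq_along(nodes), nodes)
  m <- subnets$m
  K <- character(0)
  Ki <- replicate(m, character(0), simplify = FALSE)
  removed <- character(0)
  prov <- character(0)

  non_empty <- which(vapply(subnets$v, length, integer(1L)) > 0L)
  for (j in seq_along(seeds)) {
    K <- c(K, seeds[j])
    Ki[[non_empty[j]]] <- c(Ki[[non_empty[j]]], seeds[j])
    prov <- c(prov, "seed")
  }

  sync_add <- function(v) {
    for (i in seq_len(m))
      if (v %in% subnets$v[[i]]) Ki[[i]] <<- c(Ki[[i]], v)
  }

  repeat {
    if (length(K) >= n) break
    progressed <- FALSE

    # expansion: from-scratch frontier + score recomputation per sub-network
    best_node <- NULL; best_score <- -Inf
    for (i in seq_len(m)) {
      e <- subnets$edges[[i]]
      if (!nrow(e) || !length(Ki[[i]])) next
      fr <- setdiff(unique(unlist(lapply(Ki[[i]], oracle_neighbors, edges = e))), K)
      if (!length(fr)) next
      fr <- fr[order(lexrank[fr])]
      sc <- vapply(fr, function(cand) {
        use <- intersect(oracle_neighbors(e, cand), K)
        if (!length(use)) 0
        else sum(vapply(use, function(u2) oracle_wmatrix(subnets, weights, i, cand, u2),
                        numeric(1L)))
      }, numeric(1L))
      if (max(sc) <= 0) next
      node <- fr[sc == max(sc)][1L]
      if (max(sc) > best_score ||
          (max(sc) == best_score && lexrank[[node]] < lexrank[[best_node]])) {
        best_score <- max(sc); best_node <- node
      }
    }
    if (!is.null(best_node)) {
      K <- c(K, best_node); prov <- c(prov, "expansion"); sync_add(best_node)
      progressed <- TRUE
      if (length(K) >= n) break
    }

    if (correction) {
      sc_k <- unname(weights$score_initial[K])
      min_node <- K[order(sc_k, lexrank[K])[1L]]
      fr <- setdiff(unique(unlist(lapply(K, oracle_neighbors, edges = ppi$edges))), K)
      if (length(fr)) {
        sc_f <- unname(weights$score_initial[fr])
        max_node <- fr[order(-sc_f, lexrank[fr])[1L]]
        if (weights$score_initial[[max_node]] > weights$score_initial[[min_node]]) {
          K <- c(K, max_node); prov <- c(prov, "correction"); sync_add(max_node)
          if (!(min_node %in% removed)) {
            pos <- match(min_node, K)
            K <- K[-pos]; prov <- prov[-pos]
            for (i in seq_len(m)) Ki[[i]] <- setdiff(Ki[[i]], min_node)
            removed <- c(removed, min_node)
          }
          progressed <- TRUE
        }
      }
    }
    if (!progressed) break
  }
  keep <- seq_len(min(n, length(K)))
  list(ranking = K[keep], provenance = prov[keep], removed = sort(removed, method = "radix"))
}

# Deterministic distinct seed choice (one per non-empty sub-network) used
# to feed both implementations the same explicit seeds.
pick_seeds <- function(subnets, seed) {
  non_empty <- which(vapply(subnets$v, length, integer(1L)) > 0L)
  chosen <- character(0)
  set.seed(seed)
  for (i in non_empty) {
    cand <- setdiff(sort(subnets$v[[i]], method = "radix"), chosen)
    if (!length(cand)) next
    chosen <- c(chosen, cand[sample.int(length(cand), 1L)])
  }
  chosen
}
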