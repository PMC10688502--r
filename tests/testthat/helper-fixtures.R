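# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through the round-trip tests' own temporary files.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Tiny hand-checkable network: a path a-b-c-d.
path_network <- function() {
  ppi_network(data.frame(u = c("a", "b", "c"), v = c("b", "c", "d")))
}

# Small synthetic configuration for quick end-to-end runs.
small_config <- function(seed, m_points = 6L) {
  synthetic_config(n_proteins = 40L, mean_degree = 4,
                   essential_fraction = 0.2,
                   sample_plan = plan_cycles(m_points, 2L),
                   n_go_terms = 20L, n_complexes = 12L,
                   rng_seed = seed)
}

# A fully controlled three-protein dataset where every weight component is
# known by construction: edges (u,v) and (v,x); GO overlap 2 of 4x2 terms
# on (u,v); complex counts u=3, v=2, x=4 (via a dummy non-network member);
# compartment B is selected (EPI 1 > 1/3) and holds only v.
controlled_weight_fixture <- function() {
  ppi <- ppi_network(data.frame(u = c("u", "v"), v = c("v", "x")))
  vals <- rbind(u = c(1, 2, 3, 4), v = c(2, 3, 4, 6), x = c(5, 5, 6, 5))
  expr <- raw_expression(vals, plan_replicates(4L, 1L))
  bundle <- suppressMessages(annotation_bundle(
    go_terms = list(u = c("g1", "g2"), v = c("g1", "g2", "g3", "g4"),
                    x = c("g9")),
    complexes = c(replicate(3, c("u", "zz"), simplify = FALSE),
                  replicate(2, c("v", "zz"), simplify = FALSE),
                  replicate(4, c("x", "zz"), simplify = FALSE)),
    subcellular = list(u = "A", v = c("A", "B"), x = "A"),
    essentials = "v"
  ))
  list(ppi = ppi, expr = expr, bundle = bundle)
}

# Hand-built expansion instance: subnetwork/weight objects assembled
# directly so every weight-matrix entry is a chosen constant.
manual_expansion_fixture <- function(nodes, whole_edges, sub_v, sub_edges,
                                     sub_w, score_initial) {
  ppi <- ppi_network(as.data.frame(whole_edges, stringsAsFactors = FALSE))
  stopifnot(setequal(ppi$nodes, nodes))
  ap <- matrix(0, nrow = length(ppi$nodes), ncol = length(sub_v),
               dimnames = list(ppi$nodes, NULL))
  for (i in seq_along(sub_v)) ap[sub_v[[i]], i] <- 0.99
  subnets <- sesn:::new_subnetwork_set(ppi$nodes, ap, sub_v, sub_edges, sub_w)
  weights <- structure(
    list(edges = ppi$edges, score_initial = score_initial[ppi$nodes],
         wmatrix = sub_w, alpha = rep(1L, 8L)),
    class = "weight_model")
  list(ppi = ppi, subnets = subnets, weights = weights)
}

# Canonicalize an edge matrix (smaller ID first, sorted rows).
canon_edges <- function(e) {
  a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
  o <- order(a, b, method = "radix")
  cbind(a[o], b[o], deparse.level = 0)
}
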