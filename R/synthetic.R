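#' Default compartment enrichment factors
#'
#' The eleven compartment names commonly used for yeast and fly
#' localization data, each with the factor by which essential proteins are
#' enriched there in the synthetic generator. Factors above 1 mark
#' compartments where essentials concentrate (nucleus, cytosol,
#' cytoskeleton, ER, Golgi); factors below 1 mark depleted ones.
#'
#' @return Named numeric vector of enrichment factors.
#' @export
default_compartments <- function() {
  c("Nucleus" = 3.0, "Cytosol" = 2.5, "Cytoskeleton" = 2.0,
    "Endoplasmic reticulum" = 1.6, "Golgi apparatus" = 1.6,
    "Mitochondrion" = 0.8, "Vacuole/Lysosome" = 0.8,
    "Plasma membrane" = 0.7, "Endosome" = 0.7,
    "Peroxisome" = 0.4, "Extracellular region" = 0.3)
}

#' Configuration of the synthetic dataset generator
#'
#' The defaults describe the benchmark conditions used throughout the
#' package's validation: a 200-protein network with 15% planted essential
#' proteins, a yeast-style three-cycle expression layout, and biological
#' annotations in which essentials carry more complex memberships, more
#' overlapping GO terms and stronger localization to enriched compartments
#' than the background.
#'
#' @param n_proteins number of proteins.
#' @param mean_degree target mean degree of the interaction network.
#' @param essential_fraction fraction of proteins planted as essential.
#' @param sample_plan a [plan_cycles()] or [plan_replicates()] object.
#' @param n_go_terms size of the GO term vocabulary.
#' @param n_complexes number of protein complexes.
#' @param compartments named numeric vector of per-compartment
#'   essential-enrichment factors (see [default_compartments()]).
#' @param co_expression_strength weight in \[0, 1\] of the shared periodic
#'   latent signal in essential genes' expression.
#' @param noise_sd standard deviation of the Gaussian measurement noise per
#'   raw expression column.
#' @param rng_seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L, mean_degree = 8,
                             essential_fraction = 0.15,
                             sample_plan = plan_cycles(12L, 3L),
                             n_go_terms = 60L, n_complexes = 40L,
                             compartments = default_compartments(),
                             co_expression_strength = 0.8,
                             noise_sd = 0.25, rng_seed = 1L) {
  stopifnot(n_proteins >= 10L, mean_degree >= 1,
            essential_fraction > 0, essential_fraction < 1,
            inherits(sample_plan, "sample_plan"),
            n_go_terms >= 2L, n_complexes >= 1L,
            length(compartments) >= 1L, !is.null(names(compartments)),
            co_expression_strength >= 0, co_expression_strength <= 1,
            noise_sd >= 0)
  if (mean_degree >= n_proteins)
    stop("infeasible config: mean_degree must be smaller than n_proteins")
  structure(
    list(n_proteins = as.integer(n_proteins), mean_degree = mean_degree,
         essential_fraction = essential_fraction, sample_plan = sample_plan,
         n_go_terms = as.integer(n_go_terms), n_complexes = as.integer(n_complexes),
         compartments = compartments,
         co_expression_strength = co_expression_strength,
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic benchmark dataset
#'
#' Produces a self-contained dataset with the structure the prediction
#' method assumes: (a) a preferential-attachment interaction network in
#' which the planted essential proteins receive extra mutual edges and so
#' form a denser sub-community; (b) an expression matrix in which essential
#' genes share a periodic latent signal (weighted by
#' `co_expression_strength`) while every gene also carries its own
#' random-phase oscillation plus Gaussian noise, laid out according to the
#' sample plan; (c) annotations in which essentials draw GO terms from a
#' shared core vocabulary, receive more complex memberships and localize
#' preferentially to high-enrichment compartments. The gold standard is the
#' planted essential set. Fully deterministic given `rng_seed`.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `sesn_dataset`: a list with `ppi`
#'   ([ppi_network()]), `expression` ([raw_expression()]), `bundle`
#'   ([annotation_bundle()]) and the `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng_seed(config$rng_seed, {
    n <- config$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    n_ess <- round(config$essential_fraction * n)
    essentials <- sort_ids(sample(ids, n_ess))
    is_ess <- ids %in% essentials

    # -- network: preferential attachment + planted essential community
    g <- igraph::sample_pa(n, m = max(1L, round(config$mean_degree / 2)),
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    perm <- sample(n)  # detach attachment order from ID order
    eu <- ids[perm[el[, 1L]]]
    ev <- ids[perm[el[, 2L]]]
    p_extra <- min(1, 3 * config$mean_degree / n)
    ess_pairs <- utils::combn(essentials, 2L)
    extra <- stats::runif(ncol(ess_pairs)) < p_extra
    edges <- data.frame(u = c(eu, ess_pairs[1L, extra]),
                        v = c(ev, ess_pairs[2L, extra]))
    ppi <- suppressMessages(ppi_network(edges))

    # -- expression: shared periodic signal for essentials + private oscillation
    plan <- config$sample_plan
    n_cols <- plan_length(plan)
    m <- plan_samples(plan)
    tpos <- if (plan$mode == "cycles") ((seq_len(n_cols) - 1L) %% plan$points) + 1L
            else rep(seq_len(m), each = plan$reps)
    s_common <- sin(2 * pi * (tpos - 1L) / m)
    w <- config$co_expression_strength
    baseline <- stats::runif(n, 3, 6)
    amp <- stats::runif(n, 0.8, 1.2)
    phase <- stats::runif(n, 0, 2 * pi)
    vals <- matrix(0, nrow = n, ncol = n_cols,
                   dimnames = list(ids, paste0("c", seq_len(n_cols))))
    for (k in seq_len(n)) {
      own <- sin(2 * pi * (tpos - 1L) / m + phase[k])
      sig <- if (is_ess[k]) w * s_common + (1 - w) * own else own
      vals[k, ] <- pmax(0, baseline[k] + amp[k] * sig +
                          stats::rnorm(n_cols, 0, config$noise_sd))
    }
    expression <- raw_expression(vals, plan)

    # -- GO: essentials draw from a shared core vocabulary
    terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
    core <- terms[seq_len(max(5L, round(0.25 * config$n_go_terms)))]
    go <- stats::setNames(vector("list", n), ids)
    for (k in seq_len(n)) {
      go[[k]] <- if (is_ess[k]) sample(core, min(length(core), sample(4:8, 1L)))
                 else sample(terms, sample(1:5, 1L))
    }

    # -- complexes: members drawn with essentials up-weighted 4x
    wts <- ifelse(is_ess, 4, 1)
    complexes <- lapply(seq_len(config$n_complexes), function(j) {
      size <- 2L + stats::rpois(1L, 2)
      sample(ids, min(size, n), prob = wts)
    })

    # -- subcellular: 1-3 compartments per protein, enrichment for essentials
    comp_names <- names(config$compartments)
    subcell <- stats::setNames(vector("list", n), ids)
    for (k in seq_len(n)) {
      pw <- if (is_ess[k]) config$compartments else rep(1, length(comp_names))
      nk <- sample(1:3, 1L)
      subcell[[k]] <- sample(comp_names, min(nk, length(comp_names)), prob = pw)
    }

    bundle <- suppressMessages(annotation_bundle(
      go_terms = go, complexes = complexes, subcellular = subcell,
      essentials = essentials))

    structure(list(ppi = ppi, expression = expression, bundle = bundle,
                   config = config),
              class = "sesn_dataset")
  })
}

#' @export
print.sesn_dataset <- function(x, ...) {
  cat(sprintf("<sesn_dataset> %d proteins, %d interactions, %d essential, %d raw expression columns\n",
              length(x$ppi$nodes), nrow(x$ppi$edges),
              length(x$bundle$essentials), ncol(x$expression$values)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits exactly the formats the readers consume, so
#' `generate -> write -> read` round-trips: `ppi.tsv` (edge list),
#' `expression.tsv` (gene ID + header row), `go.tsv` and `subcellular.tsv`
#' (two-column pairs), `complexes.txt` (one complex per line) and
#' `essentials.txt` (one ID per line).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sesn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             expression = file.path(dir, "expression.tsv"),
             go = file.path(dir, "go.tsv"),
             complexes = file.path(dir, "complexes.txt"),
             subcellular = file.path(dir, "subcellular.tsv"),
             essentials = file.path(dir, "essentials.txt"))
  write_ppi(dataset$ppi, paths[["ppi"]])
  expr <- data.frame(gene = rownames(dataset$expression$values),
                     dataset$expression$values, check.names = FALSE)
  utils::write.table(expr, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_pairs <- function(sl, path) {
    df <- data.frame(id = rep(names(sl), lengths(sl)),
                     label = unlist(sl, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_pairs(dataset$bundle$go_terms, paths[["go"]])
  writeLines(vapply(dataset$bundle$complexes, paste, character(1L), collapse = "\t"),
             paths[["complexes"]])
  write_pairs(dataset$bundle$subcellular, paths[["subcellular"]])
  writeLines(dataset$bundle$essentials, paths[["essentials"]])
  invisible(paths)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir directory holding the files.
#' @param plan the [plan_cycles()]/[plan_replicates()] sample plan of the
#'   expression matrix.
#' @return A list with `ppi`, `expression` and `bundle` as in
#'   [generate_dataset()].
#' @export
read_dataset <- function(dir, plan) {
  list(ppi = read_ppi(file.path(dir, "ppi.tsv")),
       expression = read_expression(file.path(dir, "expression.tsv"), plan),
       bundle = read_annotations(go_path = file.path(dir, "go.tsv"),
                                 complex_path = file.path(dir, "complexes.txt"),
                                 subcell_path = file.path(dir, "subcellular.tsv"),
                                 essential_path = file.path(dir, "essentials.txt")))
}
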