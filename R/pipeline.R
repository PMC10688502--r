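#' Run the end-to-end prediction pipeline
#'
#' Orchestrates read -> activity model -> sub-networks -> biological
#' weights -> seed expansion -> evaluation, for the full method or one of
#' its component-removal variants:
#'
#' * `"sesn"` -- the full method;
#' * `"rm_sub"` -- no sub-network decomposition: expansion runs on the whole
#'   network as a single sub-network with the activity factor fixed to 1;
#' * `"rm_correction"` -- the error-correction mechanism is skipped;
#' * `"wmatrix_only"` -- no expansion: proteins are ranked by the sum of
#'   their incident weight-matrix entries over all sub-networks;
#' * `"score_initial_only"` -- no expansion: proteins are ranked by their
#'   initial node score;
#' * `"all_subcellular"` -- the compartment selection is disabled (all
#'   compartments kept, still scored by protein counts).
#'
#' @param ppi a [ppi_network()] object.
#' @param expression a [raw_expression()] object covering (a subset of) the
#'   network's proteins.
#' @param bundle an [annotation_bundle()].
#' @param variant pipeline variant, see above.
#' @param alpha exponent vector or preset name ([alpha_preset()]).
#' @param n,n_fraction output length (see [expansion_config()]).
#' @param rng_seed integer seed for the random seed draws.
#' @param subcell_reference,ep,p,fixed_set subcellular threshold reference,
#'   passed to [subcellular_scoring()].
#' @param min_expression optional activity floor, see [activity_model()].
#' @param strict_sync see [expansion_config()].
#' @return An object of class `sesn_run`: a list with `prediction`
#'   (`ranked_prediction`), `confusion`, `measures`, `jackknife`, plus the
#'   intermediate `subnets` and `weights` objects and the resolved `n`.
#' @export
run_pipeline <- function(ppi, expression, bundle,
                         variant = c("sesn", "rm_sub", "rm_correction",
                                     "wmatrix_only", "score_initial_only",
                                     "all_subcellular"),
                         alpha = "all_ones", n = NULL, n_fraction = NULL,
                         rng_seed = 1L, subcell_reference = "self",
                         ep = NULL, p = NULL, fixed_set = NULL,
                         min_expression = NULL, strict_sync = FALSE) {
  variant <- match.arg(variant)
  avg <- average_expression(expression)
  activity <- activity_model(avg, min_expression = min_expression)
  subnets <- if (variant == "rm_sub") whole_network_subnets(ppi)
             else build_subnetworks(ppi, activity)
  weights <- build_weight_model(
    ppi, avg, bundle, subnets, alpha = alpha,
    reference = subcell_reference, ep = ep, p = p, fixed_set = fixed_set,
    select_all = (variant == "all_subcellular"))

  config <- expansion_config(n = n, n_fraction = n_fraction,
                             rng_seed = rng_seed,
                             correction = (variant != "rm_correction"),
                             strict_sync = strict_sync)
  n_out <- resolve_n(config, length(ppi$nodes))

  prediction <- switch(
    variant,
    wmatrix_only = rank_by_score(wmatrix_node_scores(ppi, weights, subnets),
                                 n_out, "wmatrix_score"),
    score_initial_only = rank_by_score(weights$score_initial, n_out,
                                       "score_initial"),
    run_expansion(ppi, subnets, weights, config)
  )

  conf <- confusion(prediction, bundle$essentials, ppi$nodes)
  structure(
    list(prediction = prediction, confusion = conf, measures = measures(conf),
         jackknife = jackknife(prediction, bundle$essentials),
         subnets = subnets, weights = weights, variant = variant, n = n_out),
    class = "sesn_run"
  )
}

# Sum of incident weight-matrix entries over all sub-networks (the
# "no seed expansion" ranking score).
wmatrix_node_scores <- function(ppi, weights, subnets) {
  sc <- stats::setNames(rep(0, length(ppi$nodes)), ppi$nodes)
  for (i in seq_len(subnets$m)) {
    e_i <- subnets$edges[[i]]
    if (!nrow(e_i)) next
    w <- weights$wmatrix[[i]]
    acc <- tapply(c(w, w), c(e_i[, 1L], e_i[, 2L]), sum)
    sc[names(acc)] <- sc[names(acc)] + as.vector(acc)
  }
  sc
}

# Descending-score ranking with lexicographic ID tie-break.
rank_by_score <- function(scores, n, label) {
  ids <- names(scores)
  ord <- order(-unname(scores), ids, method = "radix")
  top <- ids[ord][seq_len(n)]
  ranked_prediction(protein = top, provenance = rep(label, n),
                    step = seq_len(n), n = n)
}

#' @export
print.sesn_run <- function(x, ...) {
  cat(sprintf("<sesn_run> variant = %s, n = %d\n", x$variant, x$n))
  print(x$measures)
  invisible(x)
}

#' The nine exponent vectors of the standard ablation sweep
#'
#' Eight single-deletion vectors (each of the eight exponents set to 0 in
#' turn: GO, co-expression, complex and subcellular factors of the node
#' score, then GO, activity, complex and subcellular factors of the weight
#' matrix) plus the all-ones vector.
#'
#' @return Named list of nine integer vectors of length 8.
#' @export
ablation_alpha_sets <- function() {
  labels <- c("initial_go", "initial_gene", "initial_com", "initial_sub",
              "W_go", "W_gene", "W_com", "W_sub", "all")
  sets <- lapply(1:9, function(j) {
    a <- rep(1L, 8L)
    if (j <= 8L) a[j] <- 0L
    a
  })
  stats::setNames(sets, labels)
}

#' Sweep the biological-data ablation
#'
#' Runs the pipeline once per exponent vector, holding every other setting
#' (including the RNG seed, hence the seed draws) fixed, and collects the
#' statistical measures into one table.
#'
#' @inheritParams run_pipeline
#' @param alpha_sets named list of exponent vectors (default
#'   [ablation_alpha_sets()]).
#' @param ... further arguments passed to [run_pipeline()].
#' @return A list with `measures` (data frame, one row per exponent vector)
#'   and `runs` (the individual `sesn_run` objects).
#' @export
run_ablation_sweep <- function(ppi, expression, bundle,
                               alpha_sets = ablation_alpha_sets(), ...) {
  runs <- lapply(alpha_sets, function(a)
    run_pipeline(ppi, expression, bundle, variant = "sesn", alpha = a, ...))
  tab <- do.call(rbind, lapply(names(runs), function(nm) {
    m <- runs[[nm]]$measures
    data.frame(label = nm,
               alpha = paste(alpha_preset(alpha_sets[[nm]]), collapse = ""),
               sn = m$sn, sp = m$sp, ppv = m$ppv, npv = m$npv,
               f = m$f, acc = m$acc, stringsAsFactors = FALSE)
  }))
  list(measures = tab, runs = runs)
}
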