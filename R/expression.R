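#' Sample plans for raw expression matrices
#'
#' A sample plan states how the raw columns of an expression matrix map to
#' expression sample points. In `cycles` mode the columns hold `cycles`
#' repetitions of a `points`-long time course (yeast-style cell-cycle data:
#' the value of sample point i is averaged over the i-th time point of every
#' cycle). In `replicates` mode the columns hold `samples` consecutive
#' blocks of `reps` technical replicates (fly-style data). The number of
#' sample points -- and hence of active sub-networks -- is `points` or
#' `samples` respectively.
#'
#' @param points number of time points per cycle.
#' @param cycles number of cycles.
#' @return An object of class `sample_plan`.
#' @examples
#' plan_cycles(12, 3)     # 36 raw columns, 12 sample points
#' plan_replicates(34, 4) # 136 raw columns, 34 sample points
#' @export
plan_cycles <- function(points, cycles) {
  points <- as.integer(points); cycles <- as.integer(cycles)
  stopifnot(points >= 1L, cycles >= 1L)
  structure(list(mode = "cycles", points = points, cycles = cycles),
            class = "sample_plan")
}

#' @param samples number of sample points.
#' @param reps number of replicate columns per sample.
#' @rdname plan_cycles
#' @export
plan_replicates <- function(samples, reps) {
  samples <- as.integer(samples); reps <- as.integer(reps)
  stopifnot(samples >= 1L, reps >= 1L)
  structure(list(mode = "replicates", samples = samples, reps = reps),
            class = "sample_plan")
}

#' @export
print.sample_plan <- function(x, ...) {
  if (x$mode == "cycles")
    cat(sprintf("<sample_plan> cycles: %d points x %d cycles (%d columns)\n",
                x$points, x$cycles, plan_length(x)))
  else
    cat(sprintf("<sample_plan> replicates: %d samples x %d reps (%d columns)\n",
                x$samples, x$reps, plan_length(x)))
  invisible(x)
}

#' Number of raw columns / sample points implied by a plan
#'
#' @param plan a [plan_cycles()] or [plan_replicates()] object.
#' @return `plan_length()`: the required number of raw expression columns;
#'   `plan_samples()`: the number of averaged sample points.
#' @export
plan_length <- function(plan) {
  stopifnot(inherits(plan, "sample_plan"))
  if (plan$mode == "cycles") plan$points * plan$cycles else plan$samples * plan$reps
}

#' @rdname plan_length
#' @export
plan_samples <- function(plan) {
  stopifnot(inherits(plan, "sample_plan"))
  if (plan$mode == "cycles") plan$points else plan$samples
}

# Element-wise mean over rows sharing a gene ID (probe averaging).
collapse_duplicate_rows <- function(values, ids) {
  ids <- as.character(ids)
  if (!anyDuplicated(ids)) {
    rownames(values) <- ids
    return(values[order_ids(ids), , drop = FALSE])
  }
  f <- factor(ids, levels = sort_ids(unique(ids)))
  out <- rowsum(values, f) / as.vector(table(f))
  rownames(out) <- levels(f)
  out
}

#' Raw expression matrix with its sample plan
#'
#' @param values numeric matrix (genes x raw columns) with gene IDs as row
#'   names; values must be non-negative.
#' @param plan a [plan_cycles()] or [plan_replicates()] object.
#' @return An object of class `raw_expression` with elements `values` and
#'   `plan`.
#' @export
raw_expression <- function(values, plan) {
  stopifnot(is.matrix(values), is.numeric(values), !is.null(rownames(values)),
            inherits(plan, "sample_plan"))
  expected <- plan_length(plan)
  if (ncol(values) != expected)
    stop(sprintf("expression matrix has %d column(s) but the sample plan requires %d",
                 ncol(values), expected))
  if (anyNA(values) || any(values < 0))
    stop("expression values must be non-negative and non-missing")
  structure(list(values = values, plan = plan), class = "raw_expression")
}

#' @export
print.raw_expression <- function(x, ...) {
  cat(sprintf("<raw_expression> %d genes x %d raw columns (%s plan, %d sample points)\n",
              nrow(x$values), ncol(x$values), x$plan$mode, plan_samples(x$plan)))
  invisible(x)
}

#' Read a gene expression matrix
#'
#' Tab-separated, header row required, first column the gene ID. Genes that
#' appear on multiple rows (multiple probes) are collapsed by the
#' element-wise arithmetic mean. The column count is validated against the
#' sample plan.
#'
#' @param path path to the expression TSV.
#' @param plan a [plan_cycles()] or [plan_replicates()] object.
#' @return A [raw_expression()] object.
#' @export
read_expression <- function(path, plan) {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file must have a gene ID column plus data columns")
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", path)
  raw_expression(collapse_duplicate_rows(mat, ids), plan)
}

#' Average raw expression columns into per-sample values
#'
#' In `cycles` mode, sample point i is the mean of the i-th time point over
#' all cycles; in `replicates` mode it is the mean of the i-th consecutive
#' replicate block.
#'
#' @param raw a [raw_expression()] object.
#' @return An object of class `averaged_expression` with `ge` (genes x
#'   sample points matrix of averaged values), `n_samples`, and `plan`.
#' @export
average_expression <- function(raw) {
  stopifnot(inherits(raw, "raw_expression"))
  vals <- raw$values
  plan <- raw$plan
  m <- plan_samples(plan)
  ge <- matrix(0, nrow = nrow(vals), ncol = m,
               dimnames = list(rownames(vals), paste0("s", seq_len(m))))
  for (i in seq_len(m)) {
    cols <- if (plan$mode == "cycles") i + plan$points * (seq_len(plan$cycles) - 1L)
            else (i - 1L) * plan$reps + seq_len(plan$reps)
    ge[, i] <- rowMeans(vals[, cols, drop = FALSE])
  }
  structure(list(ge = ge, n_samples = m, plan = plan),
            class = "averaged_expression")
}

#' 3-sigma activity thresholds for one gene
#'
#' For an averaged expression vector with mean `Avg` and sample standard
#' deviation `sigma` (denominator n - 1), the k-sigma threshold is
#' `Avg + k * sigma * (1 - 1 / (1 + sigma^2))` for k = 1, 2, 3. The damping
#' factor shrinks the threshold towards the mean for quiet genes and
#' approaches 1 for strongly fluctuating ones.
#'
#' @param x numeric vector of averaged expression values (length >= 2).
#' @return Named numeric vector with `avg`, `sigma`, `thr1`, `thr2`, `thr3`.
#' @examples
#' compute_thresholds(c(rep(1, 11), 10))
#' @export
compute_thresholds <- function(x) {
  if (length(x) < 2L)
    stop("degenerate input: need at least 2 sample points to estimate sigma")
  avg <- mean(x)
  s <- stats::sd(x)
  damp <- 1 - 1 / (1 + s^2)
  c(avg = avg, sigma = s,
    thr1 = avg + 1 * s * damp,
    thr2 = avg + 2 * s * damp,
    thr3 = avg + 3 * s * damp)
}

#' Discretized activity probabilities for one gene
#'
#' Maps each averaged expression value to the probability that the gene is
#' actively expressed at that sample point: 0.99 at or above the 3-sigma
#' threshold, 0.95 in the 2-sigma band, 0.68 in the 1-sigma band, and 0
#' below the 1-sigma threshold.
#'
#' @param x numeric vector of averaged expression values.
#' @param thresholds output of [compute_thresholds()] for the same gene.
#' @return Numeric vector of the same length with values in
#'   \{0, 0.68, 0.95, 0.99\}.
#' @export
compute_activity <- function(x, thresholds) {
  ifelse(x >= thresholds[["thr3"]], 0.99,
         ifelse(x >= thresholds[["thr2"]], 0.95,
                ifelse(x >= thresholds[["thr1"]], 0.68, 0)))
}

#' Per-gene activity model over all sample points
#'
#' Computes, for every gene of an averaged expression matrix, the mean,
#' standard deviation, the three k-sigma thresholds and the per-sample
#' activity probabilities. Genes with constant expression have sigma 0, so
#' all thresholds collapse onto the mean and every sample is assigned 0.99;
#' the optional `min_expression` floor zeroes out the activity of genes
#' whose mean lies below it (off by default).
#'
#' @param avg an [average_expression()] result.
#' @param min_expression optional non-negative floor on the gene mean.
#' @return An object of class `activity_model` with `genes`, `avg`, `sigma`,
#'   `thr` (genes x 3 matrix), `ap` (genes x sample points matrix) and
#'   `n_samples`.
#' @export
activity_model <- function(avg, min_expression = NULL) {
  stopifnot(inherits(avg, "averaged_expression"))
  ge <- avg$ge
  if (ncol(ge) < 2L)
    stop("degenerate input: need at least 2 sample points to estimate sigma")
  mu <- rowMeans(ge)
  s <- apply(ge, 1L, stats::sd)
  damp <- 1 - 1 / (1 + s^2)
  thr <- cbind(thr1 = mu + s * damp, thr2 = mu + 2 * s * damp,
               thr3 = mu + 3 * s * damp)
  rownames(thr) <- rownames(ge)
  ap <- matrix(0, nrow = nrow(ge), ncol = ncol(ge), dimnames = dimnames(ge))
  ap[ge >= thr[, "thr1"]] <- 0.68
  ap[ge >= thr[, "thr2"]] <- 0.95
  ap[ge >= thr[, "thr3"]] <- 0.99
  if (!is.null(min_expression)) ap[mu < min_expression, ] <- 0
  structure(
    list(genes = rownames(ge), avg = mu, sigma = s, thr = thr, ap = ap,
         n_samples = ncol(ge)),
    class = "activity_model"
  )
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> %d genes x %d sample points; %.1f%% active entries\n",
              length(x$genes), x$n_samples, 100 * mean(x$ap > 0)))
  invisible(x)
}
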