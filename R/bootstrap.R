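#' Rebuild synthetic genome sets from a fitted partition
#'
#' Simulates new genome sets from a fitted core/accessory partition, for
#' bootstrap quality control. Each synthetic genome starts "complete":
#' it holds every core trait plus `k` accessory traits drawn without
#' replacement from the accessory pool, weighted by the observed
#' per-trait genome counts, where `k = round(G - |core|)` and `G` is the
#' estimated complete genome size (mean over genomes of observed size
#' divided by posterior completeness). Each synthetic genome is then
#' rarefied: every trait is independently retained with probability
#' equal to the corresponding original genome's posterior completeness.
#'
#' Construction labels are kept, so downstream reclassification can be
#' scored against the truth of the construction ([bootstrap_rates()]).
#'
#' @param object a fitted [corepan()] object.
#' @param nsim number of synthetic genome sets.
#' @param seed integer seed; the same seed reproduces the same sets.
#' @param ... unused.
#' @return a list of `nsim` lists, each with elements `matrix` (a
#'   [trait_matrix()], one synthetic genome per original genome) and
#'   `labels` (named character vector over its traits: `"core"` or
#'   `"accessory"` as constructed).
#' @export
simulate.corepan <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) .build_synthetic(object))
}

# One synthetic genome set from a fitted partition; uses the current RNG state.
.build_synthetic <- function(fit) {
  m <- fit$matrix
  post <- stats::setNames(fit$completeness$posterior, fit$completeness$genome_id)
  if (any(post == 0))
    stop("posterior completeness of 0 for genome(s) ",
         paste(utils::head(names(post)[post == 0], 5), collapse = ", "),
         ": cannot scale synthetic genome sizes", call. = FALSE)
  core <- fit$core
  acc <- setdiff(trait_ids(m), core)
  counts <- trait_count(m)

  G <- mean(genome_sizes(m) / post)
  k <- round(G - length(core))
  if (k < 0) k <- 0
  if (k > length(acc)) k <- length(acc)
  if (k > 0 && length(acc) == 0)
    stop("accessory pool empty but estimated genome size exceeds the core",
         call. = FALSE)

  genomes <- genome_ids(m)
  full <- matrix(FALSE, length(genomes), length(core) + length(acc),
                 dimnames = list(genomes, c(core, acc)))
  full[, core] <- TRUE
  for (g in genomes) {
    if (k > 0)
      full[g, sample(acc, k, replace = FALSE, prob = counts[acc])] <- TRUE
    # rarefy to the genome's posterior completeness
    keep <- stats::runif(ncol(full)) < post[g]
    full[g, ] <- full[g, ] & keep
  }
  labels <- stats::setNames(
    rep(c("core", "accessory"), c(length(core), length(acc))),
    c(core, acc))
  observed <- colSums(full) > 0
  syn <- trait_matrix(full[, observed, drop = FALSE], drop_empty = TRUE)
  list(matrix = syn, labels = labels[trait_ids(syn)])
}

#' Bootstrap false discovery rate and sensitivity of a partition
#'
#' Estimates how reliable a fitted core/accessory partition is by
#' rebuilding synthetic genome sets from it ([simulate.corepan()]),
#' re-running the classifier on each, and comparing the predicted core
#' against the construction labels. The false discovery rate is the
#' fraction of the predicted core that was constructed as accessory;
#' sensitivity is the fraction of the constructed core recovered.
#' Estimates are means over replicates; more replicates give a steadier
#' estimate.
#'
#' The synthetic runs reuse the original fit's posterior completeness
#' values as priors (the rarefaction was performed at exactly those
#' rates, so they are known to the synthetic run) and the original fit's
#' configuration.
#'
#' @param fit a fitted [corepan()] object.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed. Replicate `i` draws from its own seed
#'   derived from this one, so any replicate is reproducible on its own.
#' @return an object of class `corepan_boot`: list with `n_reps`,
#'   `per_rep` (data frame: `rep`, `constructed_core_size`,
#'   `predicted_core_size`, `true_core_recovered`,
#'   `constructed_accessory_called_core`, `fdr`, `sensitivity`),
#'   `fdr_estimate`, `sensitivity_estimate`, `seed`.
#' @examples
#' pg <- generate_pangenome(n_genomes = 10, core_size = 50,
#'                          accessory_pool_size = 100, seed = 3)
#' fit <- corepan(pg$matrix, completeness = pg$completeness)
#' bootstrap_rates(fit, n_reps = 2, seed = 1)
#' @export
bootstrap_rates <- function(fit, n_reps = 10, seed = 1) {
  stopifnot(inherits(fit, "corepan"))
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1)
    stop("n_reps must be a positive integer", call. = FALSE)
  cfg <- fit$config
  post <- stats::setNames(fit$completeness$posterior, fit$completeness$genome_id)

  per_rep <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- .rep_seed(seed, i)
    syn <- simulate(fit, nsim = 1, seed = rep_seed)[[1]]
    refit <- tryCatch(
      corepan(syn$matrix, completeness = pmin(post, 1),
              max_iter = cfg$max_iter, clamp = cfg$clamp,
              seed_core = cfg$seed_core, drop_warn = cfg$drop_warn),
      error = function(e)
        stop("bootstrap replicate ", i, " failed: ", conditionMessage(e),
             call. = FALSE))
    pred <- refit$core
    lab <- syn$labels
    recovered <- sum(lab[pred] == "core")
    false_core <- sum(lab[pred] == "accessory")
    ccs <- sum(lab == "core")
    per_rep[[i]] <- data.frame(
      rep = i,
      constructed_core_size = ccs,
      predicted_core_size = length(pred),
      true_core_recovered = recovered,
      constructed_accessory_called_core = false_core,
      fdr = if (length(pred) > 0) false_core / length(pred) else 0,
      sensitivity = if (ccs > 0) recovered / ccs else NA_real_)
  }
  per_rep <- do.call(rbind, per_rep)
  structure(list(
    n_reps = n_reps,
    per_rep = per_rep,
    fdr_estimate = mean(per_rep$fdr),
    sensitivity_estimate = mean(per_rep$sensitivity),
    seed = seed),
    class = "corepan_boot")
}

# deterministic per-replicate seed, kept inside 32-bit integer range
.rep_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %%
               (.Machine$integer.max - 1)) + 1L
}

#' @export
print.corepan_boot <- function(x, ...) {
  cat("bootstrap partition QC (", x$n_reps, " replicate(s), seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  false discovery rate: %.4f\n", x$fdr_estimate))
  cat(sprintf("  sensitivity:          %.4f\n", x$sensitivity_estimate))
  invisible(x)
}
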