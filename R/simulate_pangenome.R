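#' Generate a ground-truth synthetic pan-genome
#'
#' Builds a genome set with known core/accessory structure and known
#' per-genome completeness, for testing and benchmarking the
#' classifier. Every "full" genome carries all core traits plus an
#' independent draw of accessory traits (accessory trait `j` is carried
#' with probability `carriage[j]`); the genome is then rarefied by
#' retaining each trait independently with probability equal to its
#' true completeness — emulating the trait loss of incomplete MAGs and
#' SAGs.
#'
#' The default carriage profile decays geometrically over ranked
#' accessory traits (`0.5 * 0.998^rank`, floored at 0.01), giving a few
#' near-common accessory traits and a long tail of rare ones, the
#' qualitative shape of prokaryote accessory genomes. With the default
#' sizes a complete genome carries ~1000 core + ~240 accessory traits.
#'
#' Traits that end up in no genome after rarefaction cannot be
#' represented in the incidence matrix and are dropped from the emitted
#' matrix (their ids are recorded in `dropped`).
#'
#' @param n_genomes number of genomes.
#' @param core_size number of core traits.
#' @param accessory_pool_size number of accessory traits in the pool.
#' @param carriage per-trait carriage probabilities for the accessory
#'   pool (length `accessory_pool_size`), or `NULL` for the default
#'   geometric profile.
#' @param completeness either a length-2 range for uniform sampling of
#'   true per-genome completeness (default `c(0.5, 1)`), or a vector of
#'   length `n_genomes` of true fractions in (0, 1].
#' @param seed integer seed; same seed, same pan-genome.
#' @return an object of class `syn_pangenome`: list with `matrix` (the
#'   emitted [trait_matrix()]), `true_core` / `accessory_ids` (trait id
#'   vectors), `completeness` (named true retention fractions),
#'   `carriage`, `assigned` (pre-rarefaction logical incidence),
#'   `dropped` (trait ids lost entirely to rarefaction) and `seed`.
#' @export
generate_pangenome <- function(n_genomes = 50, core_size = 1000,
                               accessory_pool_size = 2000,
                               carriage = NULL,
                               completeness = c(0.5, 1),
                               seed = 1) {
  stopifnot(n_genomes >= 1, core_size >= 1, accessory_pool_size >= 1)
  if (is.null(carriage))
    carriage <- pmax(0.5 * 0.998^(seq_len(accessory_pool_size) - 1), 0.01)
  stopifnot(length(carriage) == accessory_pool_size,
            all(carriage > 0), all(carriage <= 1))
  set.seed(seed)
  if (length(completeness) == 2 && is.null(names(completeness)) &&
      n_genomes != 2) {
    c_true <- stats::runif(n_genomes, completeness[1], completeness[2])
  } else if (length(completeness) == n_genomes) {
    c_true <- as.numeric(completeness)
  } else if (length(completeness) == 2) {
    c_true <- stats::runif(n_genomes, completeness[1], completeness[2])
  } else {
    stop("completeness must be a length-2 range or one value per genome",
         call. = FALSE)
  }
  stopifnot(all(c_true > 0), all(c_true <= 1))
  genomes <- sprintf("g%03d", seq_len(n_genomes))
  names(c_true) <- genomes
  core_ids <- sprintf("core_%04d", seq_len(core_size))
  acc_ids <- sprintf("acc_%04d", seq_len(accessory_pool_size))

  n_traits <- core_size + accessory_pool_size
  assigned <- matrix(FALSE, n_genomes, n_traits,
                     dimnames = list(genomes, c(core_ids, acc_ids)))
  assigned[, core_ids] <- TRUE
  for (g in seq_len(n_genomes))
    assigned[g, acc_ids] <- stats::runif(accessory_pool_size) < carriage
  emitted <- assigned & matrix(stats::runif(n_genomes * n_traits), n_genomes) <
    c_true
  if (any(rowSums(emitted) == 0))
    stop("generator parameters yield empty genome(s); increase sizes or ",
         "completeness", call. = FALSE)
  observed <- colSums(emitted) > 0
  structure(list(
    matrix = trait_matrix(emitted[, observed, drop = FALSE]),
    true_core = core_ids,
    accessory_ids = acc_ids,
    completeness = c_true,
    carriage = carriage,
    assigned = assigned,
    dropped = colnames(emitted)[!observed],
    seed = seed),
    class = "syn_pangenome")
}

#' @export
print.syn_pangenome <- function(x, ...) {
  cat("synthetic pan-genome (seed ", x$seed, "): ",
      nrow(x$matrix), " genomes, core ", length(x$true_core),
      ", accessory pool ", length(x$accessory_ids), "\n", sep = "")
  cat("  true completeness: ",
      paste(signif(range(x$completeness), 3), collapse = "-"),
      "; ", length(x$dropped), " trait(s) lost to rarefaction\n", sep = "")
  invisible(x)
}

#' Hard presence/absence core baseline
#'
#' The classical core definition: traits present in (nearly) all
#' genomes. This is what threshold-based pan-genome tools compute on
#' complete genomes, and what collapses on incomplete MAGs/SAGs —
#' a core trait lost from just one incomplete genome leaves the strict
#' core.
#'
#' @param x a [trait_matrix()].
#' @param threshold minimum fraction of genomes a trait must appear in
#'   (default 1, i.e. 100% presence).
#' @return character vector of trait ids.
#' @export
strict_core <- function(x, threshold = 1) {
  stopifnot(inherits(x, "trait_matrix"), threshold > 0, threshold <= 1)
  trait_ids(x)[trait_count(x) / nrow(x) >= threshold]
}

#' Normalized residue between two core-size predictions
#'
#' Compares two predicted core sizes on a scale-free axis: the
#' difference divided by the mean of the two predictions. Antisymmetric,
#' zero for equal predictions, bounded in (-2, 2).
#'
#' @param core_a,core_b two predicted core sizes (counts).
#' @return `(core_a - core_b) / mean(core_a, core_b)`.
#' @export
normalized_residue <- function(core_a, core_b) {
  stopifnot(is.numeric(core_a), is.numeric(core_b),
            core_a >= 0, core_b >= 0)
  if (core_a + core_b == 0)
    stop("normalized residue undefined when both core sizes are zero",
         call. = FALSE)
  (core_a - core_b) / mean(c(core_a, core_b))
}

#' Core fraction of the estimated genome size
#'
#' Predicted core size divided by the estimated number of traits per
#' complete genome, where the denominator is the mean over
#' sufficiently complete genomes of observed genome size divided by
#' prior completeness. Genomes below the completeness floor are
#' excluded: their size/completeness ratio is too noisy to anchor the
#' estimate.
#'
#' @param core_size predicted core size (count).
#' @param x a [trait_matrix()].
#' @param priors named numeric vector of per-genome prior completeness
#'   fractions.
#' @param floor minimum prior completeness for a genome to enter the
#'   denominator (default 0.40).
#' @return the ratio (a fraction of the estimated genome size).
#' @export
core_fraction <- function(core_size, x, priors, floor = 0.40) {
  stopifnot(inherits(x, "trait_matrix"), core_size >= 0)
  g <- genome_ids(x)
  if (is.null(names(priors)) || !all(g %in% names(priors)))
    stop("priors must be named and cover every genome", call. = FALSE)
  priors <- priors[g]
  keep <- priors >= floor
  if (!any(keep))
    stop("no genome at or above the completeness floor of ", floor,
         call. = FALSE)
  core_size / mean(genome_sizes(x)[keep] / priors[keep])
}

#' Robustness experiments over completeness structure
#'
#' Desk-scale reproductions of two stress tests of the classifier on
#' synthetic data with known truth.
#'
#' `type = "strata"` generates genome sets whose true completeness is
#' drawn from one of three strata (10-50%, 50-70%, 70-100%) and
#' records, per run, the fraction of the true core recovered and the
#' empirical false discovery rate against the generator's truth.
#' Recovery is expected to degrade, not improve, as completeness falls.
#'
#' `type = "goodbad"` fixes one "good" genome (completeness drawn above
#' 45%) and adds a varying number of "bad" genomes (completeness below
#' 45%): additional bad genomes carry independent evidence and should
#' not inflate the false discovery rate.
#'
#' Runs use the generator truth as completeness priors (idealized runs:
#' the question is what the classifier does with correct priors, not
#' how priors are obtained). With `boot_reps >= 1`, each run also
#' records the bootstrap FDR estimate for comparison with the empirical
#' one.
#'
#' @param type `"strata"` or `"goodbad"`.
#' @param n_runs runs per stratum / per grid cell.
#' @param n_genomes,core_size,accessory_pool_size generator sizes
#'   passed to [generate_pangenome()].
#' @param n_bad numbers of bad genomes for the `"goodbad"` grid.
#' @param boot_reps bootstrap replicates per run (0 disables).
#' @param seed integer master seed; each run derives its own.
#' @return a data frame with one row per run: the configuration
#'   (`stratum` or `n_bad`), `run`, `true_core_size`, `core_size`
#'   (predicted), `sensitivity`, `fdr` (both against generator truth)
#'   and, when `boot_reps >= 1`, `boot_fdr` and `boot_sensitivity`.
#' @export
robustness_experiment <- function(type = c("strata", "goodbad"),
                                  n_runs = 30, n_genomes = 50,
                                  core_size = 1000,
                                  accessory_pool_size = 2000,
                                  n_bad = c(4, 9, 19, 39),
                                  boot_reps = 0, seed = 1) {
  type <- match.arg(type)
  configs <- if (type == "strata") {
    list("70-100%" = c(0.70, 1.00),
         "50-70%"  = c(0.50, 0.70),
         "10-50%"  = c(0.10, 0.50))
  } else {
    stats::setNames(as.list(n_bad), paste0("bad_", n_bad))
  }
  rows <- list()
  run_id <- 0L
  for (cfg_name in names(configs)) {
    for (r in seq_len(n_runs)) {
      run_id <- run_id + 1L
      run_seed <- .rep_seed(seed, run_id)
      if (type == "strata") {
        pg <- generate_pangenome(n_genomes, core_size, accessory_pool_size,
                                 completeness = configs[[cfg_name]],
                                 seed = run_seed)
      } else {
        nb <- configs[[cfg_name]]
        set.seed(run_seed)
        comp <- c(stats::runif(1, 0.45, 1.00),
                  stats::runif(nb, 0.10, 0.45))
        pg <- generate_pangenome(nb + 1L, core_size, accessory_pool_size,
                                 completeness = comp, seed = run_seed + 1L)
      }
      fit <- corepan(pg$matrix, completeness = pg$completeness)
      truth <- pg$true_core
      pred <- fit$core
      row <- data.frame(
        config = cfg_name, run = r,
        true_core_size = length(truth),
        core_size = length(pred),
        sensitivity = length(intersect(pred, truth)) / length(truth),
        fdr = if (length(pred)) sum(!(pred %in% truth)) / length(pred) else 0,
        stringsAsFactors = FALSE)
      if (boot_reps >= 1) {
        bt <- bootstrap_rates(fit, n_reps = boot_reps,
                              seed = .rep_seed(run_seed, 1L))
        row$boot_fdr <- bt$fdr_estimate
        row$boot_sensitivity <- bt$sensitivity_estimate
      }
      rows[[run_id]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
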