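#' Fit the Bayesian core/accessory partition of a genome set
#'
#' Iteratively classifies every trait of a genome set as core or
#' accessory from its presence/absence pattern and per-genome
#' completeness estimates. Each iteration scores every trait by the
#' log-likelihood ratio of a core model (presence governed directly by
#' genome completeness) against an accessory model (independent traits
#' drawn from the pool at their observed frequencies; see
#' [log_p_core()]), calls a trait core when the ratio is positive, then
#' re-estimates each genome's completeness as the fraction of the
#' current core it carries. Iteration stops when the core set is
#' identical between two successive passes, or at `max_iter`.
#'
#' Completeness priors on the percent scale (CheckM convention) are
#' divided by 100; values in (0, 1] are taken as fractions; values above
#' 100 are rejected. Working values are clamped into `clamp` so that a
#' nominally complete genome never vetoes a trait absent from it.
#'
#' With `max_iter = 1` completeness is never re-estimated: traits are
#' classified once using the priors (recommended for genome sets that
#' are not species-like clusters, where the core-sharing assumption
#' behind the completeness update is doubtful). The reported posterior
#' is still computed once from the resulting core.
#'
#' The first pass needs a provisional core size; it is seeded from trait
#' prevalence (see `seed_core`). On well-separated data the converged
#' partition is insensitive to this choice.
#'
#' If the mean posterior completeness drops more than `drop_warn` below
#' the mean prior, a warning is recorded in the result: the genome set
#' likely mixes several clades dominated by one subclade, and the
#' "core" found is that subclade's.
#'
#' @param x a [trait_matrix()].
#' @param completeness per-genome completeness priors: a single value
#'   applied to all genomes, a named numeric vector, or a data frame with
#'   columns `genome_id` and `completeness` (as returned by
#'   [read_checkm()]). Fractions in (0, 1] or percentages in (1, 100].
#' @param max_iter maximum number of classification passes (>= 1).
#' @param clamp length-2 numeric; working completeness values (priors
#'   and re-entering posteriors) are clipped into this open interval.
#' @param seed_core rule seeding the provisional core for the first
#'   pass: `"half-mean-prior"` (traits with prevalence >= mean(prior)/2,
#'   the default), `"mean-prior"`, or `"all"`. Note that `"all"` is a
#'   fixed point of the update — with every trait in the core the
#'   accessory draw count vanishes for each genome, so nothing can be
#'   pruned; it is kept as a diagnostic, not a usable initialisation.
#' @param drop_warn posterior-vs-prior mean completeness drop (fraction)
#'   that triggers the subclade warning.
#' @param verbose print the iteration trace.
#' @return an object of class `corepan`: a list with elements `scores`
#'   (per-trait data frame: `trait_id`, `trait_count`, `log_p_core`,
#'   `log_p_accessory`, `llhr` in nats, `category`), `core` (character
#'   vector of core trait ids), `completeness` (per-genome data frame:
#'   `genome_id`, `prior`, `posterior`, `clamped`), `iterations`,
#'   `converged`, `warnings`, `trace` (core size per pass), `matrix`
#'   (the input), `config` and `call`.
#' @seealso [bootstrap_rates()] for FDR/sensitivity estimation of the
#'   returned partition, [simulate.corepan()] for synthetic genome sets
#'   rebuilt from it, [strict_core()] for the hard-threshold baseline.
#' @examples
#' set.seed(1)
#' pg <- generate_pangenome(n_genomes = 12, core_size = 60,
#'                          accessory_pool_size = 120, seed = 7)
#' fit <- corepan(pg$matrix, completeness = pg$completeness)
#' fit
#' length(intersect(fit$core, pg$true_core)) / length(pg$true_core)
#' @export
corepan <- function(x, completeness = 1, max_iter = 100L,
                    clamp = c(0.01, 0.99),
                    seed_core = c("half-mean-prior", "mean-prior", "all"),
                    drop_warn = 0.15, verbose = FALSE) {
  stopifnot(inherits(x, "trait_matrix"))
  if (nrow(x) == 0) stop("empty trait_matrix", call. = FALSE)
  seed_core <- match.arg(seed_core)
  max_iter <- as.integer(max_iter)
  stopifnot(max_iter >= 1L, length(clamp) == 2, clamp[1] > 0, clamp[2] < 1,
            clamp[1] < clamp[2])

  priors <- .resolve_priors(x, completeness)
  cw <- pmin(pmax(priors, clamp[1]), clamp[2])
  clamped_prior <- cw != priors
  diagnostics <- character()

  core <- initial_core(x, priors, rule = seed_core)
  trace <- integer()
  hist_cores <- list()     # classification outputs, most recent last
  hist_scores <- list()
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    scores <- .score_all(x, cw, core_size = length(core))
    if (anyNA(scores$llhr))
      diagnostics <- c(diagnostics, paste0(
        sum(is.nan(scores$llhr)),
        " trait(s) with undefined llhr (-Inf vs -Inf) classified accessory"))
    new_core <- scores$trait_id[scores$category == "core"]
    trace <- c(trace, length(new_core))
    if (verbose)
      message("pass ", iter, ": core size ", length(new_core))
    if (length(new_core) == 0)
      stop("model degenerated: all traits classified accessory; ",
           "check completeness priors and input matrix", call. = FALSE)

    if (length(hist_cores) >= 1 &&
        setequal(new_core, hist_cores[[length(hist_cores)]])) {
      converged <- TRUE
      core <- new_core
      break
    }
    if (length(hist_cores) >= 2 &&
        setequal(new_core, hist_cores[[length(hist_cores) - 1]])) {
      # 2-cycle between new_core and the previous output: keep the smaller
      prev <- hist_cores[[length(hist_cores)]]
      diagnostics <- c(diagnostics, paste0(
        "oscillation between core sizes ", length(new_core), " and ",
        length(prev), "; returning the smaller set"))
      if (length(prev) < length(new_core)) {
        core <- prev
        scores <- hist_scores[[length(hist_scores)]]
      } else core <- new_core
      converged <- FALSE
      break
    }
    hist_cores[[length(hist_cores) + 1]] <- new_core
    hist_scores[[length(hist_scores) + 1]] <- scores
    core <- new_core
    if (iter >= max_iter) break
    # completeness re-estimation feeding the next pass
    post <- update_completeness(x, core)
    cw <- pmin(pmax(post, clamp[1]), clamp[2])
  }

  posterior <- update_completeness(x, core)
  warn <- character()
  if (mean(posterior) < mean(priors) - drop_warn)
    warn <- c(warn, sprintf(
      paste0("mean posterior completeness (%.2f) dropped more than %.2f ",
             "below the mean prior (%.2f): the genome set may combine ",
             "several clades, with the core reflecting a dominant subclade"),
      mean(posterior), drop_warn, mean(priors)))

  structure(list(
    scores = scores,
    core = core,
    completeness = data.frame(
      genome_id = genome_ids(x), prior = unname(priors),
      posterior = unname(posterior), clamped = unname(clamped_prior),
      row.names = NULL, stringsAsFactors = FALSE),
    iterations = iter,
    converged = converged,
    warnings = warn,
    diagnostics = diagnostics,
    trace = trace,
    matrix = x,
    config = list(max_iter = max_iter, clamp = clamp,
                  seed_core = seed_core, drop_warn = drop_warn,
                  tie_policy = "llhr == 0 -> accessory",
                  llhr_units = "nats"),
    call = match.call()),
    class = "corepan")
}

#' Completeness re-estimation from a core set
#'
#' A genome's posterior completeness is the fraction of the core traits
#' it carries: genomes are assumed to hold the full core, so the share
#' observed estimates the recovered fraction of the genome.
#'
#' @param x a [trait_matrix()].
#' @param core nonempty character vector of core trait ids.
#' @return named numeric vector of per-genome fractions in [0, 1].
#' @export
update_completeness <- function(x, core) {
  stopifnot(inherits(x, "trait_matrix"))
  if (length(core) == 0)
    stop("empty core: the model degenerated (all traits accessory)",
         call. = FALSE)
  miss <- setdiff(core, trait_ids(x))
  if (length(miss))
    stop("core traits absent from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  rowSums(.tm_num(x)[, core, drop = FALSE]) / length(core)
}

#' Seed core for the first classification pass
#'
#' The first pass needs a provisional core size before any trait has
#' been classified. The default rule seeds with traits whose prevalence
#' (fraction of genomes carrying them) is at least half the mean prior
#' completeness: under the core model a core trait is expected in a
#' fraction `mean(prior)` of genomes, so half of that admits every
#' plausible candidate and lets the iteration prune. The final partition
#' should be insensitive to this rule on well-separated data.
#'
#' @inheritParams corepan
#' @param priors named numeric vector of prior completeness fractions.
#' @param rule seeding rule; see [corepan()].
#' @return character vector of seed core trait ids.
#' @export
initial_core <- function(x, priors,
                         rule = c("half-mean-prior", "mean-prior", "all")) {
  stopifnot(inherits(x, "trait_matrix"))
  rule <- match.arg(rule)
  if (rule == "all") return(trait_ids(x))
  prev <- trait_count(x) / nrow(x)
  cut <- if (rule == "half-mean-prior") mean(priors) / 2 else mean(priors)
  trait_ids(x)[prev >= cut]
}

# priors: single value, named vector, or data.frame(genome_id, completeness).
# Percent scale (1, 100] divided by 100; > 100 rejected; genome sets reconciled.
.resolve_priors <- function(x, completeness) {
  g <- genome_ids(x)
  if (is.data.frame(completeness)) {
    if (!all(c("genome_id", "completeness") %in% names(completeness)))
      stop("completeness data frame needs columns genome_id and completeness",
           call. = FALSE)
    p <- stats::setNames(completeness$completeness, completeness$genome_id)
  } else if (is.numeric(completeness) && length(completeness) == 1 &&
             is.null(names(completeness))) {
    p <- stats::setNames(rep(completeness, length(g)), g)
  } else if (is.numeric(completeness) && !is.null(names(completeness))) {
    p <- completeness
  } else {
    stop("completeness must be a single value, a named vector, or a ",
         "data frame with genome_id and completeness", call. = FALSE)
  }
  extra <- setdiff(names(p), g)
  missing <- setdiff(g, names(p))
  if (length(missing))
    stop("no completeness prior for genome(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  if (length(extra))
    warning("completeness given for genome(s) absent from the matrix: ",
            paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  p <- p[g]
  if (any(!is.finite(p)) || any(p <= 0))
    stop("completeness priors must be positive and finite", call. = FALSE)
  if (any(p > 100))
    stop("completeness priors above 100 are not interpretable ",
         "(neither fraction nor percent)", call. = FALSE)
  pct <- p > 1
  p[pct] <- p[pct] / 100
  p
}

#' @export
print.corepan <- function(x, ...) {
  cat("Bayesian core/accessory partition\n")
  cat(sprintf("  %d genomes x %d traits; core %d, accessory %d\n",
              nrow(x$matrix), ncol(x$matrix), length(x$core),
              ncol(x$matrix) - length(x$core)))
  cat(sprintf("  %d pass(es); %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  completeness: mean prior %.3f -> mean posterior %.3f\n",
              mean(x$completeness$prior), mean(x$completeness$posterior)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
summary.corepan <- function(object, ...) {
  s <- list(
    n_genomes = nrow(object$matrix),
    n_traits = ncol(object$matrix),
    core_size = length(object$core),
    iterations = object$iterations,
    converged = object$converged,
    trace = object$trace,
    llhr_quartiles = stats::quantile(
      object$scores$llhr[is.finite(object$scores$llhr)],
      c(0, 0.25, 0.5, 0.75, 1)),
    completeness = object$completeness,
    warnings = object$warnings,
    diagnostics = object$diagnostics)
  class(s) <- "summary.corepan"
  s
}

#' @export
print.summary.corepan <- function(x, ...) {
  cat(sprintf("corepan partition: %d genomes, %d traits, core %d\n",
              x$n_genomes, x$n_traits, x$core_size))
  cat("  core-size trace:", paste(x$trace, collapse = " -> "),
      if (x$converged) "(converged)\n" else "(not converged)\n")
  cat("  llhr quartiles (nats):",
      paste(signif(x$llhr_quartiles, 4), collapse = " "), "\n")
  cat("  posterior completeness: mean", signif(mean(x$completeness$posterior), 4),
      "range", paste(signif(range(x$completeness$posterior), 4), collapse = "-"),
      "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

#' @export
coef.corepan <- function(object, ...) {
  stats::setNames(object$scores$llhr, object$scores$trait_id)
}

#' Extract the core trait set
#' @param object a fitted [corepan()] object.
#' @return character vector of core trait ids.
#' @export
core_traits <- function(object) {
  stopifnot(inherits(object, "corepan"))
  object$core
}

#' @export
plot.corepan <- function(x, ...) {
  llhr <- x$scores$llhr
  llhr[!is.finite(llhr)] <- NA
  cols <- ifelse(x$scores$category == "core", "#2166ac", "#b2182b")
  o <- order(llhr)
  graphics::plot(seq_along(llhr), llhr[o], col = cols[o], pch = 16,
                 cex = 0.5, xlab = "traits (ranked)",
                 ylab = "log-likelihood ratio (nats)", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::legend("topleft", legend = c("core", "accessory"),
                   col = c("#2166ac", "#b2182b"), pch = 16, bty = "n")
  invisible(x)
}
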