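#' Trait log-probabilities under the core and accessory models
#'
#' The classifier weighs two hypotheses for each trait's observed
#' presence/absence pattern across the genome set.
#'
#' Under the core hypothesis a trait belongs to every genome, and is seen
#' in genome `g` with probability equal to that genome's completeness
#' `c_g`; the pattern probability is the product of `c_g` over genomes
#' carrying the trait and `1 - c_g` over genomes missing it.
#'
#' Under the accessory hypothesis the trait is one of many independent
#' accessory traits, each with pool frequency `f = |trait| / |T|` where
#' `|T|` is the total number of trait observations. A genome's accessory
#' complement is filled by drawing from the pool
#' `e_g = max(0, |g| - c_g * core_size)` times, so the probability that a
#' given accessory trait misses genome `g` is `(1 - f)^e_g`. The pattern
#' probability multiplies miss/hit probabilities across genomes.
#'
#' All computation is in log space (natural logarithms). A genome whose
#' accessory draw count clamps to zero makes the presence of any
#' accessory trait in it impossible; its presence then contributes
#' `-Inf`, returned as is (the classifier treats it downstream).
#'
#' @param trait a single trait id present in `x`.
#' @param x a [trait_matrix()].
#' @param completeness named numeric vector of working completeness
#'   values, one per genome of `x`, each strictly inside (0, 1).
#' @param core_size the current estimate of the core size `|core|`
#'   (a non-negative count).
#' @return `log_p_core()` and `log_p_accessory()` return a single
#'   log-probability (<= 0). `trait_llhr()` returns a one-row data frame
#'   with `trait_id`, `log_p_core`, `log_p_accessory`, `llhr` and
#'   `category` ("core" iff `llhr > 0`; ties and undefined ratios go to
#'   "accessory").
#' @examples
#' m <- trait_matrix(list(g1 = c("a", "b"), g2 = c("a", "b"), g3 = "b"))
#' cw <- c(g1 = 0.9, g2 = 0.8, g3 = 0.6)
#' log_p_core("a", m, cw)           # log(0.9 * 0.8 * 0.4)
#' trait_llhr("a", m, cw, core_size = 2)
#' @export
log_p_core <- function(trait, x, completeness) {
  cw <- .check_completeness(x, completeness)
  j <- .check_trait(x, trait)
  pres <- .tm_num(x)[, j]
  sum(ifelse(pres > 0, log(cw), log1p(-cw)))
}

#' @rdname log_p_core
#' @export
log_p_accessory <- function(trait, x, completeness, core_size) {
  cw <- .check_completeness(x, completeness)
  j <- .check_trait(x, trait)
  stopifnot(is.numeric(core_size), length(core_size) == 1, core_size >= 0)
  f <- trait_count(x) / total_observations(x)
  if (f[j] >= 1)
    stop("trait '", trait, "' accounts for the entire observation pool; ",
         "the accessory model is degenerate on a single-trait matrix",
         call. = FALSE)
  e <- pmax(0, genome_sizes(x) - cw * core_size)
  log_pbar <- e * log1p(-f[j])          # log P(miss in g), 0 when e == 0
  pres <- .tm_num(x)[, j] > 0
  hit <- log(-expm1(log_pbar))          # -Inf when log_pbar == 0
  sum(log_pbar[!pres]) + sum(hit[pres])
}

#' @rdname log_p_core
#' @export
trait_llhr <- function(trait, x, completeness, core_size) {
  lpc <- log_p_core(trait, x, completeness)
  lpa <- log_p_accessory(trait, x, completeness, core_size)
  llhr <- lpc - lpa
  category <- if (isTRUE(llhr > 0)) "core" else "accessory"
  if (is.nan(llhr))
    warning("llhr undefined (-Inf vs -Inf) for trait '", trait,
            "'; classified accessory", call. = FALSE)
  data.frame(trait_id = trait, log_p_core = lpc, log_p_accessory = lpa,
             llhr = llhr, category = category, stringsAsFactors = FALSE)
}

.check_trait <- function(x, trait) {
  stopifnot(is.character(trait), length(trait) == 1)
  j <- match(trait, trait_ids(x))
  if (is.na(j)) stop("unknown trait id: '", trait, "'", call. = FALSE)
  j
}

.check_completeness <- function(x, completeness) {
  g <- genome_ids(x)
  cw <- completeness
  if (length(cw) == 1 && is.null(names(cw))) cw <- stats::setNames(rep(cw, length(g)), g)
  if (is.null(names(cw)) || !all(g %in% names(cw)))
    stop("completeness must be named and cover every genome", call. = FALSE)
  cw <- cw[g]
  if (any(!is.finite(cw)) || any(cw <= 0) || any(cw >= 1))
    stop("working completeness must lie strictly inside (0, 1); got range [",
         signif(min(cw), 4), ", ", signif(max(cw), 4), "]", call. = FALSE)
  cw
}

# Vectorised scoring of every trait at once. m: trait_matrix, cw: working
# completeness (named, inside (0,1)), core_size: current |core|.
# Returns data.frame of per-trait scores.
.score_all <- function(m, cw, core_size) {
  M <- .tm_num(m)
  cw <- cw[rownames(M)]
  n_tot <- sum(M)
  f <- colSums(M) / n_tot
  if (any(f >= 1))
    stop("a single trait accounts for the entire observation pool; ",
         "the accessory model is degenerate", call. = FALSE)
  lpc <- drop(crossprod(M, log(cw)) + crossprod(1 - M, log1p(-cw)))

  e <- pmax(0, rowSums(M) - cw * core_size)       # per-genome draw count
  log_pbar <- outer(e, log1p(-f))                 # genomes x traits, <= 0
  hit <- log(-expm1(log_pbar))                    # -Inf where log_pbar == 0
  hit_term <- M * hit
  hit_term[M == 0] <- 0                           # kill 0 * -Inf
  lpa <- colSums(hit_term) + colSums((1 - M) * log_pbar)

  llhr <- lpc - lpa
  category <- ifelse(!is.nan(llhr) & llhr > 0, "core", "accessory")
  data.frame(trait_id = colnames(M), trait_count = as.integer(colSums(M)),
             log_p_core = lpc, log_p_accessory = lpa, llhr = llhr,
             category = category, row.names = NULL, stringsAsFactors = FALSE)
}
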