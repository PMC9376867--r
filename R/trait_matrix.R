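#' Genome-by-trait incidence matrix
#'
#' The basic container for a genome set: a binary incidence structure
#' recording which genomes carry which traits. A trait is any discrete
#' genome-encoded feature (gene cluster, COG, functional annotation);
#' the package never looks at sequences, only at presence/absence.
#'
#' Internally a `trait_matrix` is a logical matrix with genomes as rows
#' and traits as columns, both named. Traits observed in no genome are
#' not representable; genomes with zero traits are allowed (they carry
#' information about absence).
#'
#' @param x a logical or 0/1 numeric matrix with genome row names and
#'   trait column names, or a named list mapping each genome id to a
#'   character vector of trait ids it carries.
#' @param drop_empty drop traits with zero observations instead of
#'   raising an error. Genomes listed in `x` are always kept, even when
#'   they end up with no traits.
#' @return an object of class `trait_matrix`.
#' @examples
#' m <- trait_matrix(list(g1 = c("tA", "tB"), g2 = c("tB", "tC"), g3 = "tB"))
#' trait_count(m)
#' genome_sizes(m)
#' @export
trait_matrix <- function(x, drop_empty = FALSE) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("genome list must be fully named", call. = FALSE)
    genomes <- names(x)
    traits <- sort(unique(unlist(x, use.names = FALSE)))
    m <- matrix(FALSE, length(genomes), length(traits),
                dimnames = list(genomes, traits))
    for (g in genomes) m[g, unique(x[[g]])] <- TRUE
  } else if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("matrix must have genome row names and trait column names",
           call. = FALSE)
    if (is.numeric(x)) {
      if (!all(x %in% c(0, 1)))
        stop("numeric incidence matrix must contain only 0 and 1",
             call. = FALSE)
      x <- x == 1
    }
    if (!is.logical(x)) stop("matrix must be logical or 0/1", call. = FALSE)
    m <- x
  } else {
    stop("cannot build a trait_matrix from class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate genome ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate trait ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  empty <- colSums(m) == 0
  if (any(empty)) {
    if (!drop_empty)
      stop(sum(empty), " trait(s) observed in zero genomes (e.g. ",
           paste(utils::head(colnames(m)[empty], 3), collapse = ", "),
           "); traits must be observed at least once", call. = FALSE)
    m <- m[, !empty, drop = FALSE]
  }
  if (ncol(m) == 0) stop("trait_matrix has no traits", call. = FALSE)
  structure(m, class = c("trait_matrix", "matrix", "array"))
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x), "genomes x", ncol(x), "traits;",
      total_observations(x), "observations\n")
  cat("  trait prevalence: ",
      paste(range(trait_count(x)), collapse = "-"), " genomes; ",
      sum(trait_count(x) == nrow(x)), " trait(s) in all genomes\n", sep = "")
  invisible(x)
}

#' Accessors for trait_matrix counts
#'
#' `trait_count()` gives, for each trait, the number of genomes carrying
#' it; `genome_sizes()` gives the number of traits per genome;
#' `total_observations()` is the total size of the trait pool, i.e. the
#' sum of the per-trait counts.
#'
#' @param x a `trait_matrix`.
#' @return a named integer vector (`trait_count`, `genome_sizes`) or a
#'   single integer (`total_observations`).
#' @export
trait_count <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  colSums(unclass(x))
}

#' @rdname trait_count
#' @export
genome_sizes <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  rowSums(unclass(x))
}

#' @rdname trait_count
#' @export
total_observations <- function(x) sum(trait_count(x))

#' @rdname trait_count
#' @export
genome_ids <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  rownames(x)
}

#' @rdname trait_count
#' @export
trait_ids <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  colnames(x)
}

# plain numeric 0/1 matrix for arithmetic
.tm_num <- function(x) {
  m <- unclass(x)
  storage.mode(m) <- "double"
  m
}
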