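#' Read a Roary gene_presence_absence.csv
#'
#' Roary's presence/absence table has a fixed set of per-gene metadata
#' columns followed by one column per genome; a nonempty cell names the
#' member gene(s) of that genome in the cluster. Metadata columns are
#' recognised by header name (not position) to tolerate version drift;
#' every remaining column is taken as a genome.
#'
#' @param path path to the CSV file.
#' @return a [trait_matrix()] with Roary cluster names as trait ids.
#' @export
read_roary <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  meta_cols <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
                 "No. sequences", "Avg sequences per isolate",
                 "Genome Fragment", "Order within Fragment",
                 "Accessory Fragment", "Accessory Order with Fragment", "QC",
                 "Min group size nuc", "Max group size nuc",
                 "Avg group size nuc")
  if (!"Gene" %in% names(df))
    stop("not a Roary gene_presence_absence table: no 'Gene' column in ",
         path, call. = FALSE)
  dup <- unique(df$Gene[duplicated(df$Gene)])
  if (length(dup))
    stop("duplicate gene cluster names in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  genome_cols <- setdiff(names(df), meta_cols)
  if (length(genome_cols) == 0)
    stop("no genome columns found in ", path, call. = FALSE)
  pres <- t(as.matrix(df[genome_cols]) != "" &
              !is.na(as.matrix(df[genome_cols])))
  colnames(pres) <- df$Gene
  rownames(pres) <- genome_cols
  empty <- rowSums(pres) == 0
  if (any(empty))
    warning("genome(s) with no gene clusters retained: ",
            paste(rownames(pres)[empty], collapse = ", "), call. = FALSE)
  trait_matrix(pres)
}

#' Read a two-column representative/member cluster table
#'
#' The mmseqs2-style cluster TSV: each line maps a cluster
#' representative to one member gene id. The genome of origin of a
#' member is, by default, its id up to the last `sep` (so `g1_00017`
#' belongs to genome `g1`); supply `genome_map` to override the
#' convention with an explicit member-to-genome mapping.
#'
#' @param path path to the headerless two-column TSV.
#' @param sep separator character; the genome id is the member id up to
#'   its last occurrence.
#' @param genome_map optional named character vector (member id ->
#'   genome id), or path to a two-column TSV with that mapping.
#' @return a [trait_matrix()] with representatives as trait ids.
#' @export
read_clusters_tsv <- function(path, sep = "_", genome_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty cluster file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("malformed cluster line(s) (need 2 tab-separated fields) at line ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  rep_id <- vapply(parts, `[[`, "", 1)
  member <- vapply(parts, `[[`, "", 2)
  if (is.character(genome_map) && length(genome_map) == 1 &&
      is.null(names(genome_map)) && file.exists(genome_map)) {
    mp <- utils::read.delim(genome_map, header = FALSE,
                            colClasses = "character")
    genome_map <- stats::setNames(mp[[2]], mp[[1]])
  }
  if (!is.null(genome_map)) {
    genome <- unname(genome_map[member])
    bad <- which(is.na(genome))
  } else {
    genome <- sub(paste0(sep, "[^", sep, "]*$"), "", member)
    bad <- which(genome == member)   # no separator found
  }
  if (length(bad))
    stop("cannot infer genome of origin for member(s) at line ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  tm <- table(genome, rep_id) > 0
  trait_matrix(matrix(tm, nrow(tm), ncol(tm),
                      dimnames = list(rownames(tm), colnames(tm))))
}

#' Read a generic genome/trait pair table
#'
#' One `genome<TAB>trait` pair per line, no header: the simplest
#' trait-agnostic input (functional annotations, COGs, any discrete
#' trait).
#'
#' @param path path to the two-column TSV.
#' @return a [trait_matrix()].
#' @export
read_trait_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty trait file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("malformed line(s) (need 2 tab-separated fields) at line ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  genome <- vapply(parts, `[[`, "", 1)
  trait <- vapply(parts, `[[`, "", 2)
  tm <- table(genome, trait) > 0
  trait_matrix(matrix(tm, nrow(tm), ncol(tm),
                      dimnames = list(rownames(tm), colnames(tm))))
}

#' Write a trait matrix as genome/trait pairs
#'
#' @param x a [trait_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_pairs <- function(x, path) {
  stopifnot(inherits(x, "trait_matrix"))
  idx <- which(unclass(x), arr.ind = TRUE)
  df <- data.frame(genome = rownames(x)[idx[, 1]],
                   trait = colnames(x)[idx[, 2]])
  df <- df[order(df$genome, df$trait), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CheckM-style genome quality table
#'
#' Expects a tab-separated table with columns `Bin Id` and
#' `Completeness` (percent scale); a `Contamination` column, when
#' present, is carried along but never used by the model. Extra columns
#' are ignored.
#'
#' @param path path to the TSV.
#' @return a data frame with columns `genome_id`, `completeness`
#'   (fraction in (0, 1]) and, if present in the input,
#'   `contamination` (fraction).
#' @export
read_checkm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("Bin Id", "Completeness") %in% names(df)))
    stop("not a CheckM-style quality table (need columns 'Bin Id' and ",
         "'Completeness'): ", path, call. = FALSE)
  comp <- as.numeric(df$Completeness)
  bad <- which(is.na(comp) | comp <= 0 | comp > 100)
  if (length(bad))
    stop("completeness outside (0, 100] at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  out <- data.frame(genome_id = as.character(df$`Bin Id`),
                    completeness = comp / 100,
                    stringsAsFactors = FALSE)
  if ("Contamination" %in% names(df))
    out$contamination <- as.numeric(df$Contamination) / 100
  out
}

#' Write a fitted partition to disk
#'
#' Emits three files under `dir`: `traits.tsv` (per-trait scores and
#' classification), `genomes.tsv` (per-genome prior and posterior
#' completeness, genome size and core content) and `summary.txt`
#' (run summary echoing every configuration value actually used).
#' Numbers are printed with 6 significant digits; log-likelihood ratios
#' are in nats.
#'
#' @param fit a fitted [corepan()] object.
#' @param dir output directory (created if absent).
#' @return the three file paths, invisibly.
#' @export
write_partition <- function(fit, dir) {
  stopifnot(inherits(fit, "corepan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traits_path <- file.path(dir, "traits.tsv")
  genomes_path <- file.path(dir, "genomes.tsv")
  summary_path <- file.path(dir, "summary.txt")

  sc <- fit$scores
  sc$log_p_core <- signif(sc$log_p_core, 6)
  sc$log_p_accessory <- signif(sc$log_p_accessory, 6)
  sc$llhr <- signif(sc$llhr, 6)
  sc <- sc[c("trait_id", "category", "llhr", "log_p_core",
             "log_p_accessory", "trait_count")]
  utils::write.table(sc, traits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  m <- fit$matrix
  core_present <- rowSums(.tm_num(m)[, fit$core, drop = FALSE])
  gdf <- data.frame(
    genome_id = fit$completeness$genome_id,
    prior = signif(fit$completeness$prior, 6),
    posterior = signif(fit$completeness$posterior, 6),
    genome_size = genome_sizes(m),
    core_traits_present = as.integer(core_present),
    row.names = NULL)
  utils::write.table(gdf, genomes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cfg <- fit$config
  lines <- c(
    "corepan run summary",
    paste0("genomes\t", nrow(m)),
    paste0("traits\t", ncol(m)),
    paste0("core_size\t", length(fit$core)),
    paste0("accessory_size\t", ncol(m) - length(fit$core)),
    paste0("iterations\t", fit$iterations),
    paste0("converged\t", fit$converged),
    paste0("core_size_trace\t", paste(fit$trace, collapse = ",")),
    paste0("mean_prior_completeness\t",
           signif(mean(fit$completeness$prior), 6)),
    paste0("mean_posterior_completeness\t",
           signif(mean(fit$completeness$posterior), 6)),
    paste0("max_iter\t", cfg$max_iter),
    paste0("clamp_low\t", cfg$clamp[1]),
    paste0("clamp_high\t", cfg$clamp[2]),
    paste0("seed_core_rule\t", cfg$seed_core),
    paste0("subclade_drop_warning_threshold\t", cfg$drop_warn),
    paste0("tie_policy\t", cfg$tie_policy),
    paste0("llhr_units\t", cfg$llhr_units),
    if (length(fit$warnings)) paste0("warning\t", fit$warnings),
    if (length(fit$diagnostics)) paste0("note\t", fit$diagnostics))
  writeLines(lines, summary_path)
  invisible(c(traits = traits_path, genomes = genomes_path,
              summary = summary_path))
}

#' Re-read a written per-trait partition table
#'
#' @param path path to a `traits.tsv` written by [write_partition()].
#' @return the per-trait data frame.
#' @export
read_partition_traits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a pairwise ANI table
#'
#' Three tab-separated columns: `genome_a`, `genome_b`, `ani` (percent
#' in (0, 100]). A header line is detected and skipped when the third
#' field of the first line is not numeric.
#'
#' @param path path to the TSV.
#' @return a data frame with columns `genome_a`, `genome_b`, `ani`.
#' @export
read_ani <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("empty ANI file: ", path, call. = FALSE)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][3])))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("ANI table needs 3 columns (genome_a, genome_b, ani): ", path,
         call. = FALSE)
  df <- df[1:3]
  names(df) <- c("genome_a", "genome_b", "ani")
  df$ani <- as.numeric(df$ani)
  bad <- which(is.na(df$ani) | df$ani <= 0 | df$ani > 100)
  if (length(bad))
    stop("ANI outside (0, 100] at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  df
}

#' Write genome-to-cluster assignments
#'
#' @param clusters a `motu_clusters` object from [motu_components()].
#' @param path output path (two-column TSV `genome<TAB>motu`).
#' @return `path`, invisibly.
#' @export
write_motus <- function(clusters, path) {
  stopifnot(inherits(clusters, "motu_clusters"))
  df <- data.frame(
    genome = unlist(clusters, use.names = FALSE),
    motu = rep(names(clusters), lengths(clusters)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
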