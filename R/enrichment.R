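#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return object of class \code{gene_set_collection}: a named list of
#'   character vectors, with a \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(names_))
    stop("duplicate set names in GMT: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set: ", f[1])
    genes
  })
  names(sets) <- names_
  structure(sets,
            descriptions = stats::setNames(vapply(fields, `[`, "", 2),
                                           names_),
            class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection named list of character vectors (descriptions taken
#'   from the \code{descriptions} attribute when present).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  if (anyDuplicated(names(collection))) stop("duplicate set names")
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to a universe and filter by size
#'
#' Each set is intersected with the universe first; sets whose
#' intersection has fewer than \code{min_size} or more than
#' \code{max_size} genes are removed (so a large set mostly outside the
#' universe can survive, and a nominally large set can be filtered out).
#'
#' @param collection named list of gene sets.
#' @param universe character vector of genes under consideration.
#' @param min_size,max_size inclusive size bounds (defaults 15 and 500).
#' @return filtered \code{gene_set_collection} (sets already
#'   intersected with the universe).
#' @export
filter_sets <- function(collection, universe, min_size = 15L,
                        max_size = 500L) {
  stopifnot(length(universe) > 0)
  trimmed <- lapply(collection, intersect, y = universe)
  sizes <- lengths(trimmed)
  keep <- sizes >= min_size & sizes <= max_size
  out <- trimmed[keep]
  desc <- attr(collection, "descriptions")
  structure(out,
            descriptions = if (!is.null(desc)) desc[names(out)],
            class = "gene_set_collection")
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score on a sorted
# ranking. `stat_sorted` is descending; `hit` marks set members.
gsea_es <- function(stat_sorted, hit, weight_exponent = 1) {
  n <- length(stat_sorted)
  m <- sum(hit)
  w <- abs(stat_sorted)^weight_exponent
  inc <- numeric(n)
  total_hit_w <- sum(w[hit])
  if (total_hit_w == 0) {
    # all hit statistics are zero: fall back to equal hit weights
    inc[hit] <- 1 / m
  } else {
    inc[hit] <- w[hit] / total_hit_w
  }
  inc[!hit] <- -1 / (n - m)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], running = running, peak = peak)
}

#' Preranked gene set enrichment analysis (GSEA)
#'
#' Genes are sorted by descending ranking statistic (meta-z), ties broken
#' by gene id. The enrichment score is the maximum deviation from zero of
#' the weighted Kolmogorov-Smirnov running sum (set members contribute
#' \code{|stat|^weight_exponent}, normalized; non-members a uniform
#' decrement). Significance comes from a gene-label permutation null:
#' random sets of the same size drawn from the ranking. NES is the ES
#' divided by the mean absolute null ES of matching sign; the empirical
#' p-value uses a +1 pseudocount.
#'
#' @param ranking named numeric vector, gene -> ranking statistic, no
#'   missing values.
#' @param sets a \code{gene_set_collection} or a single character vector
#'   of genes (already filtered against the ranking; see
#'   [filter_sets()]).
#' @param n_perm number of permutations (default 10000).
#' @param weight_exponent KS weighting exponent (default 1; 0 gives the
#'   classic unweighted statistic).
#' @param seed integer seed for the permutation null.
#' @return data.frame: \code{set_name}, \code{size}, \code{es},
#'   \code{nes}, \code{pval}, \code{padj} (Benjamini-Hochberg), and a
#'   \code{leading_edge} list-column.
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 10000L,
                           weight_exponent = 1, seed = 1L) {
  if (anyNA(ranking)) stop("ranking contains missing values")
  if (is.null(names(ranking))) stop("ranking must be named by gene id")
  if (n_perm < 2) stop("need at least 2 permutations")
  if (!is.list(sets)) sets <- structure(list(set = sets),
                                        class = "gene_set_collection")
  ord <- order(-ranking, names(ranking), method = "radix")
  stat_sorted <- ranking[ord]
  genes_sorted <- names(ranking)[ord]
  n <- length(ranking)

  results <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    set_genes <- intersect(sets[[s]], genes_sorted)
    m <- length(set_genes)
    if (m == 0) stop("set empty after filtering: ", names(sets)[s])
    if (m >= n) stop("set covers the whole ranking: ", names(sets)[s])
    hit <- genes_sorted %in% set_genes
    obs <- gsea_es(stat_sorted, hit, weight_exponent)

    set.seed(substream_seed(seed, names(sets)[s]))
    null_es <- numeric(n_perm)
    hitp <- logical(n)
    for (p in seq_len(n_perm)) {
      hitp[] <- FALSE
      hitp[sample.int(n, m)] <- TRUE
      null_es[p] <- gsea_es(stat_sorted, hitp, weight_exponent)$es
    }
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign))
           else NA_real_
    pval <- (1 + sum(abs(same_sign) >= abs(obs$es))) /
      (1 + length(same_sign))
    leading <- if (obs$es >= 0) {
      genes_sorted[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
    } else {
      genes_sorted[obs$peak:n][hit[obs$peak:n]]
    }
    results[[s]] <- data.frame(set_name = names(sets)[s], size = m,
                               es = obs$es, nes = nes, pval = pval,
                               stringsAsFactors = FALSE)
    results[[s]]$leading_edge <- list(leading)
  }
  out <- do.call(rbind, results)
  out$padj <- bh_adjust(out$pval)
  out[, c("set_name", "size", "es", "nes", "pval", "padj",
          "leading_edge")]
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing overlap
#' k between a query gene list and a gene set, drawing |query| genes from
#' a universe containing |set in universe| successes.
#'
#' @param query character vector, must be a subset of \code{universe}.
#' @param set character vector (intersected with the universe).
#' @param universe background gene list (all genes considered in the
#'   meta-analysis).
#' @param set_name label.
#' @return one-row data.frame: \code{set_name}, \code{overlap_k},
#'   \code{query_size}, \code{set_size_in_universe},
#'   \code{universe_size}, \code{pval}.
#' @export
hypergeometric_overrep <- function(query, set, universe,
                                   set_name = "set") {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query is not a subset of the universe")
  set_u <- intersect(unique(set), universe)
  k <- length(intersect(query, set_u))
  data.frame(set_name = set_name,
             overlap_k = k,
             query_size = length(query),
             set_size_in_universe = length(set_u),
             universe_size = length(universe),
             pval = stats::phyper(k - 1, length(set_u),
                                  length(universe) - length(set_u),
                                  length(query), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Overrepresentation of a query list across a collection
#'
#' @param query gene list (subset of the universe).
#' @param collection named list of gene sets.
#' @param universe background gene list.
#' @return data.frame of [hypergeometric_overrep()] rows with
#'   Benjamini-Hochberg \code{padj}.
#' @export
overrepresentation <- function(query, collection, universe) {
  rows <- lapply(names(collection), function(nm)
    hypergeometric_overrep(query, collection[[nm]], universe, nm))
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pval)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at
#' 1 (delegates to [stats::p.adjust()] after validating the input).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
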