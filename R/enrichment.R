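# Three enrichment procedures over the ranked gene list: hypergeometric
# over-representation of annotation terms, expression-weighted cell-type
# bootstrap, and candidate gene-list permutation enrichment.

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, the upper-tail hypergeometric p-value of the overlap
#' between the target set and the term, within the supplied background.
#' Annotation gene sets are intersected with the background first; terms
#' whose (intersected) size exceeds `max_term_size` are excluded, which
#' focuses results on specific terms rather than ones covering thousands of
#' genes.  Benjamini-Hochberg adjustment is applied across tested terms.
#'
#' @param target character vector of genes (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param annotation named list mapping terms to gene vectors (e.g. from
#'   [read_gmt()]).
#' @param max_term_size largest term size tested (default 1000).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return `data.frame`: `label`, `p`, `p_adjusted`, `fold_change`,
#'   `sd_from_mean`, `n_overlap`, `term_size`, `significant`.
#' @export
overrepresentation <- function(target, background, annotation,
                               max_term_size = 1000L, alpha = 0.05) {
  target <- unique(target)
  background <- unique(background)
  if (length(target) == 0L) stop_invalid("empty target set")
  if (!all(target %in% background)) {
    stop_invalid("target genes must be a subset of the background")
  }
  N <- length(background)
  t_n <- length(target)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(unique(annotation[[term]]), background)
    m <- length(genes)
    if (m == 0L || m > max_term_size) return(NULL)
    k <- length(intersect(target, genes))
    p <- phyper(k - 1, m, N - m, t_n, lower.tail = FALSE)
    mu <- t_n * m / N
    sdh <- sqrt(mu * (N - m) / N * (N - t_n) / (N - 1))
    data.frame(label = term, p = p,
               fold_change = if (mu > 0) k / mu else NA_real_,
               sd_from_mean = if (sdh > 0) (k - mu) / sdh else NA_real_,
               n_overlap = k, term_size = m, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(label = character(0), p = numeric(0),
                      p_adjusted = numeric(0), fold_change = numeric(0),
                      sd_from_mean = numeric(0), n_overlap = integer(0),
                      term_size = integer(0), significant = logical(0)))
  }
  rows$p_adjusted <- bh_fdr(rows$p)
  rows$significant <- rows$p_adjusted < alpha
  rows[order(rows$p),
       c("label", "p", "p_adjusted", "fold_change", "sd_from_mean",
         "n_overlap", "term_size", "significant")]
}

#' Cell-type specificity matrix
#'
#' Specificity of gene `g` for cell type `c` is its mean expression in `c`
#' divided by its summed mean expression over all types, so each gene row
#' sums to 1.  All-zero genes are dropped with a warning.
#'
#' @param reference cell-type x gene matrix of nonnegative mean expression.
#' @return genes x cell-types matrix of class `specificity_matrix`, rows
#'   summing to 1.
#' @export
specificity_matrix <- function(reference) {
  reference <- as.matrix(reference)
  if (any(reference < 0)) stop_invalid("reference expression must be nonnegative")
  tot <- colSums(reference)
  if (any(tot == 0)) {
    warning(sprintf("dropping %d gene(s) with zero expression in every type",
                    sum(tot == 0)))
    reference <- reference[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  out <- t(sweep(reference, 2L, tot, `/`))
  class(out) <- c("specificity_matrix", class(out))
  out
}

# Assign background genes to joint transcript-length x GC quantile bins
# (default 10 x 10).  Bins with fewer than `min_bin` members are widened to
# the length decile, then to the whole background, with a warning.
.length_gc_bins <- function(meta, genes, n_bins = 10L, min_bin = 2L) {
  meta <- meta[match(genes, meta$gene), ]
  cutq <- function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
    if (length(br) < 2L) return(rep(1L, length(x)))
    as.integer(cut(x, br, include.lowest = TRUE))
  }
  b_len <- cutq(meta$transcript_length)
  b_gc <- cutq(meta$gc)
  bin <- paste(b_len, b_gc)
  members <- split(seq_along(genes), bin)
  small <- names(members)[vapply(members, length, integer(1)) < min_bin]
  if (length(small) > 0L) {
    warning("widening sparse length x GC bins to length deciles")
    by_len <- split(seq_along(genes), b_len)
    for (bn in small) {
      lb <- strsplit(bn, " ")[[1L]][1L]
      members[[bn]] <- by_len[[lb]]
      if (length(members[[bn]]) < min_bin) members[[bn]] <- seq_along(genes)
    }
  }
  list(bin = bin, members = members)
}

#' Expression-weighted cell-type enrichment bootstrap
#'
#' Tests whether a target gene list's summed cell-type specificity exceeds
#' that of random gene lists of the same size matched to the target on
#' transcript length and GC content (joint decile bins, sampled
#' proportionally), which can otherwise bias enrichment.  Per cell type:
#' `p = (1 + #[null >= observed]) / (1 + n_boot)`, fold change =
#' observed / null mean, and SD from mean = (observed - null mean) /
#' null SD; Benjamini-Hochberg adjustment across cell types.
#'
#' @param target character vector of genes, all present in `spec` and
#'   `meta`.
#' @param spec a [specificity_matrix()].
#' @param meta gene metadata `data.frame` with `gene`, `transcript_length`,
#'   `gc`.
#' @param n_boot bootstrap lists (default 100000; at least 1000 for a
#'   reportable p).
#' @param seed integer seed.
#' @return `data.frame`: `label` (cell type), `p`, `p_adjusted`,
#'   `fold_change`, `sd_from_mean`, `n_genes`.
#' @export
ewce_bootstrap <- function(target, spec, meta, n_boot = 100000L, seed = 1L) {
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  if (n_boot < 1000L) warning("`n_boot` < 1000 gives unstable EWCE p-values")
  background <- intersect(rownames(spec), meta$gene)
  target <- unique(target)
  missing <- setdiff(target, background)
  if (length(missing) > 0L) {
    stop_invalid("target genes absent from specificity/metadata: ",
                 paste(head(missing, 5L), collapse = ", "))
  }
  S <- spec[background, , drop = FALSE]
  bins <- .length_gc_bins(meta, background)
  t_idx <- match(target, background)
  observed <- colSums(S[t_idx, , drop = FALSE])
  draws <- with_seed(seed, {
    vapply(t_idx, function(i) {
      cand <- bins$members[[bins$bin[i]]]
      cand[sample.int(length(cand), n_boot, replace = TRUE)]
    }, integer(n_boot))
  })                                             # n_boot x |target|
  types <- colnames(S)
  null <- matrix(0, n_boot, length(types), dimnames = list(NULL, types))
  for (ct in types) {
    v <- S[, ct]
    null[, ct] <- rowSums(matrix(v[draws], nrow = n_boot))
  }
  p <- vapply(types, function(ct) {
    (1 + sum(null[, ct] >= observed[[ct]])) / (1 + n_boot)
  }, numeric(1))
  mu <- colMeans(null)
  sdev <- apply(null, 2L, sd)
  out <- data.frame(label = types, p = unname(p),
                    p_adjusted = bh_fdr(unname(p)),
                    fold_change = unname(observed / mu),
                    sd_from_mean = unname((observed - mu) / sdev),
                    n_genes = length(target), stringsAsFactors = FALSE)
  out[order(out$p), ]
}

#' Candidate gene-list permutation enrichment
#'
#' Sums the bootstrap-normalized first-component weights (Z) over the
#' candidate genes and compares the sum with sums over random gene sets of
#' the same size drawn from the ranked list.  One-sided by default
#' (enrichment among high weights); the low tail is available via `side`.
#' Candidate genes absent from the ranked list are dropped (intersection;
#' the dropped count is reported), never imputed.
#'
#' @param ranked a `ranked_gene_list` (from [bootstrap_gene_ranking()]).
#' @param candidate character vector of candidate genes.
#' @param n_perm number of random gene sets.
#' @param seed integer seed.
#' @param side "high" tests enrichment of high Z, "low" of low Z.
#' @param label result label.
#' @return one-row `data.frame`: `label`, `p`, `observed`, `sd_from_mean`,
#'   `fold_change` (NA: the observed/expected ratio of signed Z sums is not
#'   meaningful), `n_genes` (used), `n_dropped`.
#' @export
candidate_list_enrichment <- function(ranked, candidate, n_perm = 10000L,
                                      seed = 1L, side = c("high", "low"),
                                      label = "candidate") {
  side <- match.arg(side)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  z <- setNames(ranked$z, ranked$gene)
  cand <- intersect(unique(candidate), names(z))
  if (length(cand) == 0L) {
    stop_invalid("no candidate gene found in the ranked list; missing: ",
                 paste(head(unique(candidate), 5L), collapse = ", "))
  }
  n_dropped <- length(unique(candidate)) - length(cand)
  if (n_dropped > 0L) {
    message(sprintf("candidate list '%s': %d gene(s) not in the ranked list dropped",
                    label, n_dropped))
  }
  k <- length(cand)
  # summation in index order keeps the degenerate candidate == background
  # case exactly tied under floating-point addition
  observed <- sum(z[sort.int(match(cand, names(z)))])
  null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) sum(z[sort.int(sample.int(length(z), k))]),
           numeric(1))
  })
  p <- if (side == "high") {
    (1 + sum(null >= observed)) / (1 + n_perm)
  } else {
    (1 + sum(null <= observed)) / (1 + n_perm)
  }
  data.frame(label = label, p = p, observed = observed,
             sd_from_mean = (observed - mean(null)) / sd(null),
             fold_change = NA_real_, n_genes = k, n_dropped = n_dropped,
             stringsAsFactors = FALSE)
}

#' Read a GMT annotation file
#'
#' Tab-separated: term name, description, then member genes.
#'
#' @param path file path.
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  out
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
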