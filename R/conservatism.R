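## Phylogenetic niche conservatism: patristic distances from a tree,
## Euclidean distances between log2 utilization profiles, Mantel-style
## association between the two, pairwise profile correlations, and a
## within-group similarity test.

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j. Requires branch lengths, unique leaf labels, and
#' non-negative edge lengths.
#'
#' @param tree an [ape::read.tree()] `phylo` object, or a path to a
#'   Newick file, or a Newick string
#' @return symmetric numeric matrix with zero diagonal, rows/columns in
#'   tip-label order
#' @export
patristic_distances <- function(tree) {
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length)) {
    stop_data("tree has no branch lengths")
  }
  if (any(tree$edge.length < 0)) stop_data("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) {
    stop_data("duplicate leaf label(s): ",
              paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                    collapse = ", "))
  }
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    out <- if (file.exists(tree)) ape::read.tree(tree)
           else ape::read.tree(text = tree)
    if (is.null(out)) stop_data("could not parse Newick input")
    return(out)
  }
  stop_data("expected a phylo object, Newick file path or Newick string")
}

#' Euclidean distances between isolate utilization profiles
#'
#' Distance between isolate column vectors of a log2 fold-change matrix.
#' By default rows (metabolites) with any NA are dropped so all pairs use
#' the same metabolite set; with `pairwise_complete = TRUE` each pair
#' uses its own complete rows (distances then need not embed in one
#' Euclidean space).
#'
#' @param fc metabolite x isolate matrix (e.g. from [fold_change()])
#' @param pairwise_complete use pairwise-complete metabolites per pair
#' @return symmetric isolate distance matrix with zero diagonal
#' @export
profile_distances <- function(fc, pairwise_complete = FALSE) {
  stopifnot(is.matrix(fc), ncol(fc) >= 2)
  if (!pairwise_complete) {
    keep <- stats::complete.cases(fc)
    if (!any(keep)) stop_data("no metabolite is unmasked in every isolate")
    return(as.matrix(stats::dist(t(fc[keep, , drop = FALSE]))))
  }
  n <- ncol(fc)
  out <- matrix(0, n, n, dimnames = list(colnames(fc), colnames(fc)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- is.finite(fc[, i]) & is.finite(fc[, j])
      if (!any(ok)) {
        stop_data("isolates '", colnames(fc)[i], "' and '",
                  colnames(fc)[j], "' share no unmasked metabolites")
      }
      out[i, j] <- out[j, i] <- sqrt(sum((fc[ok, i] - fc[ok, j])^2))
    }
  }
  out
}

check_dist_matrix <- function(m, label) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_data(label, " must be a square matrix")
  }
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop_data(label, " must carry identical row and column labels")
  }
  if (max(abs(m - t(m))) > 1e-12) stop_data(label, " is not symmetric")
  if (any(diag(m) != 0)) stop_data(label, " diagonal must be zero")
  m
}

#' Association between phylogenetic and profile distance matrices
#'
#' Relates two distance matrices over the same isolates: an ordinary
#' least-squares regression of profile distance on phylogenetic distance
#' over the n(n-1)/2 unordered pairs (reported for display parity with
#' scatter-plot regressions of this kind), plus a Spearman rank
#' correlation with a Mantel-style permutation p-value, which is the
#' defensible test given that pairwise distances are not independent.
#' One matrix's labels are permuted `n_perm` times and
#' `p = (#\{rho_perm >= rho_obs\} + 1) / (n_perm + 1)` (one-sided:
#' association stronger than chance).
#'
#' @param phylo,profile symmetric distance matrices with matching labels
#'   (order may differ; `profile` is aligned to `phylo`)
#' @param n_perm number of label permutations (default 999)
#' @param seed integer seed for the permutation draw (mandatory; the
#'   routine leaves global RNG state untouched)
#' @return list: `slope`, `intercept`, `rho`, `p_mantel`, `n_pairs`,
#'   `n_perm`
#' @export
distance_association <- function(phylo, profile, n_perm = 999, seed) {
  phylo <- check_dist_matrix(phylo, "phylo distance matrix")
  profile <- check_dist_matrix(profile, "profile distance matrix")
  if (!setequal(rownames(phylo), rownames(profile))) {
    stop_data("distance matrices label different isolates")
  }
  profile <- profile[rownames(phylo), rownames(phylo)]
  n <- nrow(phylo)
  if (n < 4) stop_data("need >= 4 isolates for a distance association")
  ut <- upper.tri(phylo)
  x <- phylo[ut]; y <- profile[ut]
  fit <- stats::lm.fit(cbind(1, x), y)
  rho_obs <- stats::cor(x, y, method = "spearman")
  perm_rho <- local_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      stats::cor(x, profile[idx, idx][ut], method = "spearman")
    }, numeric(1))
  })
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       rho = rho_obs,
       p_mantel = (sum(perm_rho >= rho_obs) + 1) / (n_perm + 1),
       n_pairs = sum(ut), n_perm = n_perm)
}

#' Pairwise Spearman correlations between utilization profiles
#'
#' Spearman rank correlation (midranks for ties) between every pair of
#' isolate fold-change profiles, with Bonferroni adjustment of the
#' p-values over the number of pairs (`p_adj = min(1, p * n_pairs)`).
#' Pairs with fewer than 4 shared metabolites, or involving a constant
#' profile, are masked (NA).
#'
#' @param fc metabolite x isolate matrix
#' @return list of symmetric matrices `rho`, `p`, `p_adj`, and `n_pairs`
#' @export
pairwise_profile_correlations <- function(fc) {
  stopifnot(is.matrix(fc), ncol(fc) >= 2)
  n <- ncol(fc)
  labs <- colnames(fc)
  rho <- p <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  diag(rho) <- 1; diag(p) <- 0
  n_pairs <- n * (n - 1) / 2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- is.finite(fc[, i]) & is.finite(fc[, j])
      if (sum(ok) < 4) next
      xi <- fc[ok, i]; yj <- fc[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(yj) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(xi, yj, method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  p_adj <- pmin(p * n_pairs, 1)
  diag(p_adj) <- 0
  list(rho = rho, p = p, p_adj = p_adj, n_pairs = n_pairs)
}

#' Within-group versus between-group profile similarity
#'
#' Tests whether isolates sharing a taxonomic group (e.g. family) have
#' more similar utilization profiles than isolates from different groups:
#' pairwise Spearman correlations are split into within-group and
#' between-group sets and compared with a one-sided rank-sum test
#' (within > between, normal approximation).
#'
#' @param fc metabolite x isolate fold-change matrix
#' @param groups named character vector, isolate -> group label, covering
#'   all columns of `fc`; at least 2 groups and 1 within-group pair
#' @return list: `statistic` (z), `p.value`, `n_within`, `n_between`,
#'   `mean_within`, `mean_between`
#' @export
group_conservatism_test <- function(fc, groups) {
  stopifnot(is.matrix(fc))
  labs <- colnames(fc)
  if (!all(labs %in% names(groups))) {
    stop_data("group label missing for isolate(s): ",
              paste(setdiff(labs, names(groups)), collapse = ", "))
  }
  g <- groups[labs]
  if (length(unique(g)) < 2) {
    stop_data("need >= 2 groups to compare within vs between")
  }
  rho <- pairwise_profile_correlations(fc)$rho
  ut <- upper.tri(rho)
  same <- outer(g, g, `==`)[ut]
  vals <- rho[ut]
  keep <- is.finite(vals)
  within <- vals[keep & same]
  between <- vals[keep & !same]
  if (!length(within)) stop_data("no within-group pair with a defined rho")
  res <- ranksum_test(within, between, method = "normal",
                      alternative = "greater")
  list(statistic = res$statistic, p.value = res$p.value,
       n_within = length(within), n_between = length(between),
       mean_within = mean(within), mean_between = mean(between))
}

#' Cophenetic distances from a profile dendrogram
#'
#' Alternative y-axis for distance-association analyses: instead of raw
#' Euclidean profile distances, the cophenetic distances implied by the
#' Bray-Curtis dendrogram of [cluster_profiles()].
#'
#' @param clustering result of [cluster_profiles()]
#' @return symmetric distance matrix
#' @export
cophenetic_profile_distances <- function(clustering) {
  as.matrix(stats::cophenetic(clustering$hclust))
}
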