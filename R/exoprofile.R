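## Targeted LC-MS peak-table processing: blank handling, normalisation to
## the uninoculated-control maximum, log2 fold-changes, rank-sum
## depletion/production calls, and Bray-Curtis clustering of utilization
## profiles.

SAMPLE_ROLES <- c("culture", "uninoculated_control", "extraction_blank")

#' Construct a peak table
#'
#' A peak table couples a non-negative feature-by-sample abundance matrix
#' (peak heights or areas) with sample annotations. Every sample must be
#' annotated with a role; culture samples carry an isolate label and
#' replicate index.
#'
#' @param mat numeric matrix, metabolites in rows (rownames = metabolite
#'   ids), samples in columns (colnames = sample ids), all entries >= 0
#' @param samples data.frame with columns `sample_id`, `role` (one of
#'   `"culture"`, `"uninoculated_control"`, `"extraction_blank"`),
#'   `isolate`, `replicate`; one row per column of `mat`
#' @param quant_type per-feature quantitation type, `"height"` or
#'   `"area"`, recycled; carried through all downstream tables
#' @return object of class `peak_table`
#' @export
peak_table <- function(mat, samples, quant_type = "height") {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_data("peak matrix must have metabolite rownames and sample colnames")
  }
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop_data("peak abundances must be finite and >= 0")
  }
  need <- c("sample_id", "role", "isolate", "replicate")
  if (!all(need %in% names(samples))) {
    stop_data("sample annotation lacks column(s): ",
              paste(setdiff(need, names(samples)), collapse = ", "))
  }
  if (!setequal(samples$sample_id, colnames(mat)) ||
      anyDuplicated(samples$sample_id)) {
    stop_data("sample annotation must match matrix columns one-to-one")
  }
  bad <- setdiff(unique(samples$role), SAMPLE_ROLES)
  if (length(bad)) {
    stop_data("unknown sample role(s): ", paste(bad, collapse = ", "))
  }
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(mat = mat, samples = samples,
                 quant_type = rep_len(quant_type, nrow(mat)),
                 normalized = FALSE,
                 masked = stats::setNames(rep(FALSE, nrow(mat)),
                                          rownames(mat))),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x$mat), " metabolites x ", ncol(x$mat),
      " samples (", sum(x$samples$role == "culture"), " culture, ",
      sum(x$samples$role == "uninoculated_control"), " control, ",
      sum(x$samples$role == "extraction_blank"), " blank)",
      if (x$normalized) "; normalized (% of control max)", "\n", sep = "")
  invisible(x)
}

cols_of_role <- function(pt, role) which(pt$samples$role == role)

#' Subtract extraction-blank background
#'
#' The per-metabolite mean abundance over extraction-blank samples is
#' subtracted from every non-blank sample; negative results are clipped to
#' zero and the blank samples are dropped from the output. A table without
#' blanks is returned unchanged with a warning.
#'
#' @param pt a `peak_table`
#' @return `peak_table` without extraction-blank samples
#' @export
blank_subtract <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  blanks <- cols_of_role(pt, "extraction_blank")
  if (!length(blanks)) {
    warning("no extraction-blank samples; table returned unchanged",
            call. = FALSE)
    return(pt)
  }
  bg <- rowMeans(pt$mat[, blanks, drop = FALSE])
  keep <- setdiff(seq_len(ncol(pt$mat)), blanks)
  mat <- pmax(pt$mat[, keep, drop = FALSE] - bg, 0)
  peak_table(mat, pt$samples[keep, , drop = FALSE], pt$quant_type)
}

#' Remove features not well above blank background
#'
#' Keeps a feature only when its maximum non-blank abundance is at least
#' `ratio` times its maximum extraction-blank abundance (boundary counts
#' as kept). Features with zero blank signal are always kept. Removed
#' feature ids are attached as attribute `"removed"`.
#'
#' @param pt a `peak_table` containing blank samples
#' @param ratio required sample/blank ratio (default 10)
#' @return filtered `peak_table`
#' @export
blank_ratio_filter <- function(pt, ratio = 10) {
  stopifnot(inherits(pt, "peak_table"), ratio > 0)
  blanks <- cols_of_role(pt, "extraction_blank")
  if (!length(blanks)) return(structure(pt, removed = character(0)))
  other <- setdiff(seq_len(ncol(pt$mat)), blanks)
  blank_max <- apply(pt$mat[, blanks, drop = FALSE], 1, max)
  samp_max <- apply(pt$mat[, other, drop = FALSE], 1, max)
  keep <- blank_max == 0 | samp_max >= ratio * blank_max
  out <- peak_table(pt$mat[keep, , drop = FALSE], pt$samples,
                    pt$quant_type[keep])
  attr(out, "removed") <- rownames(pt$mat)[!keep]
  out
}

#' Normalize each feature to the uninoculated-control maximum
#'
#' Each feature row is scaled so that the maximum abundance observed in
#' uninoculated-control samples equals 100 exactly; values are then
#' percent-of-control-max. Features whose control maximum is zero cannot
#' be normalized this way: their rows are set to NA and flagged in the
#' `masked` field rather than silently dropped. Normalisation is a fixed
#' point: applying it twice equals applying it once.
#'
#' @param pt a `peak_table` with at least one uninoculated-control sample
#' @return normalized `peak_table` (`normalized = TRUE`)
#' @export
normalize_peaks <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  ctrl <- cols_of_role(pt, "uninoculated_control")
  if (!length(ctrl)) stop_data("no uninoculated-control samples to normalize to")
  cmax <- apply(pt$mat[, ctrl, drop = FALSE], 1, max)
  masked <- !is.finite(cmax) | cmax <= 0
  masked <- masked | pt$masked  # re-normalising keeps earlier masks
  mat <- pt$mat
  mat[!masked, ] <- mat[!masked, , drop = FALSE] / cmax[!masked] * 100
  mat[masked, ] <- NA_real_
  out <- pt
  out$mat <- mat
  out$normalized <- TRUE
  out$masked <- stats::setNames(masked, rownames(mat))
  out
}

#' Per-isolate and control mean abundances
#'
#' Replicate means of a (typically normalized) peak table: the
#' metabolite x isolate matrix of culture-replicate means — the input
#' [cluster_profiles()] expects — and the per-metabolite mean over
#' uninoculated-control samples.
#'
#' @param pt a `peak_table`
#' @return list with elements `isolate` (matrix) and `control` (vector)
#' @export
profile_means <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  ctrl <- cols_of_role(pt, "uninoculated_control")
  cult <- cols_of_role(pt, "culture")
  if (!length(ctrl)) stop_data("no uninoculated-control samples")
  if (!length(cult)) stop_data("no culture samples")
  isolates <- unique(pt$samples$isolate[cult])
  iso_mean <- vapply(isolates, function(iso) {
    cols <- cult[pt$samples$isolate[cult] == iso]
    rowMeans(pt$mat[, cols, drop = FALSE])
  }, numeric(nrow(pt$mat)))
  if (is.null(dim(iso_mean))) {
    iso_mean <- matrix(iso_mean, ncol = length(isolates),
                       dimnames = list(rownames(pt$mat), isolates))
  } else {
    colnames(iso_mean) <- isolates
  }
  list(isolate = iso_mean,
       control = rowMeans(pt$mat[, ctrl, drop = FALSE]))
}

#' Log2 fold-change matrix versus the uninoculated control
#'
#' For each metabolite and isolate, `log2(mean over isolate replicates /
#' mean over control samples)` of normalized abundances. Before taking
#' logs, both means are floored at `floor` (default: half the smallest
#' non-zero normalized value in the table) so that complete depletions
#' yield large negative but finite fold-changes. Metabolites masked
#' during normalisation propagate as NA and are reported in the
#' `"masked"` attribute.
#'
#' @param pt a normalized `peak_table` (see [normalize_peaks()])
#' @param floor positive abundance floor; NULL for the default rule
#' @return metabolite x isolate numeric matrix with attributes `"masked"`
#'   (logical vector) and `"floor"`
#' @export
fold_change <- function(pt, floor = NULL) {
  stopifnot(inherits(pt, "peak_table"))
  if (!pt$normalized) stop_data("fold_change expects a normalized table")
  mm <- profile_means(pt)
  if (is.null(floor)) {
    nz <- pt$mat[is.finite(pt$mat) & pt$mat > 0]
    floor <- if (length(nz)) min(nz) / 2 else 0.5
  }
  stopifnot(floor > 0)
  fc <- log2(pmax(mm$isolate, floor) / pmax(mm$control, floor))
  fc[pt$masked, ] <- NA_real_
  attr(fc, "masked") <- pt$masked
  attr(fc, "floor") <- floor
  fc
}

#' Two-sample Wilcoxon rank-sum test, normal approximation or exact
#'
#' The `"normal"` method uses the large-sample normal approximation
#' without continuity correction and without a tie correction to the
#' variance: `z = (R1 - n1 (N+1)/2) / sqrt(n1 n2 (N+1) / 12)` with `R1`
#' the midrank sum of `x`, two-sided `p = 2 * pnorm(-|z|)`. This is the
#' flavour used throughout the depletion calls. It matters at small n:
#' for complete separation of two triplicates the approximation yields
#' p ~ 0.0495 while the exact permutation distribution (method
#' `"exact"`, full enumeration of rank assignments) can go no lower than
#' p = 0.10 at n = 3 vs 3 — so triplicate depletion calls at alpha = 0.05
#' are only reachable with the approximation.
#'
#' @param x,y numeric vectors (>= 2 values each for a meaningful test)
#' @param method `"normal"` or `"exact"` (exact requires untied data and
#'   small samples; enumeration is over `choose(n1+n2, n1)` assignments)
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`
#' @return list with `statistic` (z for normal, rank sum for exact) and
#'   `p.value`
#' @export
ranksum_test <- function(x, y, method = c("normal", "exact"),
                         alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop_data("both samples must be non-empty")
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  if (method == "normal") {
    mu <- n1 * (N + 1) / 2
    sd <- sqrt(n1 * n2 * (N + 1) / 12)
    z <- if (sd > 0) (r1 - mu) / sd else 0
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    list(statistic = z, p.value = min(p, 1))
  } else {
    if (anyDuplicated(c(x, y))) {
      stop_data("exact rank-sum enumeration requires untied data")
    }
    if (choose(N, n1) > 1e6) stop_data("samples too large for enumeration")
    sums <- utils::combn(N, n1, FUN = sum)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(mean(sums <= r1),
                                           mean(sums >= r1))),
                greater = mean(sums >= r1),
                less = mean(sums <= r1))
    list(statistic = r1, p.value = p)
  }
}

#' Depletion / production calls by rank-sum test
#'
#' Each metabolite-isolate pair is tested by comparing the isolate's
#' replicate normalized abundances against the uninoculated-control
#' samples with the normal-approximation rank-sum test (see
#' [ranksum_test()]; no multiple-testing correction, matching the
#' raw-alpha convention of targeted exometabolite panels — pass the
#' p-matrix to [stats::p.adjust()] if adjusted calls are wanted). A pair
#' is called `depleted` when p < alpha and its log2 fold-change is
#' negative, `produced` when p < alpha and the fold-change is positive,
#' otherwise `unchanged`. Pairs with fewer than 2 replicates on either
#' side, or metabolites masked during normalisation, are masked (NA).
#'
#' @param pt a normalized `peak_table`
#' @param alpha significance level for the raw p-value (default 0.05)
#' @param fc optional precomputed [fold_change()] matrix
#' @return object of class `utilization_calls`: list with matrices
#'   `call` (character), `p`, `statistic`, `fold_change`, and `alpha`
#' @export
depletion_test <- function(pt, alpha = 0.05, fc = NULL) {
  stopifnot(inherits(pt, "peak_table"), alpha > 0, alpha < 1)
  if (!pt$normalized) stop_data("depletion_test expects a normalized table")
  if (is.null(fc)) fc <- fold_change(pt)
  ctrl <- cols_of_role(pt, "uninoculated_control")
  cult <- cols_of_role(pt, "culture")
  isolates <- colnames(fc)
  mets <- rownames(pt$mat)
  p <- stat <- matrix(NA_real_, length(mets), length(isolates),
                      dimnames = list(mets, isolates))
  call <- matrix(NA_character_, length(mets), length(isolates),
                 dimnames = list(mets, isolates))
  for (iso in isolates) {
    cols <- cult[pt$samples$isolate[cult] == iso]
    for (m in seq_along(mets)) {
      if (pt$masked[m]) next
      xv <- pt$mat[m, cols]
      yv <- pt$mat[m, ctrl]
      if (sum(is.finite(xv)) < 2 || sum(is.finite(yv)) < 2) next
      res <- ranksum_test(xv, yv, method = "normal")
      p[m, iso] <- res$p.value
      stat[m, iso] <- res$statistic
      f <- fc[m, iso]
      call[m, iso] <- if (is.na(f) || res$p.value >= alpha || f == 0) {
        "unchanged"
      } else if (f < 0) "depleted" else "produced"
    }
  }
  structure(list(call = call, p = p, statistic = stat, fold_change = fc,
                 alpha = alpha),
            class = "utilization_calls")
}

#' @export
print.utilization_calls <- function(x, ...) {
  tab <- table(factor(x$call, levels = c("depleted", "produced",
                                         "unchanged")))
  cat("<utilization_calls> ", nrow(x$call), " metabolites x ",
      ncol(x$call), " isolates at alpha=", x$alpha, "\n  depleted ",
      tab[["depleted"]], ", produced ", tab[["produced"]], ", unchanged ",
      tab[["unchanged"]], ", masked ", sum(is.na(x$call)), "\n", sep = "")
  invisible(x)
}

#' Count significant calls per isolate
#'
#' @param calls a `utilization_calls` object
#' @param direction `"depleted"`, `"produced"` or `"unchanged"`
#' @return named integer vector, one entry per isolate
#' @export
count_significant <- function(calls,
                              direction = c("depleted", "produced",
                                            "unchanged")) {
  direction <- match.arg(direction)
  stopifnot(inherits(calls, "utilization_calls"))
  apply(calls$call, 2, function(col) sum(col == direction, na.rm = TRUE))
}

#' Bray-Curtis hierarchical clustering of utilization profiles
#'
#' Computes the Bray-Curtis dissimilarity between isolate profiles and
#' clusters them agglomeratively. Bray-Curtis requires non-negative
#' input, so clustering operates on per-isolate mean normalized
#' abundances (0-100 scale), never on log2 fold-changes; passing a matrix
#' with negative entries is an error pointing at the normalized input.
#'
#' @param mat metabolite x isolate matrix of non-negative mean normalized
#'   abundances (e.g. `profile_means(pt)$isolate`); rows with NA are
#'   dropped
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`, i.e. UPGMA)
#' @return list with `dissimilarity` (symmetric isolate matrix in [0,1]),
#'   `hclust`, `order` (leaf labels left to right) and `newick`
#' @export
cluster_profiles <- function(mat, linkage = "average") {
  stopifnot(is.matrix(mat))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (any(mat < 0)) {
    stop_data("Bray-Curtis dissimilarity requires non-negative input; ",
              "cluster mean normalized abundances, not log2 fold-changes")
  }
  if (ncol(mat) < 2) stop_data("need >= 2 profiles to cluster")
  d <- vegan::vegdist(t(mat), method = "bray")
  hc <- stats::hclust(d, method = linkage)
  dm <- as.matrix(d)
  list(dissimilarity = dm, hclust = hc,
       order = hc$labels[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Read / write peak tables as TSV
#'
#' The peak TSV holds one metabolite per row: first column `metabolite`,
#' optional `quant_type` column, remaining columns one per sample. The
#' sample annotation TSV has columns `sample_id`, `role`, `isolate`,
#' `replicate`.
#'
#' @param peaks_tsv,samples_tsv file paths
#' @return a `peak_table`
#' @export
read_peak_table <- function(peaks_tsv, samples_tsv) {
  peaks <- read_tsv(peaks_tsv)
  if (names(peaks)[1] != "metabolite") {
    stop_data("first column of the peak table must be 'metabolite'")
  }
  samples <- read_tsv(samples_tsv)
  qt <- if ("quant_type" %in% names(peaks)) peaks$quant_type else "height"
  value_cols <- setdiff(names(peaks), c("metabolite", "quant_type"))
  mat <- as.matrix(peaks[, value_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(peaks[value_cols], is.numeric, logical(1)))[1]
    rowi <- which(is.na(suppressWarnings(
      as.numeric(peaks[[value_cols[bad]]]))))[1]
    stop_data("non-numeric abundance in column '", value_cols[bad],
              "', row ", rowi %||% "?")
  }
  rownames(mat) <- peaks$metabolite
  peak_table(mat, samples, qt)
}

#' @rdname read_peak_table
#' @param pt a `peak_table`
#' @param path output path
#' @export
write_peak_table <- function(pt, path) {
  df <- data.frame(metabolite = rownames(pt$mat),
                   quant_type = pt$quant_type,
                   pt$mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
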