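make_table <- function(mat, roles, isolates = NULL) {
  ids <- sprintf("s%02d", seq_len(ncol(mat)))
  colnames(mat) <- ids
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("m%d", seq_len(nrow(mat)))
  }
  samples <- data.frame(
    sample_id = ids, role = roles,
    isolate = isolates %||% ifelse(roles == "culture", "iso_a", NA),
    replicate = seq_len(ncol(mat)), stringsAsFactors = FALSE)
  peak_table(mat, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("blank subtraction clips at zero and drops blank samples", {
  mat <- rbind(m1 = c(250, 250, 100), m2 = c(250, 250, 300))
  pt <- make_table(mat, c("culture", "uninoculated_control",
                          "extraction_blank"))
  out <- blank_subtract(pt)
  expect_equal(unname(out$mat["m1", ]), c(150, 150))
  expect_equal(unname(out$mat["m2", ]), c(0, 0))
  expect_false(any(out$samples$role == "extraction_blank"))
  # no blanks: identity with warning
  noblank <- make_table(mat[, 1:2], c("culture", "uninoculated_control"))
  expect_warning(same <- blank_subtract(noblank), "no extraction-blank")
  expect_equal(same$mat, noblank$mat)
})

test_that("blank-ratio filter keeps the boundary and zero-blank features", {
  mat <- rbind(removed = c(900, 900, 100),
               boundary = c(1000, 900, 100),
               zeroblank = c(5, 5, 0))
  pt <- make_table(mat, c("culture", "uninoculated_control",
                          "extraction_blank"))
  out <- blank_ratio_filter(pt, ratio = 10)
  expect_setequal(rownames(out$mat), c("boundary", "zeroblank"))
  expect_equal(attr(out, "removed"), "removed")
})

test_that("normalisation pins the control max at exactly 100", {
  mat <- rbind(m1 = c(500, 1500, 2000, 1800),
               allzero = c(3, 0, 0, 0))
  pt <- make_table(mat, c("culture", rep("uninoculated_control", 3)))
  norm <- normalize_peaks(pt)
  expect_equal(unname(norm$mat["m1", ]), c(25, 75, 100, 90))
  expect_true(norm$masked[["allzero"]])
  expect_true(all(is.na(norm$mat["allzero", ])))
  ctrl <- norm$samples$role == "uninoculated_control"
  expect_equal(max(norm$mat["m1", ctrl]), 100)
  expect_error(normalize_peaks(make_table(mat[, 1, drop = FALSE],
                                          "culture")),
               "no uninoculated-control")
})

test_that("normalisation is a fixed point and scale invariant", {
  for (seed in 1:100) {
    pt <- random_peak_table(n_met = 5, n_iso = 2, seed = seed)
    norm1 <- normalize_peaks(pt)
    norm2 <- normalize_peaks(norm1)
    expect_equal(norm2$mat, norm1$mat, tolerance = 1e-12)
    # scaling a raw feature row leaves its normalized row unchanged
    scaled <- pt
    c_mult <- withr::with_seed(seed, runif(1, 0.01, 100))
    scaled$mat[3, ] <- scaled$mat[3, ] * c_mult
    expect_equal(normalize_peaks(scaled)$mat, norm1$mat,
                 tolerance = 1e-9)
  }
  # ... and therefore fold-changes and calls are scale invariant too
  pt <- random_peak_table(n_met = 6, n_iso = 3, seed = 7)
  scaled <- pt
  scaled$mat <- pt$mat * matrix(c(0.5, 10, 1, 3, 0.01, 7),
                                nrow(pt$mat), ncol(pt$mat))
  n1 <- normalize_peaks(pt); n2 <- normalize_peaks(scaled)
  expect_equal(fold_change(n2, floor = 0.01), fold_change(n1, floor = 0.01),
               tolerance = 1e-9)
  c1 <- depletion_test(n1, fc = fold_change(n1, floor = 0.01))
  c2 <- depletion_test(n2, fc = fold_change(n2, floor = 0.01))
  expect_equal(c1$call, c2$call)
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
})

test_that("fold changes are log2 mean ratios with a floor for zeros", {
  mat <- rbind(m1 = c(25, 25, 25, 100, 100, 100),
               m2 = c(100, 100, 100, 100, 100, 100),
               m3 = c(0, 0, 0, 100, 100, 100))
  pt <- make_table(mat, c(rep("culture", 3),
                          rep("uninoculated_control", 3)))
  norm <- normalize_peaks(pt)
  fc <- fold_change(norm, floor = 2)
  expect_equal(fc["m1", "iso_a"], -2)
  expect_equal(fc["m2", "iso_a"], 0)
  expect_equal(fc["m3", "iso_a"], log2(2 / 100))
  expect_equal(attr(fc, "floor"), 2)
})

test_that("the rank-sum normal approximation reproduces small-n calls", {
  # complete separation at n = 3 vs 3
  res <- ranksum_test(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$statistic, -4.5 / sqrt(5.25), tolerance = 1e-12)
  expect_equal(res$p.value, 0.04953461, tolerance = 1e-6)
  expect_lt(res$p.value, 0.05)
  # the exact enumeration cannot go below 0.10 at 3 vs 3
  exact <- ranksum_test(c(1, 2, 3), c(10, 20, 30), method = "exact")
  expect_equal(exact$p.value, 0.10, tolerance = 1e-12)
  # identical values on both sides: midranks give p = 1
  tie <- ranksum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tie$p.value, 1)
  # sign flips with direction
  up <- ranksum_test(c(10, 20, 30), c(1, 2, 3))
  expect_equal(up$statistic, -res$statistic)
  # agrees with the uncorrected large-sample Wilcoxon on untied data
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rnorm(6); y <- rnorm(8)
      mine <- ranksum_test(x, y)$p.value
      ref <- stats::wilcox.test(x, y, exact = FALSE,
                                correct = FALSE)$p.value
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  })
})

test_that("depletion calls partition and respect fold-change signs", {
  pt <- make_toy_table()
  norm <- normalize_peaks(pt)
  calls <- depletion_test(norm)
  expect_equal(unname(calls$call["m_dep", "iso_a"]), "depleted")
  expect_equal(unname(calls$call["m_prod", "iso_a"]), "produced")
  expect_equal(unname(calls$call["m_flat", "iso_a"]), "unchanged")
  # counts partition the unmasked metabolites
  total <- count_significant(calls, "depleted") +
    count_significant(calls, "produced") +
    count_significant(calls, "unchanged")
  expect_equal(unname(total), sum(!is.na(calls$call[, "iso_a"])))
  # every significant call has the matching fold-change sign
  for (seed in 1:25) {
    ptr <- random_peak_table(n_met = 10, n_iso = 2, seed = seed)
    cl <- depletion_test(normalize_peaks(ptr))
    dep <- which(cl$call == "depleted")
    pro <- which(cl$call == "produced")
    expect_true(all(cl$fold_change[dep] < 0))
    expect_true(all(cl$fold_change[pro] > 0))
    expect_true(all(cl$p[dep] < cl$alpha, cl$p[pro] < cl$alpha))
  }
})

test_that("Bray-Curtis clustering is bounded, symmetric and sensible", {
  # identical profiles at distance 0; disjoint support at distance 1
  prof <- cbind(a = c(10, 0, 5, 0), b = c(10, 0, 5, 0),
                c = c(0, 7, 0, 3))
  rownames(prof) <- sprintf("m%d", 1:4)
  cl <- cluster_profiles(prof)
  expect_equal(cl$dissimilarity["a", "b"], 0)
  expect_equal(cl$dissimilarity["a", "c"], 1)
  # two tight pairs join before the pairs join each other
  pairs <- cbind(a1 = c(100, 90, 1), a2 = c(98, 92, 2),
                 b1 = c(2, 5, 100), b2 = c(1, 6, 97))
  rownames(pairs) <- sprintf("m%d", 1:3)
  hc <- cluster_profiles(pairs)$hclust
  first_two <- sort(abs(hc$merge[1:2, ]))
  expect_setequal(hc$labels[first_two], c("a1", "a2", "b1", "b2"))
  # negative input is rejected with guidance
  neg <- pairs; neg[1, 1] <- -1
  expect_error(cluster_profiles(neg), "non-negative")
  # bounds/symmetry/zero diagonal on random non-negative profiles
  for (seed in 1:100) {
    m <- withr::with_seed(seed,
      matrix(rexp(30), 6, 5,
             dimnames = list(sprintf("m%d", 1:6), sprintf("i%d", 1:5))))
    d <- cluster_profiles(m)$dissimilarity
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_equal(unname(diag(d)), rep(0, 5))
  }
})

test_that("peak tables round-trip through TSV", {
  pt <- random_peak_table(seed = 3)
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(pt, pf)
  sf <- withr::local_tempfile(fileext = ".tsv")
  exometab:::write_tsv(pt$samples, sf)
  back <- read_peak_table(pf, sf)
  expect_equal(back$mat, pt$mat)
  expect_equal(back$samples$role, pt$samples$role)
  # corrupted numeric cell is reported with its location
  lines <- readLines(pf)
  lines[3] <- sub("\t[0-9.]+$", "\tnot_a_number", lines[3])
  writeLines(lines, pf)
  expect_error(read_peak_table(pf, sf), "non-numeric")
})
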