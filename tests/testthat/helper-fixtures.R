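## Shared builders and independent oracles for the test suite.

## Small peak table with known structure: `depleted` metabolites are far
## below control in every culture replicate, `produced` far above.
make_toy_table <- function(n_ctrl = 3, n_rep = 3, seed = 101) {
  withr::with_seed(seed, {
    mets <- c("m_dep", "m_prod", "m_flat")
    mat <- rbind(
      m_dep = c(runif(n_rep, 10, 20), runif(n_ctrl, 900, 1100)),
      m_prod = c(runif(n_rep, 5000, 6000), runif(n_ctrl, 900, 1100)),
      m_flat = c(runif(n_rep, 900, 1100), runif(n_ctrl, 900, 1100)))
    ids <- c(sprintf("iso_a_rep%d", seq_len(n_rep)),
             sprintf("ctrl_%d", seq_len(n_ctrl)))
    colnames(mat) <- ids
    samples <- data.frame(
      sample_id = ids,
      role = c(rep("culture", n_rep), rep("uninoculated_control", n_ctrl)),
      isolate = c(rep("iso_a", n_rep), rep(NA, n_ctrl)),
      replicate = c(seq_len(n_rep), seq_len(n_ctrl)),
      stringsAsFactors = FALSE)
    peak_table(mat, samples)
  })
}

## Random non-negative peak table over several isolates.
random_peak_table <- function(n_met = 8, n_iso = 3, n_rep = 3,
                              n_ctrl = 4, seed = 1) {
  withr::with_seed(seed, {
    ids <- c(unlist(lapply(seq_len(n_iso), function(i)
      sprintf("iso_%d_rep%d", i, seq_len(n_rep)))),
      sprintf("ctrl_%d", seq_len(n_ctrl)))
    mat <- matrix(rlnorm(n_met * length(ids), 6, 1), n_met,
                  dimnames = list(sprintf("met_%d", seq_len(n_met)), ids))
    samples <- data.frame(
      sample_id = ids,
      role = c(rep("culture", n_iso * n_rep),
               rep("uninoculated_control", n_ctrl)),
      isolate = c(rep(sprintf("iso_%d", seq_len(n_iso)), each = n_rep),
                  rep(NA, n_ctrl)),
      replicate = c(rep(seq_len(n_rep), n_iso), seq_len(n_ctrl)),
      stringsAsFactors = FALSE)
    peak_table(mat, samples)
  })
}

## Random element tally drawn from the bundled weight table.
random_tally <- function(seed) {
  withr::with_seed(seed, {
    els <- sample(names(exometab::atomic_weights),
                  sample(1:6, 1))
    stats::setNames(sample.int(30, length(els), replace = TRUE), els)
  })
}

## Independent Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## Independent patristic-distance oracle: brute-force path enumeration
## over the tree's adjacency graph.
patristic_oracle <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  ntip <- length(tree$tip.label)
  out <- matrix(0, ntip, ntip,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (start in seq_len(ntip)) {
    dist <- rep(NA_real_, n_nodes)
    dist[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      for (k in seq_len(NROW(nb))) {
        w <- nb[k, 1]
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + nb[k, 2]
          queue <- c(queue, w)
        }
      }
    }
    out[start, ] <- dist[seq_len(ntip)]
  }
  out
}
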