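## Seeded synthetic-data generators: Yule trees, Brownian-motion
## utilization traits with known ground truth, replicate LC-MS peak
## tables, and logistic growth curves. Every generator takes an explicit
## seed and leaves global RNG state untouched, so identical inputs give
## byte-identical outputs.

#' Simulation configuration
#'
#' Default dimensions mirror a typical targeted exometabolite screen:
#' 30 isolates x 64 metabolites, triplicate cultures, 18 uninoculated
#' control samples across batches, 3 extraction blanks. The default
#' sigma_phylo / sigma_noise ratio of 5 encodes a strongly
#' phylogenetically conserved utilization signal; set `sigma_phylo = 0`
#' for a null (no-signal) dataset.
#'
#' @param n_isolates number of isolates (tree leaves), >= 2
#' @param n_metabolites number of metabolite features
#' @param birth_rate Yule speciation rate (per unit branch length)
#' @param sigma_phylo Brownian-motion rate: trait variance accrues as
#'   `sigma_phylo^2 * branch length`
#' @param sigma_noise sd of independent per-isolate trait jitter
#' @param replicates culture replicates per isolate, >= 2
#' @param n_controls number of uninoculated-control samples
#' @param n_blanks number of extraction-blank samples
#' @param abundance_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise on peak abundances
#' @param blank_fraction extraction-blank background as a fraction of the
#'   control abundance
#' @param production_prob probability that an isolate-metabolite cell is
#'   a production (secretion) event instead of a depletion
#' @param production_fold abundance multiplier for production cells, > 1
#' @param seed mandatory integer seed
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_isolates = 30, n_metabolites = 64,
                       birth_rate = 1, sigma_phylo = 1, sigma_noise = 0.2,
                       replicates = 3, n_controls = 18, n_blanks = 3,
                       abundance_cv = 0.2, blank_fraction = 0.05,
                       production_prob = 0.02, production_fold = 3,
                       seed) {
  if (missing(seed)) stop_data("a seed is mandatory for simulation configs")
  stopifnot(n_isolates >= 2, n_metabolites >= 1, birth_rate > 0,
            sigma_phylo >= 0, sigma_noise >= 0, replicates >= 2,
            n_controls >= 1, n_blanks >= 0, abundance_cv >= 0,
            blank_fraction >= 0, production_prob >= 0,
            production_prob <= 1, production_fold > 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: starting from two lineages, each of k concurrent
#' lineages splits after an exponential waiting time with total rate
#' `k * birth_rate`; the lineage that splits is chosen uniformly. After
#' the n-th lineage appears one further exponential waiting time is added
#' so pendant branches are positive; the tree is ultrametric. Leaves are
#' labelled `iso_1 ... iso_n`.
#'
#' @param n number of leaves, >= 2
#' @param birth_rate speciation rate, > 0
#' @param seed integer seed
#' @return an [ape] `phylo` object
#' @export
simulate_tree <- function(n, birth_rate = 1, seed) {
  stopifnot(n >= 2, birth_rate > 0)
  local_seed(seed, {
    ## each active lineage: birth time + a slot in a grow-as-you-go node
    ## store; internal nodes remember (children, birth, death)
    nodes <- list()
    new_node <- function(birth) {
      nodes[[length(nodes) + 1]] <<- list(birth = birth, children = NULL,
                                          death = NA_real_)
      length(nodes)
    }
    active <- c(new_node(0), new_node(0))
    t_now <- 0
    while (length(active) < n) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
      who <- active[sample.int(k, 1)]
      kid1 <- new_node(t_now); kid2 <- new_node(t_now)
      nodes[[who]]$children <- c(kid1, kid2)
      nodes[[who]]$death <- t_now
      active <- c(setdiff(active, who), kid1, kid2)
    }
    t_end <- t_now + stats::rexp(1, rate = n * birth_rate)
    tip_counter <- 0L
    serialize <- function(i) {
      nd <- nodes[[i]]
      if (is.null(nd$children)) {
        tip_counter <<- tip_counter + 1L
        paste0("iso_", tip_counter, ":", format(t_end - nd$birth,
                                                digits = 15))
      } else {
        paste0("(", serialize(nd$children[1]), ",",
               serialize(nd$children[2]), "):",
               format(nd$death - nd$birth, digits = 15))
      }
    }
    nwk <- paste0("(", serialize(1), ",", serialize(2), ");")
    ape::read.tree(text = nwk)
  })
}

#' Simulate phylogenetically structured utilization ground truth
#'
#' For each metabolite a latent trait evolves along the tree by Brownian
#' motion (root value `root_trait`; per-edge increment
#' `Normal(0, sigma_phylo^2 * length)`), each leaf trait receives
#' independent `Normal(0, sigma_noise^2)` jitter, and the result is mapped
#' through the logistic function to a depletion fraction in (0, 1).
#' With probability `production_prob` an isolate-metabolite cell is
#' instead flagged as a production event with multiplier
#' `production_fold`.
#'
#' @param tree a `phylo` object
#' @param sigma_phylo,sigma_noise Brownian rate and jitter sd, >= 0
#' @param n_metabolites number of metabolite traits to simulate
#' @param production_prob,production_fold see [sim_config()]
#' @param root_trait trait value at the root (0 gives a baseline
#'   depletion fraction of 0.5)
#' @param seed integer seed
#' @return list of class `ground_truth`: `tree`, `trait` (leaf trait
#'   matrix, isolate x metabolite), `depletion` (fractions in (0,1)),
#'   `production` (logical mask), `production_fold`
#' @export
simulate_profiles <- function(tree, sigma_phylo = 1, sigma_noise = 0.2,
                              n_metabolites = 64, production_prob = 0,
                              production_fold = 3, root_trait = 0, seed) {
  stopifnot(inherits(tree, "phylo"), sigma_phylo >= 0, sigma_noise >= 0)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  local_seed(seed, {
    trait <- matrix(NA_real_, nnode, n_metabolites)
    root <- ntip + 1L
    trait[root, ] <- root_trait
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; child <- edges[e, 2]
      trait[child, ] <- trait[par, ] +
        stats::rnorm(n_metabolites, 0, sigma_phylo * sqrt(lens[e]))
    }
    leaf <- trait[seq_len(ntip), , drop = FALSE] +
      matrix(stats::rnorm(ntip * n_metabolites, 0, sigma_noise),
             ntip, n_metabolites)
    rownames(leaf) <- tree$tip.label
    colnames(leaf) <- sprintf("met_%02d", seq_len(n_metabolites))
    depl <- stats::plogis(leaf)
    prod_mask <- matrix(stats::runif(ntip * n_metabolites) < production_prob,
                        ntip, n_metabolites, dimnames = dimnames(leaf))
    structure(list(tree = tree, trait = leaf, depletion = depl,
                   production = prod_mask,
                   production_fold = production_fold),
              class = "ground_truth")
  })
}

#' Simulate a replicate peak table from ground truth
#'
#' Per metabolite a control abundance is drawn log-uniformly between
#' `10^abundance_range[1]` and `10^abundance_range[2]` (raw peak-height
#' scale). Culture replicate abundance is `control * (1 - depletion)` (or
#' `control * production_fold` for production cells) times multiplicative
#' log-normal noise with the configured CV (mean 1). Uninoculated
#' controls carry the same noise around the control abundance;
#' extraction blanks sit at `blank_fraction` of it.
#'
#' @param truth a `ground_truth` from [simulate_profiles()]
#' @param config a [sim_config()] (dimensions must agree with `truth`)
#' @param abundance_range log10 range of control abundances
#' @return a `peak_table`
#' @export
simulate_peak_table <- function(truth, config,
                                abundance_range = c(4, 7)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  isolates <- rownames(truth$depletion)
  mets <- colnames(truth$depletion)
  M <- length(mets)
  stopifnot(M == config$n_metabolites,
            length(isolates) == config$n_isolates)
  sdlog <- sqrt(log(1 + config$abundance_cv^2))
  seeds <- derive_seeds(config$seed, 2)
  local_seed(seeds[2], {
    control_abund <- 10^stats::runif(M, abundance_range[1],
                                     abundance_range[2])
    noise <- function(n) {
      if (sdlog == 0) rep(1, n)
      else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    cols <- list(); ann <- list()
    push <- function(values, id, role, isolate, rep_i) {
      cols[[length(cols) + 1]] <<- values
      ann[[length(ann) + 1]] <<- data.frame(
        sample_id = id, role = role, isolate = isolate,
        replicate = rep_i, stringsAsFactors = FALSE)
    }
    for (iso in isolates) {
      mult <- 1 - truth$depletion[iso, ]
      mult[truth$production[iso, ]] <- truth$production_fold
      for (r in seq_len(config$replicates)) {
        push(control_abund * mult * noise(M),
             sprintf("%s_rep%d", iso, r), "culture", iso, r)
      }
    }
    for (r in seq_len(config$n_controls)) {
      push(control_abund * noise(M), sprintf("ctrl_%02d", r),
           "uninoculated_control", NA_character_, r)
    }
    for (r in seq_len(config$n_blanks)) {
      push(control_abund * config$blank_fraction * noise(M),
           sprintf("blank_%02d", r), "extraction_blank", NA_character_, r)
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- mets
    annotations <- do.call(rbind, ann)
    colnames(mat) <- annotations$sample_id
    peak_table(mat, annotations)
  })
}

#' Simulate a logistic growth curve with explicit lag
#'
#' Three-phase curve: constant at `od0` for `t < lag`, then logistic
#' growth `od(t) = K od0 e^(mu (t - lag)) / (K + od0 (e^(mu (t-lag)) - 1))`
#' approaching the carrying capacity `K`, plus additive Gaussian noise.
#'
#' @param mu maximum specific growth rate per hour, > 0
#' @param lag lag phase in hours, >= 0
#' @param capacity carrying capacity K (OD600 units), > 0
#' @param noise_sd sd of additive Gaussian OD noise (0 = noiseless)
#' @param grid time grid in hours (default 0-48 h at 15 min intervals)
#' @param od0 inoculation OD
#' @param seed integer seed (only used when `noise_sd > 0`)
#' @param well,medium,isolate metadata labels
#' @return a `well_series`
#' @export
simulate_growth <- function(mu, lag = 2, capacity = 1, noise_sd = 0,
                            grid = seq(0, 48, by = 0.25), od0 = 0.02,
                            seed = 1, well = "sim", medium = "NLDM",
                            isolate = "sim") {
  stopifnot(mu > 0, capacity > 0, lag >= 0, od0 > 0, noise_sd >= 0)
  tt <- pmax(grid - lag, 0)
  e <- exp(mu * tt)
  od <- capacity * od0 * e / (capacity + od0 * (e - 1))
  if (noise_sd > 0) {
    od <- od + local_seed(seed, stats::rnorm(length(od), 0, noise_sd))
  }
  well_series(grid, od, well = well, medium = medium, isolate = isolate)
}

#' Assign family labels by cutting a tree at a depth
#'
#' Tips descending from the same lineage present at `depth * tree height`
#' below the root share a family — a simple clade-based grouping that is
#' consistent with the simulated phylogeny by construction.
#'
#' @param tree a `phylo` object
#' @param depth fraction of total tree height at which to cut, in (0, 1)
#' @return named character vector, tip label -> `fam_k`
#' @export
tree_families <- function(tree, depth = 0.5) {
  stopifnot(inherits(tree, "phylo"), depth > 0, depth < 1)
  node_depth <- ape::node.depth.edgelength(tree)
  cut_at <- depth * max(node_depth)
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  fam_of <- integer(ntip)
  for (tip in seq_len(ntip)) {
    node <- tip
    ## climb until the parent lineage originates above the cut
    while (parent[node] != 0 && node_depth[parent[node]] >= cut_at) {
      node <- parent[node]
    }
    fam_of[tip] <- node
  }
  fams <- stats::setNames(paste0("fam_", match(fam_of, unique(fam_of))),
                          tree$tip.label)
  fams
}

#' Simulate a complete exometabolite experiment
#'
#' Convenience wrapper chaining [simulate_tree()], [simulate_profiles()]
#' and [simulate_peak_table()] with seeds derived from the config seed.
#'
#' @param config a [sim_config()]
#' @return list: `tree`, `truth`, `peaks` (a `peak_table`), `families`
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 3)
  tree <- simulate_tree(config$n_isolates, config$birth_rate, seeds[1])
  truth <- simulate_profiles(
    tree, sigma_phylo = config$sigma_phylo,
    sigma_noise = config$sigma_noise,
    n_metabolites = config$n_metabolites,
    production_prob = config$production_prob,
    production_fold = config$production_fold, seed = seeds[3])
  peaks <- simulate_peak_table(truth, config)
  list(tree = tree, truth = truth, peaks = peaks,
       families = tree_families(tree))
}
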