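#' Global-rate normalization constant
#'
#' Branch lengths are interpreted so that a fully neutral site accumulates
#' `global_rate` substitution events per unit branch length on average. The
#' per-site neutral rate under the raw HKY-like rates is
#' `mu_i * sum_{j != s_i} kappa^[transition] * pi_j`, which depends on the
#' site's current base and mutation-rate category; the normalization divides
#' all rates by the mean of this quantity over the root sequence, then
#' multiplies by `global_rate`. With `global_rate = 0.01` a branch of length
#' 1 therefore yields 0.01 substitutions per neutral site on average, by
#' construction.
#'
#' @param genome An [genome()] object (root sequence).
#' @param assignment An [assign_site_categories()] object.
#' @param params Resolved [substitution_params()].
#' @return A positive scalar multiplying every event rate.
#' @export
normalization_constant <- function(genome, assignment, params) {
  params <- resolve_params(params, genome)
  code <- match(genome$seq, NUCLEOTIDES)
  pi <- unname(params$pi)
  # total neutral departure rate for a site currently at base b:
  # sum over the 3 targets, kappa on the single transition partner
  partner <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
  site_rate <- numeric(genome$length)
  for (b in 1:4) {
    targets <- setdiff(1:4, b)
    r <- sum(pi[targets] * ifelse(targets == partner[b], params$kappa, 1))
    site_rate[code == b] <- r
  }
  params$global_rate / mean(assignment$mu_eff * site_rate)
}

#' Initialize a simulation at the root of the tree
#'
#' Bundles everything a run needs: validated ORFs, per-site contexts,
#' discretized rate categories, the fixed per-site category assignment
#' (drawn from R's RNG — call [set.seed()] first for reproducibility), the
#' global-rate normalization and the event-probability tree built on the
#' root sequence.
#'
#' @param genome An [genome()] object.
#' @param orfs List of [orf()] objects (may be empty for a fully neutral,
#'   non-coding genome).
#' @param params An [substitution_params()] object.
#' @param mu Global mutation-rate [dist_spec()]; defaults to a single
#'   constant category of 1.
#' @return An object of class `ovrf_simulation` (an environment; mutable).
#'   Fields include `tree` (the event tree), `contexts`, `assignment`,
#'   `params` (with `pi` resolved), `norm` and `log` (the substitution log,
#'   one row per applied event).
#' @export
ovrf_simulation <- function(genome, orfs = list(), params = substitution_params(),
                            mu = dist_spec("constant", value = 1)) {
  params <- resolve_params(params, genome)
  contexts <- site_contexts(genome, orfs)
  mu_set <- discretize(mu)
  omega_sets <- list()
  mu_orf_sets <- list()
  for (o in orfs) {
    omega_sets[[o$name]] <- discretize(o$omega)
    if (!is.null(o$mu)) mu_orf_sets[[o$name]] <- discretize(o$mu)
  }
  assignment <- assign_site_categories(contexts, mu_set, omega_sets, mu_orf_sets)
  norm <- normalization_constant(genome, assignment, params)
  tree <- build_event_tree(contexts, assignment, params, norm)
  sim <- new.env(parent = emptyenv())
  sim$genome <- genome
  sim$orfs <- orfs
  sim$contexts <- contexts
  sim$assignment <- assignment
  sim$params <- params
  sim$norm <- norm
  sim$tree <- tree
  sim$log <- empty_log()
  class(sim) <- "ovrf_simulation"
  sim
}

empty_log <- function() {
  data.frame(position = integer(), from = character(), to = character(),
             time = numeric(), branch = character(), stringsAsFactors = FALSE)
}

#' @export
print.ovrf_simulation <- function(x, ...) {
  cat(sprintf("<ovrf_simulation> %d nt, %d ORF(s), Lambda = %g, %d event(s) logged\n",
              x$genome$length, length(x$orfs), total_rate(x$tree), nrow(x$log)))
  invisible(x)
}

#' Current sequence of a simulation state
#'
#' @param sim An [ovrf_simulation()] object.
#' @param collapse Return a single string (default) or a base vector.
#' @return The evolving sequence.
#' @export
current_sequence <- function(sim, collapse = TRUE) {
  s <- tree_sequence(sim$tree)
  if (collapse) paste(s, collapse = "") else s
}

#' Independent copy of a simulation state
#'
#' Deep-copies the event tree (and the substitution log), so that further
#' evolution of the copy never affects the original. This is what the
#' phylogeny traversal does at every internal node.
#'
#' @param sim An [ovrf_simulation()] object.
#' @return A new `ovrf_simulation`.
#' @export
copy_simulation <- function(sim) {
  copy <- new.env(parent = emptyenv())
  for (f in c("genome", "orfs", "contexts", "assignment", "params", "norm", "log")) {
    assign(f, get(f, envir = sim), envir = copy)
  }
  copy$tree <- copy_event_tree(sim$tree)
  class(copy) <- "ovrf_simulation"
  copy
}

#' Evolve a simulation state along one branch
#'
#' The Gillespie loop: repeatedly draw an exponential waiting time with rate
#' Lambda (the event tree's total), stop when the accumulated time exceeds
#' the branch duration (the sequence is then propagated unchanged), and
#' otherwise sample an event with probability `lambda/Lambda`, apply it and
#' update the tree. Consumes R's RNG.
#'
#' @param sim An [ovrf_simulation()] object (modified in place).
#' @param branch_length Nonnegative branch length, in the units of the input
#'   tree; the global mutation rate has already been folded into the event
#'   rates (see [normalization_constant()]).
#' @param branch Label recorded in the substitution log.
#' @return `sim`, invisibly; new log rows describe the applied events.
#' @export
simulate_branch <- function(sim, branch_length, branch = NA_character_) {
  if (!is.finite(branch_length) || branch_length < 0) {
    stop("branch length must be nonnegative, got ", branch_length)
  }
  ev <- engine_simulate_branch(sim$tree$ptr, branch_length)
  if (length(ev$site)) {
    sim$log <- rbind(sim$log, data.frame(
      position = ev$site, from = NUCLEOTIDES[ev$from], to = NUCLEOTIDES[ev$to],
      time = ev$time, branch = branch, stringsAsFactors = FALSE
    ))
  }
  invisible(sim)
}

#' Apply a single substitution to a simulation state
#'
#' @param sim An [ovrf_simulation()] object (modified in place).
#' @param position 1-based site.
#' @param to New base.
#' @param time Optional time stamp for the log.
#' @param branch Optional branch label for the log.
#' @return `sim`, invisibly.
#' @export
apply_substitution <- function(sim, position, to, time = NA_real_,
                               branch = NA_character_) {
  from <- tree_sequence(sim$tree)[position]
  apply_event(sim$tree, position, to)
  sim$log <- rbind(sim$log, data.frame(
    position = position, from = from, to = to, time = time, branch = branch,
    stringsAsFactors = FALSE
  ))
  invisible(sim)
}

# Stable per-branch seed: a deterministic hash of the master seed and the
# child clade's tip-label signature, so adding tips elsewhere in the tree
# does not perturb this lineage's draws.
branch_seed <- function(seed, signature) {
  p <- 2147483629
  h <- 0
  for (c in utf8ToInt(signature)) h <- (h * 31 + c) %% p
  (((seed %% p) * 31 + h) %% p) + 1
}

# Tip-label signature of every node's clade.
clade_signatures <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  sig <- character(nnode)
  sig[seq_len(ntip)] <- phy$tip.label
  # process internal nodes children-first
  ord <- rev(unique(phy$edge[order(phy$edge[, 1L]), 1L]))
  for (node in ord) {
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    sig[node] <- paste(sort(sig[kids]), collapse = "|")
  }
  sig
}

#' Evolve the root state over a rooted phylogeny
#'
#' Visits the tree in level order (breadth first from the root). At each
#' internal node the state — evolving sequence plus its event-probability
#' tree — is deep-copied once per child branch, each copy is evolved along
#' its branch with [simulate_branch()], and the recursion continues until
#' every tip carries a sequence.
#'
#' @param sim The root [ovrf_simulation()] state.
#' @param phy A rooted `ape::phylo` tree with branch lengths (see
#'   [read_tree()] for validation of files).
#' @param seed Optional integer. When given, every branch is simulated under
#'   its own RNG stream derived deterministically from this seed and the
#'   branch's clade (so runs are reproducible and lineages are insensitive
#'   to sibling order). When `NULL`, the current RNG stream is used
#'   sequentially.
#' @return An `ovrf_alignment`: named character vector of tip sequences (one
#'   per tip label, all of genome length), with the concatenated
#'   substitution log in `attr(, "substitutions")` (columns `position`,
#'   `from`, `to`, `time` within the branch, `branch` = child node label).
#' @export
traverse_phylogeny <- function(sim, phy, seed = NULL) {
  validate_phylogeny(phy)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  sig <- clade_signatures(phy)
  states <- vector("list", ntip + phy$Nnode)
  states[[root]] <- sim
  queue <- root
  aln <- character(ntip)
  names(aln) <- phy$tip.label
  logs <- list()
  while (length(queue)) {
    node <- queue[1L]
    queue <- queue[-1L]
    st <- states[[node]]
    edges <- which(phy$edge[, 1L] == node)
    for (e in edges) {
      child <- phy$edge[e, 2L]
      cst <- copy_simulation(st)
      cst$log <- empty_log()
      label <- if (child <= ntip) phy$tip.label[child] else paste0("node", child)
      if (!is.null(seed)) set.seed(branch_seed(seed, sig[child]))
      simulate_branch(cst, phy$edge.length[e], branch = label)
      logs[[length(logs) + 1L]] <- cst$log
      if (child <= ntip) {
        aln[child] <- current_sequence(cst)
      } else {
        states[[child]] <- cst
        queue <- c(queue, child)
      }
    }
    states[node] <- list(NULL)
  }
  log <- do.call(rbind, c(list(empty_log()), logs))
  structure(aln, substitutions = log, class = "ovrf_alignment")
}

#' @export
print.ovrf_alignment <- function(x, ...) {
  cat(sprintf("<ovrf_alignment> %d sequence(s) x %d column(s)\n",
              length(x), if (length(x)) nchar(x[[1L]]) else 0L))
  invisible(x)
}

#' Run a complete simulation
#'
#' One-call orchestration: seeds the RNG, initializes the root state (which
#' draws the fixed site categories), evolves it over the phylogeny and
#' returns the tip alignment together with the substitution log and a run
#' summary. Identical inputs and seed give a bit-identical alignment.
#'
#' @inheritParams ovrf_simulation
#' @param phy A rooted `ape::phylo` with branch lengths.
#' @param seed Optional integer master seed.
#' @return List with `alignment` (named character vector of tip sequences),
#'   `substitutions` (data frame log), and `summary` (effective parameters,
#'   root total rate, event count).
#' @examples
#' g <- make_genome(300, seed = 1)
#' orfs <- list(orf("a", c(31, 120), omega = dist_spec("gamma", 2, 0.25)))
#' phy <- make_tree(4, total_depth = 0.5, seed = 1)
#' res <- ovrf_simulate(g, orfs, phy, params = substitution_params(global_rate = 0.1),
#'                      seed = 42)
#' res$summary$n_events
#' @export
ovrf_simulate <- function(genome, orfs, phy, params = substitution_params(),
                          mu = dist_spec("constant", value = 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- ovrf_simulation(genome, orfs, params, mu)
  lambda0 <- total_rate(sim$tree)
  aln <- traverse_phylogeny(sim, phy, seed = seed)
  log <- attr(aln, "substitutions")
  summary <- list(
    n_sites = genome$length,
    circular = genome$circular,
    n_orfs = length(orfs),
    orf_names = vapply(orfs, `[[`, "", "name"),
    n_tips = length(aln),
    n_events = nrow(log),
    root_total_rate = lambda0,
    normalization = sim$norm,
    kappa = sim$params$kappa,
    pi = as.list(sim$params$pi),
    global_rate = sim$params$global_rate,
    seed = seed
  )
  list(alignment = aln, substitutions = log, summary = summary)
}
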