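#' Specify a rate distribution
#'
#' Distributions of selection effects (omega, one per ORF) and of
#' mutation-rate multipliers (mu, one global, optionally per ORF) are
#' continuous gamma or lognormal densities replaced by `ncat`
#' equal-probability categories (see [discretize()]), or a single constant.
#'
#' Parameterization: the gamma family uses shape `alpha` and **scale**
#' `beta`, so its mean is `alpha * beta` (with shape 2 and scale 0.5 the mean
#' is 1 and the four categories are 0.293, 0.655, 1.070, 1.982). The
#' lognormal family uses `sdlog = shape` and `meanlog = log(scale)`; the
#' default `scale = 1` places the distribution's median at 1.
#'
#' @param family `"gamma"`, `"lognormal"` or `"constant"`.
#' @param shape Gamma shape alpha, or lognormal sigma. Must be positive.
#' @param scale Gamma scale beta, or lognormal median. Must be positive.
#' @param ncat Number of equal-probability categories (>= 1).
#' @param value For `family = "constant"`: the constant rate.
#' @return An object of class `ovrf_dist_spec`.
#' @examples
#' dist_spec("gamma", shape = 2, scale = 0.5, ncat = 4)
#' dist_spec("constant", value = 1)
#' @export
dist_spec <- function(family = c("gamma", "lognormal", "constant"),
                      shape = NULL, scale = 1, ncat = 4L, value = NULL) {
  family <- match.arg(family)
  ncat <- as.integer(ncat)
  if (is.na(ncat) || ncat < 1L) stop("ncat must be an integer >= 1")
  if (family == "constant") {
    if (is.null(value) || !is.finite(value) || value <= 0) {
      stop("constant distributions need a positive 'value'")
    }
    ncat <- 1L
  } else {
    if (is.null(shape) || !is.finite(shape) || shape <= 0) {
      stop(family, " distributions need a positive 'shape'")
    }
    if (!is.finite(scale) || scale <= 0) {
      stop(family, " distributions need a positive 'scale'")
    }
  }
  structure(
    list(family = family, shape = shape, scale = scale, ncat = ncat,
         value = value),
    class = "ovrf_dist_spec"
  )
}

#' @export
print.ovrf_dist_spec <- function(x, ...) {
  if (x$family == "constant") {
    cat(sprintf("<dist_spec> constant %g\n", x$value))
  } else {
    cat(sprintf("<dist_spec> %s(shape=%g, scale=%g), %d categories\n",
                x$family, x$shape, x$scale, x$ncat))
  }
  invisible(x)
}

dist_mean <- function(spec) {
  switch(spec$family,
         constant = spec$value,
         gamma = spec$shape * spec$scale,
         lognormal = exp(log(spec$scale) + spec$shape^2 / 2))
}

#' Discretize a rate distribution into equal-probability categories
#'
#' The continuous density is cut at its `k/ncat` quantiles into `ncat` bins
#' of probability `1/ncat` each, and every bin is represented by its
#' conditional mean. This representation preserves the distribution's mean
#' exactly (the bin conditional means telescope), unlike the median-of-bin
#' convention. Closed forms are used for both families: for a gamma with
#' shape a and scale b, `E[X | q1 < X < q2]` is proportional to the
#' difference of `pgamma(., a + 1, scale = b)` at the bin edges; for a
#' lognormal, to a difference of normal CDFs shifted by `sdlog`.
#'
#' @param spec A [dist_spec()].
#' @return An object of class `ovrf_categories`: list with `values`
#'   (nondecreasing positive rates, one per category, each of probability
#'   `1/ncat`) and the originating `spec`.
#' @examples
#' discretize(dist_spec("gamma", shape = 2, scale = 0.5, ncat = 4))$values
#' # 0.293 0.655 1.070 1.982  (mean exactly 1)
#' @export
discretize <- function(spec) {
  stopifnot(inherits(spec, "ovrf_dist_spec"))
  k <- spec$ncat
  probs <- (0:k) / k
  values <- switch(
    spec$family,
    constant = rep(spec$value, k),
    gamma = {
      q <- qgamma(probs, shape = spec$shape, scale = spec$scale)
      mass <- pgamma(q[-1L], shape = spec$shape + 1, scale = spec$scale) -
        pgamma(q[-(k + 1L)], shape = spec$shape + 1, scale = spec$scale)
      spec$shape * spec$scale * mass * k
    },
    lognormal = {
      mulog <- log(spec$scale)
      sdlog <- spec$shape
      q <- qlnorm(probs, meanlog = mulog, sdlog = sdlog)
      z <- (log(q) - mulog) / sdlog - sdlog
      z[1L] <- -Inf; z[k + 1L] <- Inf
      mass <- pnorm(z[-1L]) - pnorm(z[-(k + 1L)])
      exp(mulog + sdlog^2 / 2) * mass * k
    }
  )
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("discretization produced non-finite or non-positive category means")
  }
  structure(list(values = values, spec = spec), class = "ovrf_categories")
}

#' @export
print.ovrf_categories <- function(x, ...) {
  cat(sprintf("<ovrf_categories> %d equal-probability categories: %s\n",
              length(x$values), paste(signif(x$values, 4), collapse = ", ")))
  invisible(x)
}

#' Global substitution-model parameters
#'
#' @param kappa Transition/transversion rate multiplier (transitions are
#'   A<->G and C<->T); dimensionless, default 0.3.
#' @param pi Stationary nucleotide frequencies in A, C, G, T order (a named
#'   or unnamed numeric of length 4, strictly positive, summing to 1 within
#'   1e-9), or `NULL` to use the empirical frequencies of the root sequence.
#' @param global_rate Expected substitution events per neutral site per unit
#'   branch length; branch lengths are effectively rescaled by this factor.
#' @return An object of class `ovrf_params`.
#' @export
substitution_params <- function(kappa = 0.3, pi = NULL, global_rate = 1) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  if (!is.finite(global_rate) || global_rate <= 0) {
    stop("global_rate must be positive")
  }
  if (!is.null(pi)) {
    if (!is.null(names(pi))) pi <- pi[NUCLEOTIDES]
    pi <- as.numeric(pi)
    if (length(pi) != 4L || anyNA(pi) || any(pi <= 0)) {
      stop("pi must be 4 strictly positive frequencies (A, C, G, T)")
    }
    if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1 (within 1e-9)")
    names(pi) <- NUCLEOTIDES
  }
  structure(list(kappa = kappa, pi = pi, global_rate = global_rate),
            class = "ovrf_params")
}

#' Empirical nucleotide frequencies of a genome
#'
#' @param genome An [genome()] object.
#' @return Named numeric of length 4 (A, C, G, T), summing to 1.
#' @export
empirical_pi <- function(genome) {
  counts <- tabulate(match(genome$seq, NUCLEOTIDES), nbins = 4L)
  p <- counts / sum(counts)
  names(p) <- NUCLEOTIDES
  p
}

# Fill a NULL pi from the root sequence and check positivity.
resolve_params <- function(params, genome) {
  if (is.null(params$pi)) {
    p <- empirical_pi(genome)
    if (any(p <= 0)) {
      stop("root sequence lacks at least one nucleotide; supply pi explicitly")
    }
    params$pi <- p
  }
  params
}

#' Draw fixed per-site rate categories
#'
#' Every site draws one mutation-rate (mu) category uniformly from the global
#' set, and, for each ORF covering it, one omega category uniformly from that
#' ORF's set. ORFs carrying their own mu distribution additionally contribute
#' a per-(site, ORF) multiplier to the site's effective mu. Assignments are
#' drawn once from R's RNG (seed with [set.seed()]) and stay fixed for the
#' lifetime of the run; they are not resampled along the tree.
#'
#' @param contexts An [site_contexts()] object.
#' @param mu_set Global mu [discretize()] categories.
#' @param omega_sets Named list (by ORF name) of omega [discretize()]
#'   categories.
#' @param mu_orf_sets Optional named list (by ORF name) of per-ORF mu
#'   multiplier categories.
#' @return An object of class `ovrf_assignment`: `mu_cat`/`mu_val` (global
#'   category index and value per site), `mu_eff` (effective per-site mu
#'   after ORF multipliers), `mu_eff_cat` (index over distinct effective mu
#'   values, used as the event tree's mu level), and `omega_cat`/`omega_val`
#'   aligned with the rows of `contexts$membership`.
#' @export
assign_site_categories <- function(contexts, mu_set,
                                   omega_sets = list(), mu_orf_sets = list()) {
  stopifnot(inherits(mu_set, "ovrf_categories"))
  L <- contexts$genome$length
  m <- contexts$membership
  mu_cat <- sample.int(length(mu_set$values), L, replace = TRUE)
  mu_val <- mu_set$values[mu_cat]
  omega_cat <- integer(nrow(m))
  omega_val <- numeric(nrow(m))
  for (o in contexts$orfs) {
    idx <- which(m$orf == o$name)
    set <- omega_sets[[o$name]]
    if (is.null(set)) stop("no omega categories supplied for ORF '", o$name, "'")
    omega_cat[idx] <- sample.int(length(set$values), length(idx), replace = TRUE)
    omega_val[idx] <- set$values[omega_cat[idx]]
  }
  mu_eff <- mu_val
  for (o in contexts$orfs) {
    set <- mu_orf_sets[[o$name]]
    if (is.null(set)) next
    sites <- unique(m$site[m$orf == o$name])
    mult <- set$values[sample.int(length(set$values), length(sites),
                                  replace = TRUE)]
    mu_eff[sites] <- mu_eff[sites] * mult
  }
  mu_eff_cat <- as.integer(factor(mu_eff, levels = sort(unique(mu_eff))))
  structure(
    list(mu_cat = mu_cat, mu_val = mu_val, mu_eff = mu_eff,
         mu_eff_cat = mu_eff_cat, omega_cat = omega_cat,
         omega_val = omega_val),
    class = "ovrf_assignment"
  )
}

# For one candidate substitution, the (ORF, category) pairs in which it is
# non-synonymous, canonicalized by ORF id. Returns a data frame with one row
# per non-synonymous frame context.
substitution_nonsyn <- function(contexts, assignment, sequence, position, to_nt) {
  m <- contexts$membership
  idx <- which(m$site == position)
  out <- list()
  for (r in idx) {
    p <- c(m$p1[r], m$p2[r], m$p3[r])
    nts <- sequence[p]
    alt <- nts
    alt[m$codon_pos[r] + 1L] <- to_nt
    if (m$strand[r] == "-") {
      nts <- complement_nt(nts)
      alt <- complement_nt(alt)
    }
    aa0 <- translate_codon(paste(nts, collapse = ""))
    aa1 <- translate_codon(paste(alt, collapse = ""))
    if (aa0 != aa1) {
      out[[length(out) + 1L]] <- data.frame(
        orf = m$orf[r], orf_id = m$orf_id[r], frame_label = m$frame_label[r],
        omega_cat = assignment$omega_cat[r], omega_val = assignment$omega_val[r],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(orf = character(), orf_id = integer(),
                      frame_label = character(), omega_cat = integer(),
                      omega_val = numeric()))
  }
  do.call(rbind, out)
}

#' Selection-effect vector of a candidate substitution
#'
#' Evaluates a substitution in every reading-frame context of a site. The
#' result is the six-slot vector `w` indexed by frame labels
#' `{-2, -1, -0, +0, +1, +2}` (relative to the plus-strand reference frame):
#' a slot is 1 when the substitution is synonymous in (or absent from) that
#' frame, and otherwise carries the site's assigned omega category value for
#' the ORF in that frame. When several ORFs share a frame slot their omegas
#' multiply within the slot, so `prod(w)` is always the total selective
#' effect.
#'
#' @param contexts An [site_contexts()] object.
#' @param assignment An [assign_site_categories()] object.
#' @param sequence Current sequence as a character vector of bases.
#' @param position 1-based site of the substitution.
#' @param from_nt Current residue at the position (checked).
#' @param to_nt Proposed residue, different from `from_nt`.
#' @return Named numeric of length 6.
#' @export
substitution_effect <- function(contexts, assignment, sequence, position,
                                from_nt, to_nt) {
  if (sequence[position] != from_nt) {
    stop("from_nt does not match the current residue at position ", position)
  }
  if (from_nt == to_nt) stop("to_nt must differ from from_nt")
  w <- c("-2" = 1, "-1" = 1, "-0" = 1, "+0" = 1, "+1" = 1, "+2" = 1)
  ns <- substitution_nonsyn(contexts, assignment, sequence, position, to_nt)
  for (r in seq_len(nrow(ns))) {
    w[ns$frame_label[r]] <- w[ns$frame_label[r]] * ns$omega_val[r]
  }
  w
}

#' Total selective effect of a substitution
#'
#' The combined dN/dS effect across frame contexts is assumed multiplicative:
#' the product of the six-slot selection vector. It equals 1 exactly when the
#' substitution is non-coding or synonymous in every frame.
#'
#' @param w Selection vector from [substitution_effect()].
#' @return A positive scalar.
#' @export
omega_product <- function(w) prod(w)

#' Rate of one substitution event
#'
#' The HKY-like event rate: `mu_i * pi_j`, multiplied by `kappa` for
#' transitions and by the total selective effect `omega` for substitutions
#' that are non-synonymous in at least one frame (`omega = 1` means fully
#' synonymous or non-coding).
#'
#' @param mu Site's (effective) mutation-rate multiplier.
#' @param params An [substitution_params()] object with `pi` resolved.
#' @param to_nt Target nucleotide.
#' @param transition Logical; is the change a transition?
#' @param omega Total selective effect ([omega_product()]).
#' @return The event rate lambda (before the simulator's global-rate
#'   normalization).
#' @export
event_rate <- function(mu, params, to_nt, transition, omega = 1) {
  mu * (if (transition) params$kappa else 1) * omega * params$pi[[to_nt]]
}

#' Flat enumeration of all candidate substitution events
#'
#' Computes, in plain R and without any hierarchical structure, the rate of
#' every possible substitution at every unprotected site via
#' [substitution_effect()] and [event_rate()]. This is the reference against
#' which the event-probability tree is validated, and is practical for small
#' genomes.
#'
#' @param contexts An [site_contexts()] object.
#' @param assignment An [assign_site_categories()] object.
#' @param params Resolved [substitution_params()].
#' @param sequence Current sequence (character vector); defaults to the root.
#' @param norm Scaling applied to every rate (the simulator's global-rate
#'   normalization constant; 1 by default).
#' @return Data frame with one row per event: `site`, `from`, `to`,
#'   `transition`, `omega`, `omega_key` (canonical ORF:category combination
#'   label, empty when fully synonymous), `mu_cat` (effective), `region`,
#'   `lambda`.
#' @export
enumerate_events <- function(contexts, assignment, params, sequence = NULL,
                             norm = 1) {
  params <- resolve_params(params, contexts$genome)
  if (is.null(sequence)) sequence <- contexts$genome$seq
  sites <- which(!contexts$protected)
  out <- vector("list", length(sites) * 3L)
  n <- 0L
  for (i in sites) {
    cur <- sequence[i]
    for (to in setdiff(NUCLEOTIDES, cur)) {
      ns <- substitution_nonsyn(contexts, assignment, sequence, i, to)
      omega <- prod(ns$omega_val)
      key <- paste(sprintf("%d:%d", ns$orf_id, ns$omega_cat), collapse = ",")
      ts <- is_transition(cur, to)
      lam <- norm * event_rate(assignment$mu_eff[i], params, to, ts, omega)
      n <- n + 1L
      out[[n]] <- data.frame(site = i, from = cur, to = to, transition = ts,
                             omega = omega, omega_key = key,
                             mu_cat = assignment$mu_eff_cat[i],
                             region = contexts$region_id[i], lambda = lam,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(n)])
  rownames(res) <- NULL
  res
}
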