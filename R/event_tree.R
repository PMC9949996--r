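#' Build the event-probability tree
#'
#' Constructs the hierarchical sampler that stores every possible
#' substitution event at an unprotected site, grouped level by level (target
#' nucleotide, transition/transversion class, mutation-rate category,
#' membership region, omega-combination class) so that all events at one tip
#' share a single rate. Subtree weights are cached at every node; the root
#' weight is the total rate Lambda. Sampling from the tree reproduces the
#' flat distribution `lambda_e / Lambda` exactly (see [enumerate_events()]
#' for the reference enumeration).
#'
#' @param contexts An [site_contexts()] object.
#' @param assignment An [assign_site_categories()] object.
#' @param params Resolved [substitution_params()] (with `pi` set; see
#'   [empirical_pi()]).
#' @param norm Global-rate normalization constant multiplying every rate
#'   (see [normalization_constant()]); 1 by default.
#' @return An object of class `ovrf_event_tree` (an environment wrapping the
#'   compiled engine plus its inputs). The tree is mutable: [apply_event()]
#'   updates it in place; use [copy_event_tree()] for an independent copy.
#' @export
build_event_tree <- function(contexts, assignment, params, norm = 1) {
  params <- resolve_params(params, contexts$genome)
  m <- contexts$membership
  ptr <- engine_build(
    seq0 = match(contexts$genome$seq, NUCLEOTIDES) - 1L,
    prot = contexts$protected,
    region = contexts$region_id,
    muval = assignment$mu_eff,
    mucat = assignment$mu_eff_cat,
    msite = m$site,
    morf = m$orf_id,
    mocat = assignment$omega_cat,
    moval = assignment$omega_val,
    mp1 = m$p1, mp2 = m$p2, mp3 = m$p3,
    moff = m$codon_pos,
    mstrand = ifelse(m$strand == "+", 1L, -1L),
    kappa = params$kappa,
    pi = unname(params$pi),
    norm = norm,
    aacode = aacode_table()
  )
  tree <- new.env(parent = emptyenv())
  tree$ptr <- ptr
  tree$contexts <- contexts
  tree$assignment <- assignment
  tree$params <- params
  tree$norm <- norm
  class(tree) <- "ovrf_event_tree"
  tree
}

# Amino-acid integer codes for the 64 codons in engine order
# (index = 16 b1 + 4 b2 + b3 with A=0, C=1, G=2, T=3).
aacode_table <- function() {
  bases <- NUCLEOTIDES
  idx <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)  # b1-major order
  codons <- paste0(bases[idx$b1], bases[idx$b2], bases[idx$b3])
  aa <- translate_codon(codons)
  match(aa, unique(aa))
}

#' @export
print.ovrf_event_tree <- function(x, ...) {
  cat(sprintf("<ovrf_event_tree> %d nt genome, total rate Lambda = %g\n",
              x$contexts$genome$length, total_rate(x)))
  invisible(x)
}

#' Total rate at the root of the event tree
#'
#' @param tree An [build_event_tree()] object.
#' @return Lambda, the sum of all event rates.
#' @export
total_rate <- function(tree) engine_total_rate(tree$ptr)

#' Current sequence held by an event tree
#'
#' @param tree An [build_event_tree()] object.
#' @return Character vector of bases.
#' @export
tree_sequence <- function(tree) NUCLEOTIDES[engine_sequence(tree$ptr)]

#' Sample one substitution event
#'
#' Traverses the tree from the root, choosing at each level a child with
#' probability proportional to its cached subtree weight, then picks an
#' event uniformly from the tip subset (valid because all members of a tip
#' share one probability). The event is returned but not applied. Consumes
#' R's RNG.
#'
#' @param tree An [build_event_tree()] object.
#' @return List with `position`, `from`, `to` (bases) and `lambda`.
#' @export
sample_event <- function(tree) {
  s <- engine_sample(tree$ptr)
  list(position = s$site, from = NUCLEOTIDES[s$from], to = NUCLEOTIDES[s$to],
       lambda = s$lambda)
}

#' Tabulate repeated draws from the event tree
#'
#' Draws `n` events (without applying any) and returns how often each
#' candidate event was selected — the empirical counterpart of the
#' `lambda_e / Lambda` distribution, used to validate the sampler against
#' [enumerate_events()].
#'
#' @param tree An [build_event_tree()] object.
#' @param n Number of draws.
#' @return Data frame with `site`, `to` and `count` for every possible
#'   event (including zero counts at unprotected sites).
#' @export
sample_event_counts <- function(tree, n) {
  counts <- engine_sample_counts(tree$ptr, as.integer(n))
  L <- tree$contexts$genome$length
  df <- data.frame(
    site = rep(seq_len(L), each = 4L),
    to = rep(NUCLEOTIDES, L),
    count = counts
  )
  cur <- tree_sequence(tree)
  df[!tree$contexts$protected[df$site] & df$to != cur[df$site], , drop = FALSE]
}

#' Apply a substitution and update the tree incrementally
#'
#' Writes the new base into the sequence and re-derives every event whose
#' rate or classification may have changed: the mutated site and all sites
#' sharing a codon with it in any reading frame. Cached weights are
#' re-propagated to the root. The updated tree is equivalent,
#' event-by-event, to a fresh build on the updated sequence.
#'
#' @param tree An [build_event_tree()] object (modified in place).
#' @param position 1-based site.
#' @param to New base at the site (must differ from the current one; the
#'   site must not be protected).
#' @return The tree, invisibly.
#' @export
apply_event <- function(tree, position, to) {
  engine_apply(tree$ptr, position, match(to, NUCLEOTIDES))
  invisible(tree)
}

#' Deep copy of an event tree
#'
#' @param tree An [build_event_tree()] object.
#' @return An independent copy: substitutions applied to the copy never
#'   affect the original, and vice versa.
#' @export
copy_event_tree <- function(tree) {
  copy <- new.env(parent = emptyenv())
  copy$ptr <- engine_clone(tree$ptr)
  copy$contexts <- tree$contexts
  copy$assignment <- tree$assignment
  copy$params <- tree$params
  copy$norm <- tree$norm
  class(copy) <- "ovrf_event_tree"
  copy
}

#' Flat table of the events currently stored at the tips
#'
#' @param tree An [build_event_tree()] object.
#' @return Data frame with `site`, `to` (base), `lambda` and the canonical
#'   `omega_key` of the tip holding the event.
#' @export
event_table <- function(tree) {
  df <- engine_events(tree$ptr)
  df$to <- NUCLEOTIDES[df$to]
  df <- df[order(df$site, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cached weights of every level of the event tree
#'
#' A diagnostic dump of the sampler's internal state: the root total, the
#' per-target and per-transition-class weights, the mutation-rate-category
#' and region levels, and the tip subsets (with their shared rate and
#' member count).
#'
#' @param tree An [build_event_tree()] object.
#' @return A list of weight tables.
#' @export
tree_weights <- function(tree) engine_weights(tree$ptr)

#' Write the event-tree weight dump as JSON
#'
#' @param tree An [build_event_tree()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
dump_event_tree_json <- function(tree, path) {
  jsonlite::write_json(tree_weights(tree), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
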