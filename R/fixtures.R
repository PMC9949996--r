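#' Generate a random genome
#'
#' Deterministic (seeded) synthetic root sequences for tests and demos.
#'
#' @param length Sequence length (>= 9).
#' @param gc_content Expected G+C fraction (G and C equiprobable, as are A
#'   and T). Ignored when `pi` is given.
#' @param seed Optional seed; the caller's RNG stream is left untouched.
#' @param pi Optional explicit base frequencies (A, C, G, T).
#' @param circular Circularity flag of the resulting genome.
#' @return An [genome()] object.
#' @export
make_genome <- function(length, gc_content = 0.5, seed = NULL, pi = NULL,
                        circular = FALSE) {
  if (is.null(pi)) {
    pi <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
            (1 - gc_content) / 2)
  }
  seqc <- with_seed(seed,
    sample(NUCLEOTIDES, length, replace = TRUE, prob = pi))
  genome(seqc, circular = circular)
}

# Snap an interval to a length that is a positive multiple of 3.
snap3 <- function(start, end) {
  len <- end - start + 1L
  end <- end - (len %% 3L)
  c(start, end)
}

#' Synthetic overlapping-ORF layouts
#'
#' Deterministic ORF arrangements used throughout the tests and the
#' entropy diagnostics:
#' \describe{
#'   \item{`fig2`}{Three plus-strand ORFs on a linear genome: one isolated
#'     ORF `a` and a pair `b`, `c` overlapping each other. The genome
#'     partitions into exactly five membership regions (`a`-only,
#'     non-coding, `b`-only, `b` and `c`, `c`-only).}
#'   \item{`hbv-like`}{Four plus-strand ORFs on a circular genome echoing
#'     the geometry of the hepatitis B virus genome: a long polymerase-like
#'     ORF `P` wrapping the origin; `S` fully inside `P` at a +1 frameshift;
#'     `X` overlapping the end of `P`'s post-origin segment; and `C`
#'     straddling `P`'s start at a +0 frameshift; about 14 per cent of the
#'     genome stays non-coding.}
#'   \item{`dense`}{Two full-length ORFs on opposite strands of a linear
#'     genome (length must be a multiple of 3), so every site is coding in
#'     at least two frames.}
#' }
#' All layouts default to a purifying selection distribution,
#' `dist_spec("gamma", shape = 2, scale = 0.25, ncat = 4)` (mean omega 0.5),
#' on every ORF.
#'
#' @param style `"fig2"`, `"hbv-like"` or `"dense"`.
#' @param length Genome length the layout is scaled to (>= 120 for `fig2`
#'   and `hbv-like`).
#' @param omega [dist_spec()] applied to every ORF.
#' @return List of [orf()] objects with attribute `circular` (logical:
#'   does the layout require a circular genome?).
#' @export
make_overlap_layout <- function(style = c("fig2", "hbv-like", "dense"),
                                length = 1200L,
                                omega = dist_spec("gamma", shape = 2,
                                                  scale = 0.25, ncat = 4)) {
  style <- match.arg(style)
  L <- as.integer(length)
  frac <- function(x) as.integer(round(x * L))
  orfs <- switch(
    style,
    "fig2" = {
      if (L < 120L) stop("fig2 layout needs length >= 120")
      a <- snap3(frac(0.06), frac(0.26))
      b <- snap3(frac(0.40), frac(0.60))
      cc <- snap3(frac(0.55), frac(0.78))
      list(orf("a", a, omega = omega),
           orf("b", b, omega = omega),
           orf("c", cc, omega = omega))
    },
    "hbv-like" = {
      if (L < 300L) stop("hbv-like layout needs length >= 300")
      p1s <- frac(0.76)
      p2e <- frac(0.45)
      # wrap length multiple of 3
      p2e <- p2e - ((L - p1s + 1L) + p2e) %% 3L
      off_p <- function(x) (L - p1s + 1L + x - 1L) %% 3L  # P's frame in segment 2
      s1 <- frac(0.05)
      while (off_p(s1) != 1L) s1 <- s1 + 1L               # S at +1 relative to P
      s <- snap3(s1, frac(0.35))
      x1 <- frac(0.40)
      x <- snap3(x1, frac(0.52))
      c1 <- frac(0.66)
      while ((c1 - p1s) %% 3L != 0L) c1 <- c1 + 1L        # C at +0 relative to P
      cend <- min(frac(0.85), L - 3L)
      cc <- snap3(c1, cend)
      stopifnot(s[2L] < x[1L] - 1L, x[2L] < c1 - 1L, x[1L] < p2e - 3L,
                cc[1L] < p1s, cc[2L] > p1s)
      out <- list(
        orf("P", list(c(p1s, L), c(1L, p2e)), omega = omega),
        orf("S", s, omega = omega),
        orf("X", x, omega = omega),
        orf("C", cc, omega = omega)
      )
      attr(out, "circular") <- TRUE
      out
    },
    "dense" = {
      if (L %% 3L != 0L) stop("dense layout needs a length divisible by 3")
      list(orf("fwd", c(1L, L), "+", omega = omega),
           orf("rev", c(1L, L), "-", omega = omega))
    }
  )
  if (is.null(attr(orfs, "circular"))) attr(orfs, "circular") <- FALSE
  orfs
}

#' Imprint start and stop codons for a set of ORFs
#'
#' Overwrites each ORF's first codon with ATG and its last with TAA (on the
#' ORF's own strand), so synthetic genomes carry literal translation
#' signals. With overlapping ORFs a later ORF's signal may fall inside an
#' earlier one; the simulator is agnostic either way, since terminal codons
#' are protected from substitution.
#'
#' @param genome An [genome()] object.
#' @param orfs List of [orf()] objects.
#' @return A new [genome()] with the signals written in.
#' @export
imprint_orf_signals <- function(genome, orfs) {
  seqc <- genome$seq
  for (o in orfs) {
    s <- orf_sites(o, genome)  # reading order; codon bases are
    start <- c("A", "T", "G")  # complemented on the minus strand
    stopc <- c("T", "A", "A")
    if (o$strand == "-") {
      start <- complement_nt(start)
      stopc <- complement_nt(stopc)
    }
    n <- base::length(s)
    seqc[s[1:3]] <- start
    seqc[s[(n - 2L):n]] <- stopc
  }
  genome(seqc, circular = genome$circular)
}

#' Generate a random rooted tree
#'
#' A seed-reproducible random binary rooted tree with strictly positive
#' branch lengths, rescaled so the deepest root-to-tip path has length
#' `total_depth`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param total_depth Maximum root-to-tip path length after rescaling.
#' @param seed Optional seed; the caller's RNG stream is left untouched.
#' @return An `ape::phylo` that passes [validate_phylogeny()].
#' @export
make_tree <- function(n_tips, total_depth = 1, seed = NULL) {
  if (n_tips < 2L) stop("a tree needs at least 2 tips")
  phy <- with_seed(seed, ape::rtree(n_tips, rooted = TRUE))
  phy$edge.length <- pmax(phy$edge.length, 1e-6)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (total_depth / depth)
  phy
}

#' Write a ready-to-run fixture data set
#'
#' Produces a FASTA root sequence (with imprinted start/stop codons), a YAML
#' run configuration describing the layout's ORFs, and a Newick tree, so a
#' complete simulation can be run from files alone.
#'
#' @param dir Output directory (created if missing).
#' @param style Layout style for [make_overlap_layout()].
#' @param length Genome length.
#' @param n_tips Tips of the generated tree.
#' @param total_depth Tree depth.
#' @param seed Seed for the genome and tree.
#' @return Named character vector of the three file paths, invisibly.
#' @export
make_fixture_files <- function(dir, style = "hbv-like", length = 1200L,
                               n_tips = 20L, total_depth = 1, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  orfs <- make_overlap_layout(style, length)
  circ <- attr(orfs, "circular")
  g <- imprint_orf_signals(
    make_genome(length, seed = seed, circular = circ), orfs)
  phy <- make_tree(n_tips, total_depth = total_depth, seed = seed)
  fa <- file.path(dir, paste0(style, ".fasta"))
  writeLines(c(paste0(">", style, "_root"), as.character(g)), fa)
  cfg <- list(
    circular = circ,
    kappa = 0.3,
    global_rate = 1,
    orfs = lapply(orfs, function(o) {
      list(name = o$name, coords = lapply(o$segments, as.integer),
           strand = o$strand,
           omega = list(family = o$omega$family, shape = o$omega$shape,
                        scale = o$omega$scale, ncat = o$omega$ncat))
    })
  )
  yml <- file.path(dir, paste0(style, ".yaml"))
  yaml::write_yaml(cfg, yml)
  nwk <- file.path(dir, paste0(style, ".nwk"))
  ape::write.tree(phy, nwk)
  invisible(c(fasta = fa, config = yml, tree = nwk))
}
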