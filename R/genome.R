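#' Construct a genome object
#'
#' A genome is the root nucleotide sequence of a simulation together with its
#' topology (linear or circular). Sequences must be at least 9 nt long and may
#' only contain the unambiguous bases A, C, G and T; IUPAC ambiguity codes are
#' rejected because every site must have well-defined substitution rates.
#'
#' @param sequence A single string, or a character vector of single bases.
#' @param circular Logical; is the genome circular?
#' @return An object of class `ovrf_genome` with fields `seq` (character
#'   vector of bases), `length` and `circular`.
#' @examples
#' g <- genome("ATGAAATAGGGG")
#' g$length
#' @export
genome <- function(sequence, circular = FALSE) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  }
  sequence <- toupper(as.character(sequence))
  bad <- !(sequence %in% NUCLEOTIDES)
  if (any(bad)) {
    stop("sequence contains characters outside A/C/G/T: ",
         paste(unique(sequence[bad]), collapse = ", "),
         " (ambiguity codes are not accepted)")
  }
  if (length(sequence) < 9L) {
    stop("root sequence must be at least 9 nt (got ", length(sequence), ")")
  }
  structure(
    list(seq = sequence, length = length(sequence), circular = isTRUE(circular)),
    class = "ovrf_genome"
  )
}

#' @export
print.ovrf_genome <- function(x, ...) {
  cat(sprintf("<ovrf_genome> %d nt, %s\n", x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
as.character.ovrf_genome <- function(x, ...) paste(x$seq, collapse = "")

#' Define an open reading frame
#'
#' Coordinates are 1-based and inclusive, on the plus strand of the genome.
#' An ORF is one segment, or exactly two segments when it crosses the origin
#' of a circular genome (GenBank `join()` semantics). Segments are listed in
#' the ORF's reading order: a plus-strand wrap is `list(c(s, L), c(1, e))`,
#' a minus-strand wrap is `list(c(1, e), c(s, L))` (the minus strand reads
#' toward decreasing plus-strand coordinates).
#'
#' @param name ORF label, unique within a run.
#' @param coords A numeric `c(start, end)` pair or a list of one or two such
#'   pairs (1-based inclusive, `start <= end` within each segment).
#' @param strand `"+"` or `"-"`.
#' @param omega A [dist_spec()] describing the dN/dS (omega) distribution for
#'   this ORF. Defaults to neutral (`omega = 1` everywhere).
#' @param mu Optional [dist_spec()] of per-site mutation-rate multipliers
#'   applied on top of the global mu distribution for sites in this ORF.
#' @return An object of class `ovrf_orf`.
#' @examples
#' orf("C", c(1816, 2454), "+", omega = dist_spec("gamma", shape = 2, scale = 0.5))
#' @export
orf <- function(name, coords, strand = c("+", "-"),
                omega = dist_spec("constant", value = 1), mu = NULL) {
  strand <- match.arg(strand)
  if (is.numeric(coords)) coords <- list(coords)
  if (!is.list(coords) || !length(coords) %in% 1:2) {
    stop("ORF '", name, "': coords must be one or two (start, end) pairs")
  }
  segments <- lapply(coords, function(x) {
    x <- as.integer(x)
    if (length(x) != 2L || anyNA(x) || x[1L] < 1L || x[2L] < x[1L]) {
      stop("ORF '", name, "': each segment must be c(start, end) with ",
           "1 <= start <= end")
    }
    x
  })
  if (!is.null(omega) && !inherits(omega, "ovrf_dist_spec")) {
    stop("ORF '", name, "': omega must be a dist_spec()")
  }
  if (!is.null(mu) && !inherits(mu, "ovrf_dist_spec")) {
    stop("ORF '", name, "': mu must be a dist_spec()")
  }
  structure(
    list(name = as.character(name), segments = segments, strand = strand,
         omega = omega, mu = mu),
    class = "ovrf_orf"
  )
}

#' @export
print.ovrf_orf <- function(x, ...) {
  segs <- vapply(x$segments, function(s) paste0(s[1L], "..", s[2L]), "")
  cat(sprintf("<ovrf_orf> %s (%s) %s\n", x$name, x$strand,
              paste(segs, collapse = " + ")))
  invisible(x)
}

#' Genome positions of an ORF in reading order
#'
#' Returns the 1-based genome coordinates of every nucleotide of the ORF, in
#' the order in which they are read (5' to 3' along the coding strand). For
#' minus-strand ORFs the positions therefore run toward decreasing
#' coordinates; consecutive triples are codons.
#'
#' @param orf An [orf()] object.
#' @param genome The [genome()] the ORF lives on (used only for validation
#'   context; may be omitted).
#' @return Integer vector of genome positions, length a multiple of 3.
#' @export
orf_sites <- function(orf, genome = NULL) {
  segs <- orf$segments
  if (orf$strand == "+") {
    unlist(lapply(segs, function(s) s[1L]:s[2L]), use.names = FALSE)
  } else {
    unlist(lapply(segs, function(s) s[2L]:s[1L]), use.names = FALSE)
  }
}

orf_length <- function(orf) {
  sum(vapply(orf$segments, function(s) s[2L] - s[1L] + 1L, 1L))
}

#' Validate a set of ORFs against a genome
#'
#' Checks coordinate bounds, the multiple-of-3 length rule, self-overlap,
#' circular-wrap representation (exactly two segments meeting at the origin)
#' and name uniqueness. Emits a warning when an ORF does not literally begin
#' with ATG or end with a stop codon; the simulator itself is agnostic to
#' that.
#'
#' @param genome An [genome()] object.
#' @param orfs List of [orf()] objects.
#' @return Invisibly, `orfs`.
#' @export
validate_orfs <- function(genome, orfs) {
  if (!length(orfs)) return(invisible(orfs))
  nms <- vapply(orfs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate ORF names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  L <- genome$length
  for (o in orfs) {
    n <- orf_length(o)
    if (n < 3L || n %% 3L != 0L) {
      stop("ORF '", o$name, "': total length ", n,
           " is not a positive multiple of 3")
    }
    for (s in o$segments) {
      if (s[2L] > L) stop("ORF '", o$name, "': segment ", s[1L], "..", s[2L],
                          " exceeds genome length ", L)
    }
    if (length(o$segments) == 2L) {
      if (!genome$circular) {
        stop("ORF '", o$name, "': two segments are only allowed for an ",
             "origin-crossing ORF on a circular genome")
      }
      a <- o$segments[[1L]]; b <- o$segments[[2L]]
      ok <- if (o$strand == "+") a[2L] == L && b[1L] == 1L else a[1L] == 1L && b[2L] == L
      if (!ok) {
        stop("ORF '", o$name, "': a circular wrap must be two segments ",
             "meeting at the origin, listed in reading order")
      }
    }
    sites <- orf_sites(o, genome)
    if (anyDuplicated(sites)) stop("ORF '", o$name, "': segments self-overlap")
    cds <- genome$seq[sites]
    if (o$strand == "-") cds <- complement_nt(cds)
    first <- paste(cds[1:3], collapse = "")
    last <- paste(cds[length(cds) - 2:0], collapse = "")
    if (first != "ATG") {
      warning("ORF '", o$name, "' does not begin with ATG (", first, ")",
              call. = FALSE)
    }
    if (!last %in% c("TAA", "TAG", "TGA")) {
      warning("ORF '", o$name, "' does not end with a stop codon (", last, ")",
              call. = FALSE)
    }
  }
  invisible(orfs)
}

# Frame label of an ORF relative to the genome reference frame (plus strand,
# codons starting at positions 1, 4, 7, ...). Used to place selection effects
# in the six-slot omega vector; the reference choice is presentational and
# does not affect any rate.
orf_frame_label <- function(orf) {
  first <- orf_sites(orf)[1L]
  d <- (first - 1L) %% 3L
  paste0(if (orf$strand == "+") "+" else "-", d)
}

#' Classify the frameshift between two overlapping ORFs
#'
#' Overlaps between reading frames fall into six classes, labelled
#' `+0, +1, +2` (same strand) and `-0, -1, -2` (opposite strands), where the
#' digit is the shift of `b`'s reading frame relative to `a`'s, modulo 3,
#' measured along `a`'s strand orientation.
#'
#' @param a,b [orf()] objects that overlap by at least one nucleotide.
#' @param genome The [genome()] both ORFs are annotated on.
#' @return A single character label, e.g. `"+1"`.
#' @examples
#' g <- genome(strrep("ACGT", 100))
#' a <- orf("a", c(1, 300)); b <- orf("b", c(101, 400))
#' classify_frameshift(a, b, g)  # "+1"
#' @export
classify_frameshift <- function(a, b, genome) {
  sa <- orf_sites(a, genome)
  sb <- orf_sites(b, genome)
  shared <- intersect(sa, sb)
  if (!length(shared)) {
    stop("ORFs '", a$name, "' and '", b$name, "' do not overlap: no overlap")
  }
  p <- shared[1L]
  off_a <- (match(p, sa) - 1L) %% 3L
  off_b <- (match(p, sb) - 1L) %% 3L
  if (a$strand == b$strand) {
    paste0("+", (off_a - off_b) %% 3L)
  } else {
    # On opposite strands the two codon offsets move in opposite directions
    # along the genome, so their sum (mod 3) is constant over the overlap.
    paste0("-", (off_a + off_b) %% 3L)
  }
}

#' Partition a genome into regions of identical ORF membership
#'
#' Regions are the equivalence classes of sites under "annotated by exactly
#' the same set of ORFs". Non-coding sites (empty membership) form one
#' region. Regions need not be contiguous.
#'
#' @param genome An [genome()] object.
#' @param orfs List of [orf()] objects (may be empty).
#' @return A list of regions, each a list with `id`, `sites` (integer
#'   positions) and `orf_membership` (character vector of ORF names, possibly
#'   empty), classed `ovrf_regions`.
#' @export
partition_regions <- function(genome, orfs) {
  L <- genome$length
  n <- length(orfs)
  if (n == 0L) {
    key <- rep("", L)
  } else {
    memb <- matrix(FALSE, nrow = L, ncol = n)
    for (k in seq_len(n)) memb[orf_sites(orfs[[k]], genome), k] <- TRUE
    key <- do.call(paste0, as.data.frame(memb))
  }
  ids <- unique(key)
  nms <- if (n) vapply(orfs, `[[`, "", "name") else character()
  regions <- lapply(seq_along(ids), function(i) {
    sites <- which(key == ids[i])
    member <- if (n) nms[memb[sites[1L], ]] else character()
    list(id = paste0("R", i), sites = sites, orf_membership = member)
  })
  structure(regions, class = "ovrf_regions")
}

#' @export
print.ovrf_regions <- function(x, ...) {
  cat(sprintf("<ovrf_regions> %d region(s)\n", length(x)))
  for (r in x) {
    cat(sprintf("  %s: %d site(s), membership {%s}\n", r$id, length(r$sites),
                paste(r$orf_membership, collapse = ",")))
  }
  invisible(x)
}

#' Per-site reading-frame contexts
#'
#' Builds the per-nucleotide bookkeeping the simulator relies on: for every
#' site, which ORFs cover it (with codon index and within-codon offset along
#' the ORF's own strand), whether the site is protected (first or last codon
#' of any ORF, excluded from substitution sampling so that ORFs are never
#' disrupted), and which membership region it belongs to.
#'
#' @param genome An [genome()] object.
#' @param orfs List of [orf()] objects.
#' @return An object of class `ovrf_contexts`: a list with `protected`
#'   (logical per site), `membership` (one data-frame row per (site, ORF)
#'   pair: `site`, `orf`, `orf_id`, `codon_index`, `codon_pos`, `strand`,
#'   `frame_label`, codon genome positions `p1`,`p2`,`p3`, and the omega
#'   category columns filled by [assign_site_categories()]), `regions`,
#'   `region_id` (integer per site), plus the genome and ORFs.
#' @export
site_contexts <- function(genome, orfs) {
  validate_orfs(genome, orfs)
  L <- genome$length
  protected <- rep(FALSE, L)
  rows <- vector("list", length(orfs))
  for (k in seq_along(orfs)) {
    o <- orfs[[k]]
    s <- orf_sites(o, genome)
    ncod <- length(s) %/% 3L
    ci <- rep(seq_len(ncod), each = 3L)
    protected[s[ci == 1L | ci == ncod]] <- TRUE
    rows[[k]] <- data.frame(
      site = s,
      orf = o$name,
      orf_id = k,
      codon_index = ci,
      codon_pos = rep(0:2, ncod),
      strand = o$strand,
      frame_label = orf_frame_label(o),
      p1 = s[(ci - 1L) * 3L + 1L],
      p2 = s[(ci - 1L) * 3L + 2L],
      p3 = s[(ci - 1L) * 3L + 3L],
      stringsAsFactors = FALSE
    )
  }
  membership <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(), orf = character(), orf_id = integer(),
               codon_index = integer(), codon_pos = integer(),
               strand = character(), frame_label = character(),
               p1 = integer(), p2 = integer(), p3 = integer())
  membership <- membership[order(membership$site, membership$orf_id), ,
                           drop = FALSE]
  rownames(membership) <- NULL
  regions <- partition_regions(genome, orfs)
  region_id <- integer(L)
  for (i in seq_along(regions)) region_id[regions[[i]]$sites] <- i
  structure(
    list(protected = protected, membership = membership, regions = regions,
         region_id = region_id, genome = genome, orfs = orfs),
    class = "ovrf_contexts"
  )
}

#' Context of a single site
#'
#' @param contexts An [site_contexts()] object.
#' @param position 1-based genome position.
#' @return List with `position`, `frame_memberships` (data frame of the
#'   site's (ORF, codon index, codon offset) records) and `protected`.
#' @export
site_context <- function(contexts, position) {
  m <- contexts$membership
  list(
    position = position,
    frame_memberships = m[m$site == position, , drop = FALSE],
    protected = contexts$protected[position]
  )
}

#' Codon containing a site, read from the current sequence
#'
#' Returns the codon of the given ORF that contains `position`, assembled
#' from the *current* (possibly evolved) sequence: reverse-complemented for
#' minus-strand ORFs and stitched across the origin for wrapping ORFs.
#'
#' @param sequence Character vector of single bases (the evolving sequence),
#'   or an [genome()] object.
#' @param contexts An [site_contexts()] object.
#' @param position 1-based genome position.
#' @param orf Name of an ORF covering the position.
#' @return List with `codon` (3-character string, in the ORF's reading
#'   frame) and `offset` (0, 1 or 2: the site's position within the codon).
#' @export
codon_at <- function(sequence, contexts, position, orf) {
  if (inherits(sequence, "ovrf_genome")) sequence <- sequence$seq
  m <- contexts$membership
  row <- m[m$site == position & m$orf == orf, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("position ", position, " is not part of ORF '", orf, "'")
  }
  nts <- sequence[c(row$p1, row$p2, row$p3)]
  if (row$strand == "-") nts <- complement_nt(nts)
  list(codon = paste(nts, collapse = ""), offset = row$codon_pos)
}
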