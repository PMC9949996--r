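#' Read the root sequence from FASTA or GenBank
#'
#' FASTA files must contain exactly one record. GenBank flat files
#' additionally yield candidate ORFs from their CDS features (including
#' `join(...)` across the origin of a circular record and `complement(...)`
#' for minus-strand genes) and the circularity flag from the LOCUS line.
#' Sequences are uppercased and validated (A/C/G/T only, minimum 9 nt).
#'
#' @param path Input file.
#' @param format `"auto"` (by content), `"fasta"` or `"genbank"`.
#' @param circular Circularity flag for FASTA input (GenBank records carry
#'   their own).
#' @return List with `genome` (an [genome()]) and `orfs` (list of [orf()]
#'   skeletons with neutral omega placeholders; `NULL` for FASTA input).
#' @export
read_root_sequence <- function(path, format = c("auto", "fasta", "genbank"),
                               circular = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L) {
      stop("expected exactly one FASTA record, found ", length(set))
    }
    g <- genome(as.character(set[[1L]]), circular = circular)
    return(list(genome = g, orfs = NULL))
  }
  gb <- parse_genbank(path)
  g <- genome(gb$sequence, circular = gb$circular)
  orfs <- lapply(gb$features, function(f) {
    orf(f$name, f$segments, f$strand)
  })
  list(genome = g, orfs = orfs)
}

# Minimal GenBank flat-file parser: LOCUS (length + circular token), FEATURES
# CDS locations with join()/complement(), /gene= or /locus_tag= names, and
# the ORIGIN sequence block. Spliced CDS with more than two segments are not
# supported (only the circular-origin wrap needs two).
parse_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank file: no LOCUS line")
  circular <- grepl("circular", locus[1L], ignore.case = TRUE)
  org <- grep("^ORIGIN", lines)
  if (!length(org)) stop("GenBank file has no ORIGIN sequence block")
  seq_lines <- lines[(org[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat)) {
    block <- lines[(feat[1L] + 1L):(org[1L] - 1L)]
    is_key <- grepl("^ {5}\\S", block)
    starts <- which(is_key & grepl("^ {5}CDS\\s", block))
    bounds <- c(which(is_key), length(block) + 1L)
    for (s in starts) {
      endl <- min(bounds[bounds > s]) - 1L
      chunk <- block[s:endl]
      loc <- sub("^ {5}CDS\\s+", "", chunk[1L])
      qual_start <- grep("^\\s+/", chunk)
      cont <- if (length(qual_start)) {
        if (qual_start[1L] > 2L) chunk[2:(qual_start[1L] - 1L)] else character()
      } else chunk[-1L]
      loc <- paste0(loc, gsub("\\s", "", paste(cont, collapse = "")))
      name <- NA_character_
      for (q in c("gene", "locus_tag", "product")) {
        m <- grep(sprintf('^\\s+/%s="?', q), chunk, value = TRUE)
        if (length(m)) {
          name <- gsub('"', "", sub(sprintf('^\\s+/%s=', q), "", m[1L]))
          break
        }
      }
      parsed <- parse_gb_location(loc)
      if (is.na(name)) name <- paste0("CDS_", length(features) + 1L)
      features[[length(features) + 1L]] <-
        list(name = name, segments = parsed$segments, strand = parsed$strand)
    }
  }
  list(sequence = sequence, circular = circular, features = features)
}

# "complement(join(a..b,c..d))" etc. -> segments in reading order + strand.
parse_gb_location <- function(loc) {
  loc <- gsub("\\s|<|>", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1L]]
    if (length(m) != 3L) stop("cannot parse GenBank location part '", p, "'")
    as.integer(m[2:3])
  })
  if (length(segs) > 2L) {
    stop("spliced CDS with more than two segments are not supported")
  }
  # complement(join(A, B)) reads revcomp(B) then revcomp(A)
  if (strand == "-") segs <- rev(segs)
  list(segments = segs, strand = strand)
}

spec_keys <- c("family", "shape", "scale", "ncat", "value")

parse_dist_spec <- function(x, where) {
  if (inherits(x, "ovrf_dist_spec")) return(x)
  if (!is.list(x)) stop(where, ": distribution spec must be a mapping")
  unknown <- setdiff(names(x), spec_keys)
  if (length(unknown)) {
    stop(where, ": unknown distribution key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(dist_spec, x)
}

#' Read a YAML run configuration
#'
#' Strict parsing: unknown keys raise errors naming the offender. An empty
#' file yields the documented defaults (linear genome, `kappa = 0.3`,
#' `global_rate = 1`, empirical `pi`, a single constant mu category, no
#' ORFs). ORF coordinates are 1-based inclusive; ORF total lengths must be
#' positive multiples of 3.
#'
#' @param path YAML file.
#' @return An object of class `ovrf_config`: list with `circular`, `kappa`,
#'   `pi` (or `NULL` for empirical), `global_rate`, `mu` (a [dist_spec()])
#'   and `orfs` (list of [orf()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- c("circular", "kappa", "pi", "global_rate", "mu", "orfs")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  circular <- isTRUE(raw$circular)
  kappa <- if (is.null(raw$kappa)) 0.3 else as.numeric(raw$kappa)
  global_rate <- if (is.null(raw$global_rate)) 1 else as.numeric(raw$global_rate)
  pi <- if (is.null(raw$pi)) NULL else unlist(raw$pi)
  params <- substitution_params(kappa = kappa, pi = pi,
                                global_rate = global_rate)
  mu <- if (is.null(raw$mu)) dist_spec("constant", value = 1) else
    parse_dist_spec(raw$mu, "mu")
  orfs <- list()
  for (i in seq_along(raw$orfs)) {
    block <- raw$orfs[[i]]
    where <- paste0("orfs[", i, "]")
    allowed_orf <- c("name", "coords", "strand", "omega", "mu")
    unknown <- setdiff(names(block), allowed_orf)
    if (length(unknown)) {
      stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "))
    }
    if (is.null(block$name)) stop(where, ": missing 'name'")
    if (is.null(block$coords)) stop(where, ": missing 'coords'")
    coords <- block$coords
    if (is.numeric(coords)) coords <- list(coords)
    coords <- lapply(coords, function(s) as.integer(unlist(s)))
    omega <- if (is.null(block$omega)) dist_spec("constant", value = 1) else
      parse_dist_spec(block$omega, paste0(where, "$omega"))
    mu_o <- if (is.null(block$mu)) NULL else
      parse_dist_spec(block$mu, paste0(where, "$mu"))
    o <- orf(block$name, coords, strand = if (is.null(block$strand)) "+" else
      block$strand, omega = omega, mu = mu_o)
    n <- orf_length(o)
    if (n < 3L || n %% 3L != 0L) {
      stop(where, " ('", o$name, "'): length ", n,
           " is not a positive multiple of 3")
    }
    orfs[[length(orfs) + 1L]] <- o
  }
  structure(
    list(circular = circular, kappa = kappa, pi = params$pi,
         global_rate = global_rate, mu = mu, orfs = orfs),
    class = "ovrf_config"
  )
}

#' Validate a phylogeny for simulation
#'
#' The tree must be rooted (bifurcating at the root unless
#' `allow_polytomy`), and every branch needs a nonnegative length.
#'
#' @param phy An `ape::phylo` object.
#' @param allow_polytomy Accept a root with more than two children.
#' @return `phy`, invisibly.
#' @export
validate_phylogeny <- function(phy, allow_polytomy = FALSE) {
  if (!inherits(phy, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; the tree must contain branch lengths")
  }
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0)) {
    stop("tree has missing or negative branch lengths")
  }
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  root <- length(phy$tip.label) + 1L
  nchild <- sum(phy$edge[, 1L] == root)
  if (nchild != 2L && !allow_polytomy) {
    stop("tree must be rooted with a bifurcating root (found ", nchild,
         " basal children); a basal polytomy is treated as unrooted")
  }
  invisible(phy)
}

#' Read a rooted Newick tree
#'
#' @param path Newick file.
#' @param allow_polytomy Accept a root with more than two children.
#' @return A validated `ape::phylo`.
#' @export
read_tree <- function(path, allow_polytomy = FALSE) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse a Newick tree from ", path)
  validate_phylogeny(phy, allow_polytomy = allow_polytomy)
  phy
}

#' Generate a YAML configuration skeleton from a GenBank record
#'
#' Lists every CDS feature as an ORF block with a neutral placeholder omega
#' distribution (gamma, shape 1, scale 1, 4 categories) for the user to
#' edit, and carries over the record's circularity.
#'
#' @param path GenBank flat file.
#' @param out Optional output YAML path.
#' @return The configuration as a list (invisibly when `out` is given).
#' @export
genbank_to_config <- function(path, out = NULL) {
  gb <- parse_genbank(path)
  cfg <- list(
    circular = gb$circular,
    kappa = 0.3,
    global_rate = 1,
    orfs = lapply(gb$features, function(f) {
      list(name = f$name,
           coords = lapply(f$segments, as.integer),
           strand = f$strand,
           omega = list(family = "gamma", shape = 1, scale = 1, ncat = 4L))
    })
  )
  if (!is.null(out)) {
    yaml::write_yaml(cfg, out)
    return(invisible(cfg))
  }
  cfg
}

#' Write a tip alignment as FASTA
#'
#' @param alignment Named character vector of equal-length sequences (an
#'   `ovrf_alignment`).
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  if (!length(alignment)) stop("alignment is empty")
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    stop("alignment sequences must be named by tip label")
  }
  set <- Biostrings::DNAStringSet(unclass(alignment))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a FASTA alignment
#'
#' @param path FASTA file.
#' @return Named character vector classed `ovrf_alignment`; all sequences
#'   must have equal length.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("alignment is empty")
  seqs <- as.character(set)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment sequences have unequal lengths")
  }
  structure(seqs, class = "ovrf_alignment")
}

#' Write the substitution log as TSV
#'
#' @param log Substitution data frame (`position`, `from`, `to`, `time`,
#'   `branch`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_substitution_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the run summary as JSON
#'
#' Echoes the effective configuration (defaults resolved), the root total
#' rate and the event count of a finished run.
#'
#' @param result Return value of [ovrf_simulate()] or [run_simulation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(result, path) {
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a simulation from input files
#'
#' The file-level pipeline: reads the root sequence (FASTA or GenBank), the
#' YAML configuration and the Newick tree, runs [ovrf_simulate()], and — if
#' `out_prefix` is given — writes `<prefix>.fasta` (tip alignment),
#' `<prefix>_substitutions.tsv` (event log) and `<prefix>_summary.json`.
#' ORFs come from the configuration; a GenBank input may also supply them
#' (configuration ORFs take precedence when both are present).
#'
#' @param seq_file FASTA or GenBank root sequence.
#' @param config_file YAML run configuration.
#' @param tree_file Newick rooted tree with branch lengths.
#' @param out_prefix Optional output path prefix.
#' @param seed Optional integer master seed.
#' @param allow_polytomy Accept a basal polytomy in the tree.
#' @return As [ovrf_simulate()], invisibly when writing files.
#' @export
run_simulation <- function(seq_file, config_file, tree_file, out_prefix = NULL,
                           seed = NULL, allow_polytomy = FALSE) {
  cfg <- read_config(config_file)
  inp <- read_root_sequence(seq_file, circular = cfg$circular)
  g <- genome(inp$genome$seq, circular = cfg$circular || inp$genome$circular)
  orfs <- if (length(cfg$orfs)) cfg$orfs else inp$orfs
  if (is.null(orfs)) orfs <- list()
  phy <- read_tree(tree_file, allow_polytomy = allow_polytomy)
  params <- substitution_params(kappa = cfg$kappa, pi = cfg$pi,
                                global_rate = cfg$global_rate)
  res <- ovrf_simulate(g, orfs, phy, params = params, mu = cfg$mu, seed = seed)
  if (!is.null(out_prefix)) {
    write_alignment(res$alignment, paste0(out_prefix, ".fasta"))
    write_substitution_log(res$substitutions,
                           paste0(out_prefix, "_substitutions.tsv"))
    write_run_summary(res, paste0(out_prefix, "_summary.json"))
    return(invisible(res))
  }
  res
}
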