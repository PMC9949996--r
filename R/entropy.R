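#' Shannon entropy of one alignment column
#'
#' `H = -sum(P_i * log2(P_i))` over the residues present in the column
#' (`0 * log 0 := 0`). For nucleotide columns H ranges from 0 (completely
#' conserved) to 2 bits (all four bases equally frequent).
#'
#' @param counts Nonnegative residue counts (named or not) with at least one
#'   residue.
#' @return Entropy in bits.
#' @examples
#' column_entropy(c(A = 2, T = 2))  # 1
#' @export
column_entropy <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) stop("a column needs at least one residue")
  p <- counts / n
  -sum(p * log2(p))
}

# Alignment as a residue matrix (rows = sequences, columns = sites).
alignment_matrix <- function(alignment) {
  if (inherits(alignment, "ovrf_alignment") || is.character(alignment)) {
    m <- do.call(rbind, strsplit(toupper(unclass(alignment)), "",
                                 fixed = TRUE))
  } else {
    m <- alignment
  }
  m
}

#' Per-column entropy profile of an alignment
#'
#' Gap and ambiguity characters are excluded from the frequencies (with a
#' warning); columns are scored on their A/C/G/T content.
#'
#' @param alignment Named character vector of equal-length sequences (or an
#'   `ovrf_alignment`).
#' @return Numeric vector of per-column entropies (bits).
#' @export
alignment_entropy <- function(alignment) {
  m <- alignment_matrix(alignment)
  known <- m %in% NUCLEOTIDES
  if (!all(known)) {
    warning(sum(!known), " non-ACGT residue(s) excluded from entropy")
  }
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    counts <- tabulate(match(col, NUCLEOTIDES), nbins = 4L)
    column_entropy(counts)
  }, numeric(1))
}

#' Sliding-window mean of an entropy profile
#'
#' Averages per-column entropy over windows of `width` columns advancing by
#' `step`. Linear profiles yield only complete windows
#' (`length - width + 1` start positions at `step = 1`); circular profiles
#' wrap around the origin and yield one window per start position.
#'
#' @param h Per-column entropy (from [alignment_entropy()]).
#' @param width Window width in columns (default 20).
#' @param step Step size in columns (default 1).
#' @param circular Wrap windows around the end of the profile?
#' @return Data frame with `start`, `center` and `mean_h` per window.
#' @export
sliding_window_mean <- function(h, width = 20L, step = 1L, circular = FALSE) {
  n <- length(h)
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1")
  if (!circular && n < width) {
    stop("profile length ", n, " is shorter than the window width ", width)
  }
  starts <- if (circular) seq(1L, n, by = step) else
    seq(1L, n - width + 1L, by = step)
  means <- vapply(starts, function(s) {
    idx <- s:(s + width - 1L)
    if (circular) idx <- ((idx - 1L) %% n) + 1L
    mean(h[idx])
  }, numeric(1))
  center <- starts + (width - 1) / 2
  if (circular) center <- ((center - 1) %% n) + 1
  data.frame(start = starts, center = center, mean_h = means)
}

#' Region-stratified entropy summary
#'
#' Summarizes a per-column entropy profile within each ORF-membership region
#' (mean and interquartile range; quartiles use R's default linear
#' interpolation, `quantile type 7`), and compares overlapping coding
#' columns (two or more ORFs) against non-overlapping coding columns
#' (exactly one ORF) with a two-sided Wilcoxon rank-sum test.
#'
#' @param h Per-column entropy (from [alignment_entropy()]).
#' @param regions An [partition_regions()] object.
#' @return List with `regions` (data frame: `region`, `membership`,
#'   `n_sites`, `mean`, `q1`, `q3`) and `overlap_vs_single` (means of the
#'   two classes and the Wilcoxon p-value, or `NULL` when either class is
#'   empty).
#' @export
region_summary <- function(h, regions) {
  df <- do.call(rbind, lapply(regions, function(r) {
    hh <- h[r$sites]
    q <- quantile(hh, c(0.25, 0.75), names = FALSE, type = 7)
    data.frame(region = r$id,
               membership = paste(r$orf_membership, collapse = ","),
               n_sites = length(r$sites), mean = mean(hh),
               q1 = q[1L], q3 = q[2L], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  n_memb <- vapply(regions, function(r) length(r$orf_membership), 1L)
  ov <- unlist(lapply(regions[n_memb >= 2L], `[[`, "sites"))
  single <- unlist(lapply(regions[n_memb == 1L], `[[`, "sites"))
  cmp <- NULL
  if (length(ov) && length(single)) {
    w <- wilcox.test(h[ov], h[single], exact = FALSE)
    cmp <- list(mean_overlap = mean(h[ov]), mean_single = mean(h[single]),
                p_value = w$p.value, statistic = unname(w$statistic))
  }
  list(regions = df, overlap_vs_single = cmp)
}

#' Write an entropy profile as TSV
#'
#' Emits per-column entropies and, when `width` is given, the
#' sliding-window means, in one table (`type` column distinguishes rows).
#'
#' @param h Per-column entropy.
#' @param path Output file.
#' @param width,step,circular Passed to [sliding_window_mean()]; `width =
#'   NULL` skips the windowed rows.
#' @return `path`, invisibly.
#' @export
write_entropy_profile <- function(h, path, width = 20L, step = 1L,
                                  circular = FALSE) {
  cols <- data.frame(type = "column", position = seq_along(h), value = h,
                     stringsAsFactors = FALSE)
  out <- cols
  if (!is.null(width)) {
    w <- sliding_window_mean(h, width = width, step = step,
                             circular = circular)
    out <- rbind(cols, data.frame(type = "window", position = w$center,
                                  value = w$mean_h, stringsAsFactors = FALSE))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
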