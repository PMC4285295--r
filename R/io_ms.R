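## ms text format --------------------------------------------------------
##
## Interoperability with the ms / msABC ecosystem: datasets are written
## and read as the classic text layout (`//` block per locus, `segsites:`,
## `positions:`, one 0/1 haplotype row per sequence). Population sizes
## are not part of the format, so the reader takes them as a sidecar
## argument.

#' Write a dataset in ms text format
#'
#' Sites are written in column order; positions are taken from the
#' `positions` attribute of each locus matrix when present, otherwise
#' evenly spaced on (0, 1) (positions carry no information here: loci are
#' non-recombining). Loci with zero segregating sites produce a block
#' with `segsites: 0` and no haplotype rows.
#'
#' @param dataset a `dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ms_text <- function(dataset, path) {
  stopifnot(inherits(dataset, "dataset"))
  n <- length(dataset$pops)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("admixabc %d %d", n, length(dataset$loci)),
               sprintf("%d", dataset$provenance$seed %||% 0L), ""), con)
  for (l in dataset$loci) {
    S <- nrow(l)
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      pos <- attr(l, "positions") %||% sprintf("%.4f", seq_len(S) / (S + 1))
      writeLines(paste("positions:", paste(pos, collapse = " ")), con)
      writeLines(apply(l, 2, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read ms-format simulator output
#'
#' Parses `//` blocks into a `dataset`. Population sample sizes (the
#' sidecar the format lacks) are given via `n_seq`; sequences in each
#' block are assigned to populations in order, as ms does.
#'
#' @param path ms text file.
#' @param n_seq integer triple of per-population sample sizes.
#' @param locus_length nominal locus length in bp for the resulting
#'   [sample_config()].
#' @return a `dataset`.
#' @export
read_ms_text <- function(path, n_seq, locus_length = 500L) {
  stopifnot(length(n_seq) == 3, all(n_seq >= 1))
  n <- sum(n_seq)
  lines <- readLines(path)
  starts <- which(lines == "//")
  if (!length(starts)) stop("no '//' blocks found in ", path)
  loci <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    i <- starts[b] + 1L
    if (i > length(lines) || !startsWith(lines[i], "segsites:"))
      stop("malformed block ", b, ": expected 'segsites:' after '//'")
    S <- as.integer(sub("segsites:\\s*", "", lines[i]))
    if (is.na(S) || S < 0) stop("malformed segsites count in block ", b)
    if (S == 0) {
      loci[[b]] <- matrix(0L, 0, n)
      next
    }
    i <- i + 1L
    if (i > length(lines) || !startsWith(lines[i], "positions:"))
      stop("malformed block ", b, ": expected 'positions:'")
    pos <- strsplit(sub("positions:\\s*", "", lines[i]), "\\s+")[[1]]
    rows <- lines[(i + 1L):(i + n)]
    if (length(rows) < n || any(nchar(rows) != S))
      stop("row-length mismatch in block ", b, ": expected ", n,
           " haplotypes of ", S, " sites")
    m <- matrix(0L, S, n)
    for (j in seq_len(n)) {
      v <- as.integer(strsplit(rows[j], "")[[1]])
      if (anyNA(v) || any(v > 1)) stop("non-binary haplotype in block ", b)
      m[, j] <- v
    }
    attr(m, "positions") <- pos
    loci[[b]] <- m
  }
  new_dataset(loci, rep(1:3, n_seq),
              sample_config(n_seq, n_loci = length(loci),
                            locus_length = locus_length))
}
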