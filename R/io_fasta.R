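## Empirical alignments --------------------------------------------------
##
## Per-locus multiple sequence alignments with a sample -> population
## map. Diploid individuals may be encoded either as one record per
## individual using IUPAC ambiguity codes for heterozygous sites, or as
## two unordered haplotype records. Only biallelic, ungapped, fully
## determined sites are used; the filter operates per site, not per
## locus.

.IUPAC2 <- list(A = c("A", "A"), C = c("C", "C"), G = c("G", "G"),
                T = c("T", "T"),
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

#' Read a sample-to-population map
#'
#' Two tab-separated columns, `sample` and `population`, no header (a
#' header line naming the columns is tolerated and skipped).
#'
#' @param path TSV file.
#' @return data.frame with columns `sample`, `population`.
#' @export
read_popmap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "population"),
                   stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(df$sample[1]), "sample"))
    df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read per-locus alignments into a dataset
#'
#' Each FASTA file holds the aligned sequences of one locus. Record
#' names are resolved through the population map; with
#' `diploid = "iupac"` every record is a diploid individual contributing
#' two allele observations per site (heterozygote ambiguity codes
#' contribute one of each allele), with `diploid = "haplotypes"` every
#' record is a single haplotype. Sites containing a gap, an `N`, a
#' three-fold ambiguity code, or more than two alleles are excluded; the
#' counts of excluded and of monomorphic sites are recorded in the
#' dataset's `filter_counts` attribute and reported via [message()].
#'
#' @param files character vector of FASTA paths (one locus each).
#' @param popmap data.frame from [read_popmap()] (or equivalent).
#' @param pop_order optional character triple fixing which population is
#'   1 (first-diverging), 2 and 3; defaults to order of first appearance
#'   in `popmap`.
#' @param diploid `"iupac"` or `"haplotypes"`.
#' @return a `dataset`; sequences are ordered by population.
#' @export
read_alignments <- function(files, popmap, pop_order = NULL,
                            diploid = c("iupac", "haplotypes")) {
  diploid <- match.arg(diploid)
  stopifnot(all(c("sample", "population") %in% names(popmap)))
  pop_order <- pop_order %||% unique(popmap$population)
  if (length(pop_order) != 3) stop("exactly three populations are required")
  popmap <- popmap[order(match(popmap$population, pop_order)), , drop = FALSE]
  per_ind <- if (diploid == "iupac") 2L else 1L
  pops_seq <- rep(match(popmap$population, pop_order), each = per_ind)

  dropped_bad <- dropped_mono <- 0L
  loci <- vector("list", length(files))
  lens <- integer(length(files))
  for (f in seq_along(files)) {
    aln <- toupper(vapply(as.character(ape::read.FASTA(files[f])),
                          paste, "", collapse = ""))
    names(aln) <- sub("\\s.*$", "", names(aln))
    missing <- setdiff(popmap$sample, names(aln))
    if (length(missing))
      stop("locus ", files[f], ": unmapped or absent sample(s): ",
           paste(missing, collapse = ", "))
    aln <- aln[popmap$sample]
    L <- unique(nchar(aln))
    if (length(L) != 1)
      stop("locus ", files[f], ": ragged alignment (lengths ",
           paste(unique(nchar(aln)), collapse = ", "), ")")
    lens[f] <- L
    # expand to haplotype rows: characters matrix, sites x haplotypes
    chars <- vapply(aln, function(s) strsplit(s, "")[[1]], character(L))
    chars <- matrix(chars, nrow = L)
    hap <- matrix(NA_character_, L, length(aln) * per_ind)
    for (k in seq_along(aln)) {
      dec <- .IUPAC2[chars[, k]]
      bad <- vapply(dec, is.null, TRUE)
      if (per_ind == 2L) {
        hap[!bad, 2 * k - 1] <- vapply(dec[!bad], `[`, "", 1)
        hap[!bad, 2 * k] <- vapply(dec[!bad], `[`, "", 2)
      } else {
        ok <- !bad & chars[, k] %in% c("A", "C", "G", "T")
        hap[ok, k] <- chars[ok, k]
      }
    }
    keep_site <- !apply(is.na(hap), 1, any)
    nall <- apply(hap, 1, function(r) length(unique(r[!is.na(r)])))
    biallelic <- keep_site & nall == 2
    dropped_bad <- dropped_bad + sum(!keep_site | (keep_site & nall > 2))
    dropped_mono <- dropped_mono + sum(keep_site & nall == 1)
    sub <- hap[biallelic, , drop = FALSE]
    m <- matrix(0L, nrow(sub), ncol(hap))
    if (nrow(sub))
      for (s in seq_len(nrow(sub))) m[s, ] <- as.integer(sub[s, ] != sub[s, 1])
    loci[[f]] <- m
  }
  message(sprintf("alignment filter: %d site(s) dropped (gap/N/ambiguity/multiallelic), %d monomorphic site(s) skipped",
                  dropped_bad, dropped_mono))
  n_seq <- vapply(1:3, function(p) sum(pops_seq == p), 0L)
  ds <- new_dataset(loci, pops_seq,
                    sample_config(n_seq, n_loci = length(loci),
                                  locus_length = max(lens)))
  attr(ds, "filter_counts") <- c(excluded = dropped_bad, monomorphic = dropped_mono)
  ds
}

#' Observed statistics straight from alignments
#'
#' Convenience wrapper: [read_alignments()] followed by
#' [dataset_stats()].
#'
#' @inheritParams read_alignments
#' @param config a [stat_config()].
#' @return named statistic vector.
#' @export
stats_from_alignments <- function(files, popmap, config = stat_config("full_3pop"),
                                  pop_order = NULL,
                                  diploid = c("iupac", "haplotypes")) {
  dataset_stats(read_alignments(files, popmap, pop_order, diploid), config)
}

#' Export a dataset's segregating sites as FASTA alignments
#'
#' Writes one FASTA file per locus into `dir`, encoding the binary
#' alleles with the two nucleotides in `alleles` (the choice is
#' immaterial: all statistics are polarity-invariant). Record names are
#' `seq<k>`; the matching population map is written as `popmap.tsv`.
#' Intended for round-tripping simulated data through the empirical
#' input path.
#'
#' @param dataset a `dataset`.
#' @param dir output directory (created if needed).
#' @param alleles length-2 character vector of nucleotides.
#' @return character vector of FASTA paths (the popmap path is attached
#'   as attribute `popmap`).
#' @export
dataset_to_fasta <- function(dataset, dir, alleles = c("A", "G")) {
  stopifnot(inherits(dataset, "dataset"), length(alleles) == 2)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("seq%d", seq_along(dataset$pops))
  paths <- character(length(dataset$loci))
  for (l in seq_along(dataset$loci)) {
    m <- dataset$loci[[l]]
    seqs <- apply(m, 2, function(col) paste(alleles[col + 1L], collapse = ""))
    if (nrow(m) == 0) seqs <- rep(alleles[1], length(ids))  # 1-bp stub
    paths[l] <- file.path(dir, sprintf("locus_%04d.fa", l))
    writeLines(paste0(">", ids, "\n", seqs), paths[l])
  }
  pm <- file.path(dir, "popmap.tsv")
  write.table(data.frame(ids, paste0("pop", dataset$pops)), pm,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  attr(paths, "popmap") <- pm
  paths
}
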