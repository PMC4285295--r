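## Wakeley-Hey site-category summary statistics --------------------------

.PAIRS <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))

per_locus_stat_names <- function() {
  c("fixed_12", "shared_12", "private_12",
    "fixed_13", "shared_13", "private_13",
    "fixed_23", "shared_23", "private_23",
    "S_pop1", "S_pop2", "S_pop3", "S_total")
}

#' Summary-statistic configurations
#'
#' Defines which per-locus statistics are computed and how many
#' across-locus moments compress them:
#'
#' * `full_3pop`: 13 per-locus statistics (for each population pair, the
#'   proportions of informative sites that are fixed differences, shared
#'   polymorphisms, or private polymorphisms; the number of segregating
#'   sites in each population; and in the total sample) x 4 moments =
#'   52 statistics;
#' * `reduced_single_haploid`: when one population contributes a single
#'   sequence, its own S and the shared-polymorphism proportions of its
#'   two pairs are identically zero and are dropped: 10 x 4 = 40;
#' * `means_only`: the 13 per-locus statistics compressed by their means
#'   alone.
#'
#' @param id configuration identifier.
#' @param singleton_pop for `reduced_single_haploid`, which population
#'   (1-3) holds the single sequence.
#' @return an object of class `stat_config`.
#' @export
#' @examples
#' length(stat_names(stat_config("full_3pop")))               # 52
#' length(stat_names(stat_config("reduced_single_haploid")))  # 40
stat_config <- function(id = c("full_3pop", "reduced_single_haploid", "means_only"),
                        singleton_pop = 3L) {
  id <- match.arg(id)
  base <- per_locus_stat_names()
  moments <- c("mean", "var", "skew", "kurt")
  if (id == "reduced_single_haploid") {
    stopifnot(singleton_pop %in% 1:3)
    k <- singleton_pop
    drop <- c(sprintf("shared_%d%d", pmin(k, setdiff(1:3, k)), pmax(k, setdiff(1:3, k))),
              sprintf("S_pop%d", k))
    base <- setdiff(base, drop)
  } else if (id == "means_only") {
    moments <- "mean"
  }
  structure(list(id = id, per_locus = base, moments = moments,
                 singleton_pop = if (id == "reduced_single_haploid") as.integer(singleton_pop) else NA_integer_),
            class = "stat_config")
}

#' @rdname stat_config
#' @param config a `stat_config`.
#' @return `stat_names()` returns the ordered names of the compressed
#'   statistic vector (`<per-locus statistic>_<moment>`).
#' @export
stat_names <- function(config) {
  as.vector(t(outer(config$per_locus, config$moments, paste, sep = "_")))
}

#' @export
print.stat_config <- function(x, ...) {
  cat(sprintf("Statistic configuration '%s': %d per-locus statistics x %d moments = %d\n",
              x$id, length(x$per_locus), length(x$moments),
              length(x$per_locus) * length(x$moments)))
  invisible(x)
}

#' Classify one biallelic site for an ordered population pair
#'
#' The four mutually exclusive Wakeley-Hey categories, requiring no
#' ancestral-state polarization: a site is a `fixed_difference` when both
#' populations are monomorphic for different alleles, a
#' `shared_polymorphism` when both are polymorphic, `private_pop_i` /
#' `private_pop_j` when only that population is polymorphic, and
#' `uninformative` when both are monomorphic for the same allele. The
#' classification is symmetric under relabelling 0 <-> 1.
#'
#' @param alleles_i,alleles_j 0/1 allele vectors observed in each
#'   population (arbitrary labels).
#' @return one of `"fixed_difference"`, `"shared_polymorphism"`,
#'   `"private_pop_i"`, `"private_pop_j"`, `"uninformative"`.
#' @export
#' @examples
#' classify_site(c(0, 0, 0), c(1, 1))   # fixed_difference
#' classify_site(c(0, 1), c(0, 1, 1))   # shared_polymorphism
classify_site <- function(alleles_i, alleles_j) {
  if (!length(alleles_i) || !length(alleles_j))
    stop("both populations must have at least one allele observation")
  stopifnot(all(alleles_i %in% 0:1), all(alleles_j %in% 0:1))
  pi <- any(alleles_i != alleles_i[1])
  pj <- any(alleles_j != alleles_j[1])
  if (pi && pj) return("shared_polymorphism")
  if (pi) return("private_pop_i")
  if (pj) return("private_pop_j")
  if (alleles_i[1] != alleles_j[1]) return("fixed_difference")
  "uninformative"
}

## counts of derived-labelled alleles per population for a site matrix
pop_allele_counts <- function(sites, pops) {
  matrix(vapply(1:3, function(p) {
    cols <- which(pops == p)
    if (length(cols) == 1) as.numeric(sites[, cols])
    else rowSums(sites[, cols, drop = FALSE])
  }, numeric(nrow(sites))), nrow = nrow(sites))
}

#' Per-locus Wakeley-Hey statistics
#'
#' Computes the per-locus statistic vector for one locus: for each
#' population pair, the proportions of sites that are fixed differences,
#' shared polymorphisms or private polymorphisms (pooling the two private
#' categories), computed over the sites segregating within that pair's
#' combined sample (0 if there are none); the number of sites segregating
#' within each population; and in the total sample. All statistics are
#' functions of per-population allele counts only, so they are invariant
#' to phase and to 0/1 relabelling.
#'
#' @param locus either a `locus_data` object or a 0/1 site-by-sequence
#'   matrix (sites in rows).
#' @param config a [stat_config()].
#' @param pops integer vector (values 1-3) assigning each sequence
#'   (column) to a population; unused when `locus` is a `locus_data`.
#' @return named numeric vector (length 13 for `full_3pop` /
#'   `means_only`, 10 for `reduced_single_haploid`).
#' @export
locus_stats <- function(locus, config = stat_config("full_3pop"), pops = NULL) {
  if (inherits(locus, "locus_data")) {
    pops <- locus$pops
    locus <- locus$sites
  }
  stopifnot(is.matrix(locus), !is.null(pops), ncol(locus) == length(pops))
  npop <- vapply(1:3, function(p) sum(pops == p), 0L)
  if (any(npop == 0)) stop("every population needs at least one sequence")
  if (config$id == "reduced_single_haploid" && npop[config$singleton_pop] != 1L)
    stop("reduced_single_haploid requires exactly one sequence in population ",
         config$singleton_pop)
  cnt <- if (nrow(locus) == 0) matrix(numeric(0), 0, 3)
         else pop_allele_counts(locus, pops)
  poly <- sweep(cnt, 2, npop, function(c, n) c > 0 & c < n)
  full <- numeric(13)
  names(full) <- per_locus_stat_names()
  for (k in seq_along(.PAIRS)) {
    i <- .PAIRS[[k]][1]; j <- .PAIRS[[k]][2]
    cc <- cnt[, i] + cnt[, j]
    informative <- cc > 0 & cc < npop[i] + npop[j]
    d <- sum(informative)
    if (d > 0) {
      sh <- poly[, i] & poly[, j] & informative
      pv <- xor(poly[, i], poly[, j]) & informative
      fx <- informative & !poly[, i] & !poly[, j]
      full[3 * k - 2] <- sum(fx) / d
      full[3 * k - 1] <- sum(sh) / d
      full[3 * k]     <- sum(pv) / d
    }
  }
  full[10:12] <- colSums(poly)
  ctot <- rowSums(cnt)
  full[13] <- sum(ctot > 0 & ctot < sum(npop))
  full[config$per_locus]
}

#' Compress per-locus statistics into across-locus moments
#'
#' For each per-locus statistic, emits its across-locus mean and (unless
#' `means_only`) sample variance, standardized skewness
#' (m3 / m2^(3/2)) and standardized kurtosis (m4 / m2^2, without excess
#' correction). Statistics that are constant across loci get 0 for the
#' standardized higher moments.
#'
#' @param per_locus_matrix numeric matrix, loci x per-locus statistics
#'   (columns in the order of `config$per_locus`).
#' @param config a [stat_config()].
#' @return named numeric vector of length
#'   `length(config$per_locus) * length(config$moments)`.
#' @export
compress_moments <- function(per_locus_matrix, config = stat_config("full_3pop")) {
  m <- as.matrix(per_locus_matrix)
  n <- nrow(m)
  if (n < 2) stop("at least 2 loci are required to compute across-locus moments")
  if (ncol(m) != length(config$per_locus))
    stop("per-locus matrix has ", ncol(m), " columns; configuration '",
         config$id, "' expects ", length(config$per_locus))
  mu <- colMeans(m)
  if (identical(config$moments, "mean")) {
    out <- mu
    names(out) <- stat_names(config)
    return(out)
  }
  ctr <- sweep(m, 2, mu)
  m2 <- colMeans(ctr^2)
  m3 <- colMeans(ctr^3)
  m4 <- colMeans(ctr^4)
  vr <- m2 * n / (n - 1)
  ok <- m2 > 1e-12
  sk <- ifelse(ok, m3 / m2^1.5, 0)
  ku <- ifelse(ok, m4 / m2^2, 0)
  out <- as.vector(rbind(mu, vr, sk, ku))
  names(out) <- stat_names(config)
  out
}

#' Compute the compressed statistic vector of a dataset
#'
#' Applies [locus_stats()] to every locus and [compress_moments()] to the
#' resulting matrix.
#'
#' @param dataset a `dataset` object (see [simulate_dataset()],
#'   [read_alignments()], [read_ms_text()]).
#' @param config a [stat_config()].
#' @return named numeric statistic vector.
#' @export
dataset_stats <- function(dataset, config = stat_config("full_3pop")) {
  stopifnot(inherits(dataset, "dataset"))
  m <- t(vapply(dataset$loci,
                function(l) locus_stats(l, config, pops = dataset$pops),
                numeric(length(config$per_locus))))
  compress_moments(m, config)
}
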