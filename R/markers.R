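# Default single-copy ribosomal marker set: 14 universally single-copy
# ribosomal protein genes. The identities are configurable placeholders;
# the normalization arithmetic, not the database, is the contract.
.DEFAULT_MARKERS <- c("rplB", "rplC", "rplD", "rplE", "rplF", "rplN",
                      "rplP", "rplR", "rplV", "rpsC", "rpsH", "rpsJ",
                      "rpsQ", "rpsS")

#' Default single-copy marker gene ids
#'
#' @return character vector of 14 ribosomal protein gene ids.
#' @export
default_marker_genes <- function() .DEFAULT_MARKERS

#' Reads per kilobase per million (RPKM)
#'
#' \eqn{RPKM = reads / (length/10^3) / (library/10^6)}: read counts
#' normalized for gene length and sequencing depth.
#'
#' @param reads mapped read count(s).
#' @param length_bp gene length(s), bp.
#' @param library_size total library read count(s).
#' @return RPKM value(s), vectorized.
#' @export
rpkm <- function(reads, length_bp, library_size) {
  if (any(reads < 0)) stop("read counts must be non-negative", call. = FALSE)
  if (any(length_bp <= 0)) stop("gene length must be positive", call. = FALSE)
  if (any(library_size <= 0)) stop("library size must be positive",
                                   call. = FALSE)
  if (any(reads > library_size)) {
    stop("mapped reads exceed library size", call. = FALSE)
  }
  reads / (length_bp / 1e3) / (library_size / 1e6)
}

#' Community fraction of a target gene
#'
#' Fraction of the community encoding a target gene, inferred by
#' normalizing the target's RPKM against the mean RPKM of single-copy
#' ribosomal marker genes (whose mean abundance estimates total community
#' size): \eqn{100 \times RPKM_{target} / \overline{RPKM}_{markers}}.
#'
#' @param target_rpkm RPKM of the target gene (e.g. mcrA).
#' @param marker_rpkms numeric vector of marker-gene RPKMs in the same
#'   sample.
#' @return percentage of the community encoding the gene.
#' @export
community_fraction <- function(target_rpkm, marker_rpkms) {
  if (length(marker_rpkms) == 0 || mean(marker_rpkms) <= 0) {
    stop("marker RPKM mean must be positive", call. = FALSE)
  }
  if (any(target_rpkm < 0)) stop("target RPKM must be non-negative",
                                 call. = FALSE)
  100 * target_rpkm / mean(marker_rpkms)
}

#' Community fractions from a long-format count table
#'
#' Convenience wrapper: computes per-sample RPKM for every gene in a long
#' count table and normalizes a target gene against the marker set.
#'
#' @param counts data.frame with columns \code{sample}, \code{gene_id},
#'   \code{reads}, \code{length_bp}, \code{library_size}.
#' @param target target gene id (default \code{"mcrA"}).
#' @param markers marker gene ids present in the table.
#' @return data.frame with one row per sample: \code{sample},
#'   \code{target_rpkm}, \code{marker_mean_rpkm}, \code{fraction_pct}.
#' @export
community_fraction_table <- function(counts, target = "mcrA",
                                     markers = default_marker_genes()) {
  need <- c("sample", "gene_id", "reads", "length_bp", "library_size")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  counts$rpkm <- rpkm(counts$reads, counts$length_bp, counts$library_size)
  out <- lapply(split(counts, counts$sample), function(d) {
    m <- d$rpkm[d$gene_id %in% markers]
    t_rpkm <- d$rpkm[d$gene_id == target]
    if (length(t_rpkm) == 0) t_rpkm <- 0
    data.frame(sample = d$sample[1],
               target_rpkm = sum(t_rpkm),
               marker_mean_rpkm = mean(m),
               fraction_pct = community_fraction(sum(t_rpkm), m))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold change between two community fractions
#'
#' Ratio of a gene's community fraction in sample B over sample A. A zero
#' baseline is flagged as infinite rather than raising an error, since
#' detection from absence is a real outcome in low-biomass samples.
#'
#' @param fraction_a baseline community fraction (percent).
#' @param fraction_b comparison community fraction (percent).
#' @return list with \code{fold}, \code{fraction_a}, \code{fraction_b} and
#'   logical \code{infinite_baseline}.
#' @export
fold_change <- function(fraction_a, fraction_b) {
  if (fraction_a < 0 || fraction_b < 0) {
    stop("fractions must be non-negative", call. = FALSE)
  }
  if (fraction_a == 0) {
    return(list(fold = Inf, fraction_a = fraction_a,
                fraction_b = fraction_b, infinite_baseline = TRUE))
  }
  list(fold = fraction_b / fraction_a, fraction_a = fraction_a,
       fraction_b = fraction_b, infinite_baseline = FALSE)
}
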