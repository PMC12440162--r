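#' Polygenic score from allele dosages and SNP effect sizes
#'
#' Per-bee sum of effect-size-weighted alternative-allele dosages:
#' \eqn{score_b = \sum_s dosage_{b,s} \beta_s}. The effect allele is the
#' alternative allele, so a higher score aggregates more copies of
#' trait-associated alternative alleles.
#'
#' @param dosages bees-by-SNPs matrix with entries in \{0, 1, 2\} and SNP
#'   ids as column names.
#' @param effects data.frame \code{snp_id}, \code{beta}.
#' @return named numeric vector of per-bee scores.
#' @export
polygenic_score <- function(dosages, effects) {
  stopifnot(is.matrix(dosages), !is.null(colnames(dosages)),
            all(c("snp_id", "beta") %in% names(effects)))
  if (!all(dosages %in% c(0, 1, 2))) stop("dosages must be in {0, 1, 2}")
  missing <- setdiff(effects$snp_id, colnames(dosages))
  if (length(missing))
    stop("effect SNPs absent from dosage matrix: ",
         paste(missing, collapse = ", "))
  stats::setNames(
    as.numeric(dosages[, effects$snp_id, drop = FALSE] %*% effects$beta),
    rownames(dosages))
}

#' Hypergeometric gene-list overlap test
#'
#' Tests whether two gene lists drawn from a common background overlap more
#' than expected by chance. With background size N, list sizes |A| and |B|
#' and overlap k: fold enrichment is \eqn{k / (|A||B|/N)} and the p-value is
#' the upper-tail hypergeometric probability \eqn{P(X \ge k)} (the observed
#' overlap included). A Bonferroni adjustment multiplies by \code{n_tests}
#' and caps at 1.
#'
#' @param list_a,list_b character vectors of gene identifiers (deduplicated
#'   internally).
#' @param background_size number of genes in the common background N.
#' @param n_tests Bonferroni divisor (>= 1).
#' @return list of class \code{"overlap_result"}: \code{overlap},
#'   \code{fold_enrichment}, \code{p_value}, \code{p_adjusted},
#'   \code{n_a}, \code{n_b}, \code{background_size}.
#' @export
overlap_test <- function(list_a, list_b, background_size, n_tests = 1L) {
  a <- unique(list_a); b <- unique(list_b)
  if (length(a) > background_size || length(b) > background_size)
    stop("list larger than the background")
  if (n_tests < 1) stop("n_tests must be >= 1")
  k <- length(intersect(a, b))
  expected <- length(a) * length(b) / background_size
  fold <- if (expected > 0) k / expected else 0
  p <- stats::phyper(k - 1, length(a), background_size - length(a),
                     length(b), lower.tail = FALSE)
  structure(list(overlap = k, fold_enrichment = fold, p_value = p,
                 p_adjusted = min(1, p * n_tests),
                 n_a = length(a), n_b = length(b),
                 background_size = background_size),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("gene-list overlap: k =", x$overlap, "of", x$n_a, "x", x$n_b,
      "on background", x$background_size, "\n")
  cat("fold enrichment =", signif(x$fold_enrichment, 4),
      "; hypergeometric P(X >= k) =", format(x$p_value, digits = 4),
      "; Bonferroni-adjusted =", format(x$p_adjusted, digits = 4), "\n")
  invisible(x)
}

#' Group comparison statistics (one-way ANOVA, Tukey, rank-sum)
#'
#' One-way ANOVA across groups with all pairwise Tukey HSD comparisons;
#' when exactly two groups are present a Wilcoxon rank-sum test (midranks
#' for ties) is added.
#'
#' @param values numeric vector of per-bee measurements.
#' @param groups factor/character of group memberships, same length.
#' @return list: \code{anova} (data.frame \code{F}, \code{df1}, \code{df2},
#'   \code{p_value}), \code{tukey} (data.frame of pairwise comparisons with
#'   adjusted p), \code{wilcoxon} (two groups only: \code{W},
#'   \code{p_value}), \code{n_per_group}.
#' @export
group_stats <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n_per <- table(g)
  if (any(n_per < 2)) stop("group with < 2 observations: ",
                           paste(names(n_per)[n_per < 2], collapse = ", "))
  if (stats::var(values) == 0)
    stop("zero variance in values: F statistic undefined")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adjusted = tk[, "p adj"], row.names = NULL)
  res <- list(anova = data.frame(F = an$`F value`[1], df1 = an$Df[1],
                                 df2 = an$Df[2], p_value = an$`Pr(>F)`[1]),
              tukey = tukey, n_per_group = as.integer(n_per))
  if (nlevels(g) == 2) {
    w <- stats::wilcox.test(values[g == levels(g)[1]],
                            values[g == levels(g)[2]], exact = FALSE)
    res$wilcoxon <- data.frame(W = unname(w$statistic), p_value = w$p.value)
  }
  res
}

#' Spearman rank correlation between paired vectors
#'
#' Midranks handle ties. Used to relate polygenic scores to social-influence
#' information flow and other per-bee quantities.
#'
#' @param x,y equal-length numeric vectors.
#' @return list \code{rho}, \code{p_value}, \code{n}.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Read alternative-allele dosages from a VCF file
#'
#' Parses GT fields into per-individual counts of the alternative allele
#' (0/1/2) for biallelic SNPs, producing the bees-by-SNPs matrix consumed by
#' \code{\link{polygenic_score}}. Requires the \pkg{vcfR} package.
#'
#' @param path path to a VCF file (uncompressed or bgzipped).
#' @return integer matrix, rows = samples, columns = SNP ids
#'   (\code{CHROM_POS} when ID is missing).
#' @export
read_dosages_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  fallback <- paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = "_")
  ids[is.na(ids) | ids == "."] <- fallback[is.na(ids) | ids == "."]
  count_alt <- function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  }
  d <- t(apply(gt, c(1, 2), count_alt))
  colnames(d) <- ids
  storage.mode(d) <- "integer"
  d
}
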