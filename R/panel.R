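#' Construct a SNP effect panel
#'
#' A SNP panel holds the per-SNP summary statistics that parameterise the
#' polygenic model: the signed effect size `beta` (in phenotype-SD units per
#' copy of the effect allele), its standard error, and the effect-allele
#' frequency. All downstream quantities — the weighted allele score (WAS),
#' its centering constant and variance, expected tail odds ratios, and the
#' simulated Z-score model — are derived from these three columns.
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param effect_allele,other_allele Allele strings; must differ per SNP.
#' @param beta Numeric effect sizes in phenotype-SD units per effect allele.
#' @param se Numeric nonnegative standard errors of `beta`.
#' @param eaf Effect-allele frequencies, strictly inside (0, 1).
#'
#' @return A data frame of class `snp_panel` with one row per SNP.
#' @examples
#' pan <- snp_panel(paste0("rs", 1:3), "A", "G",
#'                  beta = c(0.05, -0.03, 0.08), se = 0.01,
#'                  eaf = c(0.3, 0.5, 0.12))
#' was_alpha(pan)
#' was_variance(pan)
#' @export
snp_panel <- function(snp_id, effect_allele, other_allele, beta, se, eaf) {
  n <- length(snp_id)
  panel <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = toupper(rep_len(as.character(effect_allele), n)),
    other_allele = toupper(rep_len(as.character(other_allele), n)),
    beta = rep_len(as.numeric(beta), n),
    se = rep_len(as.numeric(se), n),
    eaf = rep_len(as.numeric(eaf), n),
    stringsAsFactors = FALSE
  )
  validate_snp_panel(panel)
}

#' Coerce a data frame to a validated SNP panel
#'
#' Revalidates the panel invariants (unique ids, admissible frequencies and
#' variance budget); useful after subsetting or combining panels.
#'
#' @param x Data frame with the [snp_panel()] columns.
#' @return A validated `snp_panel`.
#' @export
as_snp_panel <- function(x) {
  validate_snp_panel(as.data.frame(x))
}

validate_snp_panel <- function(panel) {
  if (nrow(panel) < 1L) stop("panel must contain at least one SNP")
  if (anyNA(panel[c("snp_id", "beta", "se", "eaf")]))
    stop("panel contains missing values")
  if (any(!nzchar(panel$snp_id))) stop("snp_id must be nonempty")
  if (anyDuplicated(panel$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  if (any(panel$eaf <= 0 | panel$eaf >= 1))
    stop("effect_allele_freq must lie strictly in (0, 1)")
  if (any(panel$se < 0)) stop("se must be nonnegative")
  if (any(panel$effect_allele == panel$other_allele))
    stop("effect_allele and other_allele must differ")
  v <- sum(panel$beta^2 * 2 * panel$eaf * (1 - panel$eaf))
  if (v >= 1)
    stop("var(WAS) = ", format(v), " >= 1: no admissible residual variance")
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP effect panel:", nrow(x), "SNPs\n")
  cat(sprintf("  alpha (centering constant): %.4f SD\n", was_alpha(x)))
  cat(sprintf("  var(WAS): %.4f (residual sigma^2 = %.4f)\n",
              was_variance(x), 1 - was_variance(x)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more SNPs\n")
  invisible(x)
}

#' Centering constant of the weighted allele score
#'
#' The constant `alpha = sum_j beta_j * 2 * eaf_j` is the expectation of the
#' raw weighted dosage sum when dosages are drawn at panel frequencies, so
#' that the centered score `WAS = sum_j beta_j * dosage_j - alpha` has
#' population expectation zero.
#'
#' @param panel A [snp_panel()].
#' @return The centering constant, in phenotype-SD units.
#' @export
was_alpha <- function(panel) {
  sum(panel$beta * 2 * panel$eaf)
}

#' Variance of the weighted allele score
#'
#' Under independent biallelic SNPs with Binomial(2, eaf) dosages,
#' `var(WAS) = sum_j beta_j^2 * 2 * eaf_j * (1 - eaf_j)`. This must be
#' below 1 for the polygenic Z-score model to admit a nonnegative residual
#' variance `sigma^2_remaining = 1 - var(WAS)`.
#'
#' @param panel A [snp_panel()].
#' @return The score variance, in squared phenotype-SD units.
#' @export
was_variance <- function(panel) {
  v <- sum(panel$beta^2 * 2 * panel$eaf * (1 - panel$eaf))
  if (v >= 1) stop("var(WAS) >= 1: no admissible residual variance")
  v
}

#' Compute weighted allele scores
#'
#' For each individual the score is the effect-size-weighted sum of
#' effect-allele dosages, centered so its population expectation is zero:
#' `WAS_i = sum_j beta_j * dosage_ij - alpha_i`. Under missing genotypes the
#' centering constant `alpha_i` is restricted to the SNPs observed for that
#' individual, which preserves a zero expectation regardless of the
#' missingness pattern. Individuals with no observed SNPs get `NA`.
#'
#' @param dosages Numeric matrix, individuals x SNPs, effect-allele dosages
#'   in `{0, 1, 2}` with `NA` marking missing genotypes. Columns must align
#'   with the panel rows (checked by name when dimnames are present).
#' @param panel A [snp_panel()].
#' @return A data frame with columns `score` (SD units) and `n_snps_used`.
#' @examples
#' pan <- snp_panel("rs1", "A", "G", beta = 0.1, se = 0.01, eaf = 0.5)
#' compute_was(matrix(2, 1, 1), pan)  # 0.2 - 0.1 = 0.1
#' @export
compute_was <- function(dosages, panel) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(panel))
    stop("dosage matrix has ", ncol(dosages), " columns but panel has ",
         nrow(panel), " SNPs")
  if (!is.null(colnames(dosages)) &&
      !identical(colnames(dosages), panel$snp_id))
    stop("dosage columns are not aligned to the panel snp_id order")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && any(bad != 0 & bad != 1 & bad != 2))
    stop("dosages must be 0, 1, 2 or NA")
  beta <- panel$beta
  two_bp <- 2 * beta * panel$eaf
  miss <- is.na(dosages)
  d0 <- dosages
  d0[miss] <- 0
  # full-panel centering, then add back alpha contributions of missing SNPs
  score <- as.vector(d0 %*% beta) - sum(two_bp) + as.vector(miss %*% two_bp)
  n_used <- ncol(dosages) - rowSums(miss)
  score[n_used == 0L] <- NA_real_
  data.frame(score = score, n_snps_used = n_used,
             row.names = rownames(dosages))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles of their fractional rank
#' positions using Blom's offset `(rank - 3/8) / (n + 1/4)`, averaging ranks
#' over ties. The output is monotone in the input with mean approximately 0
#' and variance approximately 1; used as a robustness transform for
#' phenotype Z-scores.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Numeric vector of Z-scores, `NA` where the input is `NA`.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2L)
    stop("inverse normal transform needs at least 2 distinct values")
  n <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}
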