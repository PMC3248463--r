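#' Read a SNP effect panel from TSV
#'
#' Expects a tab-separated file with header
#' `snp_id  effect_allele  other_allele  eaf  beta  se` (any column order,
#' lower-case names, '.' decimals). Rows failing validation are reported
#' with their line number.
#'
#' @param path File path.
#' @return A [snp_panel()].
#' @examples
#' # bundled synthetic demo panel (160 SNPs explaining ~10% of variance)
#' pan <- read_panel(system.file("extdata", "synthetic_panel.tsv",
#'                               package = "polytail"))
#' pan
#' @export
read_panel <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("panel file missing column(s): ", paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("malformed ", col, " at line ", bad[1] + 1L, ": '",
           raw[[col]][bad[1]], "'")
    v
  }
  snp_panel(raw$snp_id, raw$effect_allele, raw$other_allele,
            beta = num("beta"), se = num("se"), eaf = num("eaf"))
}

#' Write a SNP effect panel to TSV
#'
#' @param panel A [snp_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(
    as.data.frame(panel)[c("snp_id", "effect_allele", "other_allele",
                           "eaf", "beta", "se")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from TSV, aligned to a panel
#'
#' The file's first column is the individual id; remaining columns are
#' snp_ids with cells 0/1/2/NA. Panel SNPs absent from the file are listed
#' and dropped with a warning (the returned attribute `panel` holds the
#' reduced panel); file columns not in the panel are ignored.
#'
#' @param path File path.
#' @param panel A [snp_panel()] giving the column order.
#' @return Numeric matrix (individuals x SNPs) with `NA` for missing, and
#'   attribute `panel` (the possibly reduced panel).
#' @export
read_dosages <- function(path, panel) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- raw[[1]]
  have <- intersect(panel$snp_id, names(raw))
  absent <- setdiff(panel$snp_id, names(raw))
  if (length(absent)) {
    warning("panel SNP(s) absent from dosage file, dropped: ",
            paste(absent, collapse = ", "))
    panel <- validate_snp_panel(
      as.data.frame(panel)[panel$snp_id %in% have, ])
  }
  m <- as.matrix(raw[have])
  if (!is.numeric(m)) storage.mode(m) <- "numeric"
  bad <- m[!is.na(m)]
  if (length(bad) && any(bad != 0 & bad != 1 & bad != 2))
    stop("dosage cells must be 0, 1, 2 or NA")
  rownames(m) <- ids
  attr(m, "panel") <- panel
  m
}

#' Write a dosage matrix to TSV
#'
#' @param dosages Matrix with individual rownames and snp_id colnames.
#' @param path Output path.
#' @param seed Optional seed recorded as a `# seed:` header comment.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(dosages, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste("# seed:", seed), con)
  df <- data.frame(individual_id = rownames(dosages) %||%
                     paste0("ind", seq_len(nrow(dosages))),
                   dosages, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sample table
#'
#' Tab-separated with columns `individual_id`, `z`, `group` and optionally
#' `stratum` (defaults to `"all"`). Group labels must be among
#' `short`/`tall`/`middle`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_samples <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("individual_id", "z", "group")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("sample file missing column(s): ", paste(miss, collapse = ", "))
  if (!all(s$group %in% c("short", "tall", "middle")))
    stop("group labels must be short/tall/middle")
  if (is.null(s$stratum)) s$stratum <- "all"
  s
}

#' Read effect-allele dosages from a VCF
#'
#' Matches VCF records to the panel by ID and converts genotypes to
#' effect-allele dosages by exact allele-string comparison: when
#' REF/ALT equal other/effect alleles the ALT dosage is used directly;
#' when swapped, `2 - dosage`. Any other combination — including
#' strand-ambiguous mismatches — is an error, never silently flipped.
#' Requires the vcfR package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param panel A [snp_panel()].
#' @return Dosage matrix as in [read_dosages()].
#' @export
read_dosages_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  id <- fix[, "ID"]
  have <- intersect(panel$snp_id, id)
  absent <- setdiff(panel$snp_id, id)
  if (length(absent)) {
    warning("panel SNP(s) absent from VCF, dropped: ",
            paste(absent, collapse = ", "))
    panel <- validate_snp_panel(
      as.data.frame(panel)[panel$snp_id %in% have, ])
  }
  if (!nrow(panel)) stop("no panel SNPs found in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  rows <- match(panel$snp_id, id)
  alt_dosage <- function(g) {
    ifelse(is.na(g), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1"), numeric(1)))
  }
  out <- matrix(NA_real_, ncol(gt), nrow(panel),
                dimnames = list(colnames(gt), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    r <- rows[j]
    ref <- toupper(fix[r, "REF"]); alt <- toupper(fix[r, "ALT"])
    d <- alt_dosage(gt[r, ])
    if (ref == panel$other_allele[j] && alt == panel$effect_allele[j]) {
      out[, j] <- d
    } else if (ref == panel$effect_allele[j] &&
               alt == panel$other_allele[j]) {
      out[, j] <- 2 - d
    } else {
      stop("allele mismatch for ", panel$snp_id[j], ": VCF ", ref, "/", alt,
           " vs panel ", panel$effect_allele[j], "/", panel$other_allele[j],
           " (strand flips are refused)")
    }
  }
  attr(out, "panel") <- panel
  out
}

#' Run the simulation-and-inference pipeline end to end
#'
#' Orchestrates the stages — simulate an ascertained cohort, score it,
#' run the per-SNP association scan, fit the observed-vs-null tail test,
#' optionally the stratified analysis, scenario comparison and sibling
#' benchmark — and writes tab-separated outputs (each with a `# seed:`
#' header) plus a plain-text log to `out_dir`. Re-running with the same
#' seed reproduces every output byte for byte.
#'
#' @param panel A [snp_panel()] (or a path read via [read_panel()]).
#' @param scheme Ascertainment scheme for the simulated cohort.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing all randomness.
#' @param n_replicates Null replicates for the tail test.
#' @param generating_model Optional [rare_variant_model()] used to
#'   generate the cohort.
#' @param scenarios Optional named list of scenarios for
#'   [scenario_comparison()].
#' @param strata Optional list of stratum specs for
#'   [stratified_tail_analysis()].
#' @param missing_rates Optional per-SNP missing rates for the cohort.
#' @param sibling_r,n_sib_pairs Optional sibling benchmark settings.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(panel, scheme, out_dir, seed = 1,
                         n_replicates = 500, generating_model = NULL,
                         scenarios = NULL, strata = NULL,
                         missing_rates = NULL,
                         sibling_r = NULL, n_sib_pairs = 10000) {
  if (is.character(panel)) panel <- read_panel(panel)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out_dir, "run.log")
  cat("polytail pipeline; seed:", seed, "\n", file = log)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    cat(sprintf("stage %s: %.2fs\n", name, proc.time()[["elapsed"]] - t0),
        file = log, append = TRUE)
    r
  }
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(paste("# seed:", seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  set.seed(seed)
  cohort <- stage("simulate",
                  simulate_cohort(panel, scheme, generating_model,
                                  missing_rates))
  was <- stage("was", compute_was(cohort$dosages, panel))
  tsv(data.frame(individual_id = paste0("ind", seq_along(was$score)),
                 z = cohort$z, group = cohort$group,
                 stratum = cohort$stratum, was = was$score,
                 n_snps_used = was$n_snps_used), "samples.tsv")
  write_dosages(cohort$dosages, file.path(out_dir, "dosages.tsv"),
                seed = seed)
  assoc <- stage("assoc", assoc_scan(
    cohort, panel,
    method = if (inherits(scheme, "quota_scheme")) "cmh" else "logistic"))
  exp_or <- expected_odds_ratio(panel$beta, panel$se, panel$eaf)
  tsv(cbind(assoc, exp_or), "assoc.tsv")
  fit <- stage("tail_test",
               was_tail_test(cohort, panel, scheme,
                             n_replicates = n_replicates))
  tsv(fit$table, "tail_test.tsv")
  strat <- scen <- sibs <- NULL
  if (!is.null(strata)) {
    strat <- stage("stratified",
                   stratified_tail_analysis(cohort, strata, panel, scheme,
                                            n_replicates = n_replicates))
    tsv(strat, "stratified.tsv")
  }
  if (!is.null(scenarios)) {
    scen <- stage("scenario",
                  scenario_comparison(cohort, scenarios, panel, scheme,
                                      n_replicates = n_replicates))
    tsv(scen, "scenarios.tsv")
  }
  if (!is.null(sibling_r)) {
    sibs <- stage("sibs", {
      pairs <- simulate_sibling_pairs(n_sib_pairs, sibling_r)
      s <- sibling_mean_z(pairs, "short")
      t <- sibling_mean_z(pairs, "tall")
      data.frame(tail = c("short", "tall"),
                 n = c(s$n, t$n), mean_sib_z = c(s$mean, t$mean),
                 ci_lo = c(s$ci[1], t$ci[1]), ci_hi = c(s$ci[2], t$ci[2]),
                 expected_additive = c(
                   expected_sib_mean_additive(sibling_r, 2.81, "short"),
                   expected_sib_mean_additive(sibling_r, 2.81, "tall")),
                 p_differential = tail_regression_test(s$sib_z, t$sib_z)$p)
    })
    tsv(sibs, "siblings.tsv")
  }
  invisible(list(cohort = cohort, was = was, assoc = assoc, fit = fit,
                 stratified = strat, scenarios = scen, siblings = sibs))
}
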