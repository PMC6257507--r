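# Reading, validation and harmonization of GWAS summary statistics.
#
# The canonical internal schema for an association table is one row per
# variant x trait with columns:
#   snp, effect_allele, other_allele, beta, se, pvalue, eaf, n, trait
# beta is the additive effect per copy of the effect allele: SD units for
# quantitative biomarkers, log-odds for case-control outcomes.

CANONICAL_COLUMNS <- c("snp", "effect_allele", "other_allele",
                       "beta", "se", "pvalue", "eaf", "n")
MANDATORY_COLUMNS <- c("snp", "effect_allele", "other_allele", "beta", "se")

#' Build a validated association table
#'
#' Constructs the canonical summary-statistic table used throughout the
#' package from vectors (or a data.frame with canonical column names) and
#' validates its invariants: positive standard errors, distinct A/C/G/T
#' alleles, p-values in \[0, 1\] and allele frequencies in (0, 1).
#'
#' @param snp Character vector of variant identifiers (rsIDs).
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @param beta,se Effect estimate per effect-allele copy and its standard
#'   error (SD units for biomarkers, log-odds for binary outcomes).
#' @param pvalue Two-sided p-values; computed from `beta/se` when missing.
#' @param eaf Effect-allele frequencies (optional, `NA` allowed).
#' @param n Per-variant sample size (optional).
#' @param trait Trait label attached to every row.
#' @return A `data.frame` with the canonical columns plus `trait`.
#' @examples
#' association_table(snp = "rs1800562", effect_allele = "A",
#'                   other_allele = "G", beta = 0.33, se = 0.01,
#'                   trait = "serum_iron")
#' @export
association_table <- function(snp, effect_allele, other_allele, beta, se,
                              pvalue = NULL, eaf = NA_real_, n = NA_real_,
                              trait = "trait") {
  df <- data.frame(
    snp = as.character(snp),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pvalue = if (is.null(pvalue)) z_pvalue(as.numeric(beta), as.numeric(se))
             else as.numeric(pvalue),
    eaf = as.numeric(eaf),
    n = as.numeric(n),
    trait = as.character(trait),
    stringsAsFactors = FALSE
  )
  validate_associations(df)
  df
}

#' Validate an association table against the schema invariants
#'
#' Checks every row of a canonical association table and raises a
#' `validation_error` naming the offending rows: `se > 0`,
#' `effect_allele != other_allele`, alleles in A/C/G/T, `pvalue` in
#' \[0, 1\], `eaf` missing or in (0, 1).
#'
#' @param df Data frame with at least the mandatory canonical columns.
#' @return `df`, invisibly, when valid.
#' @export
validate_associations <- function(df) {
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    ironmr_error(sprintf("association table lacks mandatory column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "configuration_error")
  }
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      ironmr_error(sprintf("%s in row(s) %s", what,
                           paste(utils::head(idx, 10), collapse = ", ")),
                   "validation_error")
    }
  }
  bad(!is.finite(df$se) | df$se <= 0, "non-positive or missing standard error")
  bad(!df$effect_allele %in% VALID_ALLELES | !df$other_allele %in% VALID_ALLELES,
      "allele not one of A/C/G/T")
  bad(df$effect_allele == df$other_allele, "identical effect and other allele")
  bad(!is.finite(df$beta), "missing beta")
  if ("pvalue" %in% names(df)) {
    bad(!is.na(df$pvalue) & (df$pvalue < 0 | df$pvalue > 1),
        "p-value outside [0, 1]")
  }
  if ("eaf" %in% names(df)) {
    bad(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1),
        "effect-allele frequency outside (0, 1)")
  }
  invisible(df)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited summary-statistic file into the canonical
#' schema. Non-canonical headers are handled through `column_map`, a named
#' character vector mapping canonical names to the file's column names
#' (e.g. `c(snp = "MarkerName", beta = "Effect")`). The p-value is computed
#' from beta/se when the file carries none.
#'
#' @param path Path to the file. The delimiter is sniffed from the header
#'   line unless `sep` is given.
#' @param trait Trait label attached to every record.
#' @param column_map Named character vector, canonical -> file column name.
#'   Canonical names not in the map are looked up verbatim.
#' @param sep Field separator; default sniffs `\t` vs `,`.
#' @return Canonical association `data.frame` (see [association_table()]).
#' @examples
#' path <- system.file("extdata", "gis_synthetic_serum_iron.tsv",
#'                     package = "ironmr")
#' head(read_gwas_summary(path, trait = "serum_iron"))
#' @export
read_gwas_summary <- function(path, trait, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) {
    ironmr_error(sprintf("summary-statistic file not found: %s", path),
                 "configuration_error")
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  resolve <- function(canon) {
    nm <- if (!is.null(column_map) && canon %in% names(column_map))
      column_map[[canon]] else canon
    if (!nm %in% names(raw)) return(NULL)
    raw[[nm]]
  }
  for (canon in MANDATORY_COLUMNS) {
    if (is.null(resolve(canon))) {
      ironmr_error(sprintf(
        "column for '%s' not found in %s (header: %s); supply a column_map",
        canon, path, paste(names(raw), collapse = ", ")),
        "configuration_error")
    }
  }
  association_table(
    snp = resolve("snp"),
    effect_allele = resolve("effect_allele"),
    other_allele = resolve("other_allele"),
    beta = resolve("beta"),
    se = resolve("se"),
    pvalue = resolve("pvalue"),
    eaf = resolve("eaf") %||% NA_real_,
    n = resolve("n") %||% NA_real_,
    trait = trait
  )
}

# Expected direction of each biomarker under rising systemic iron status:
# serum iron, ferritin and transferrin saturation rise, transferrin falls.
IRON_BIOMARKERS <- c(iron = 1, ferritin = 1, saturation = 1, transferrin = -1)

#' Select iron-status instruments from the four biomarker GWAS tables
#'
#' Implements the two instrument-selection rules of the study. In `strict`
#' mode a variant qualifies only if it is genome-wide significant
#' (`p < gw_threshold`) in all four biomarkers with a direction pattern
#' concordant with systemic iron status (serum iron, ferritin and
#' transferrin saturation moving together, transferrin opposite). In
#' `relaxed` mode genome-wide significance is required for at least one
#' biomarker, with direction concordance (at any p) in the remaining three.
#' Output is re-oriented so the effect allele is the iron-increasing allele.
#'
#' @param biomarker_tables Named list of canonical association tables with
#'   names `iron`, `ferritin`, `saturation`, `transferrin`.
#' @param mode `"strict"` or `"relaxed"`.
#' @param gw_threshold Genome-wide significance threshold (default 5e-8).
#' @return A `data.frame` with one row per selected variant: `snp`,
#'   iron-increasing `effect_allele`/`other_allele`, and per-biomarker
#'   `beta_*`, `se_*`, `pvalue_*` columns oriented to that allele.
#' @examples
#' tabs <- lapply(names(gis_synthetic_paths()), function(bm)
#'   read_gwas_summary(gis_synthetic_paths()[[bm]], trait = bm))
#' names(tabs) <- names(gis_synthetic_paths())
#' select_instruments(tabs, mode = "strict")$snp
#' @export
select_instruments <- function(biomarker_tables,
                               mode = c("strict", "relaxed"),
                               gw_threshold = 5e-8) {
  mode <- match.arg(mode)
  needed <- names(IRON_BIOMARKERS)
  missing_bm <- setdiff(needed, names(biomarker_tables))
  if (length(missing_bm) > 0) {
    ironmr_error(sprintf("biomarker table(s) missing: %s",
                         paste(missing_bm, collapse = ", ")),
                 "configuration_error")
  }
  for (bm in needed) validate_associations(biomarker_tables[[bm]])

  ref <- biomarker_tables[["iron"]]
  common <- Reduce(intersect, lapply(biomarker_tables[needed], `[[`, "snp"))
  out <- list()
  for (id in sort(common)) {
    ref_row <- ref[ref$snp == id, , drop = FALSE][1, ]
    aligned <- list()
    ok <- TRUE
    for (bm in needed) {
      row <- biomarker_tables[[bm]]
      row <- row[row$snp == id, , drop = FALSE][1, ]
      al <- align_to_alleles(row, ref_row$effect_allele, ref_row$other_allele)
      if (is.null(al)) { ok <- FALSE; break }
      aligned[[bm]] <- al
    }
    if (!ok) next
    betas <- vapply(aligned, `[[`, numeric(1), "beta")
    pvals <- vapply(aligned, `[[`, numeric(1), "pvalue")
    if (any(betas == 0)) next
    # concordance with a common iron-status direction (global sign s)
    s <- sign(betas[["iron"]])
    if (!all(sign(betas) == s * IRON_BIOMARKERS[needed])) next
    keep <- if (mode == "strict") all(pvals < gw_threshold)
            else any(pvals < gw_threshold)
    if (!keep) next
    # orient to the iron-increasing allele
    if (s < 0) {
      ea <- ref_row$other_allele; oa <- ref_row$effect_allele
      betas <- -betas
      aligned <- lapply(aligned, function(a) { a$eaf <- 1 - a$eaf; a })
    } else {
      ea <- ref_row$effect_allele; oa <- ref_row$other_allele
    }
    rec <- data.frame(snp = id, effect_allele = ea, other_allele = oa,
                      stringsAsFactors = FALSE)
    for (bm in needed) {
      rec[[paste0("beta_", bm)]] <- betas[[bm]]
      rec[[paste0("se_", bm)]] <- aligned[[bm]]$se
      rec[[paste0("pvalue_", bm)]] <- pvals[[bm]]
      rec[[paste0("eaf_", bm)]] <- aligned[[bm]]$eaf
    }
    out[[id]] <- rec
  }
  if (length(out) == 0) {
    res <- data.frame(snp = character(0), effect_allele = character(0),
                      other_allele = character(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
  }
  res
}

#' Align one association record to a reference allele pair
#'
#' Returns the record re-expressed with `ea`/`oa` as effect/other allele
#' (negating beta and flipping eaf when the record is oriented the other
#' way), resolving strand complements for non-palindromic pairs; NULL when
#' the allele sets are incompatible.
#' @noRd
align_to_alleles <- function(row, ea, oa) {
  a1 <- row$effect_allele; a2 <- row$other_allele
  if (a1 == ea && a2 == oa) return(row)
  if (a1 == oa && a2 == ea) {
    row$beta <- -row$beta
    row$eaf <- 1 - row$eaf
    row$effect_allele <- ea; row$other_allele <- oa
    return(row)
  }
  if (!is_palindromic(a1, a2)) {
    c1 <- allele_complement(a1); c2 <- allele_complement(a2)
    if (c1 == ea && c2 == oa) {
      row$effect_allele <- ea; row$other_allele <- oa
      return(row)
    }
    if (c1 == oa && c2 == ea) {
      row$beta <- -row$beta
      row$eaf <- 1 - row$eaf
      row$effect_allele <- ea; row$other_allele <- oa
      return(row)
    }
  }
  NULL
}

#' Harmonize an exposure/outcome record pair to a common effect allele
#'
#' Aligns the outcome association to the exposure's effect allele so the
#' pair refers to the same allele. Identical alleles leave betas unchanged;
#' swapped alleles negate the outcome beta (`flipped = TRUE`); strand
#' complements of non-palindromic pairs are resolved silently. Palindromic
#' variants (A/T, C/G) are ambiguous: under the default `"frequency"`
#' policy the pair is kept (orientation as labelled) only when both
#' effect-allele frequencies are available and both fall on the same side
#' of 0.5 outside the ambiguous band (`both < freq_threshold` or
#' `both > 1 - freq_threshold`); otherwise — or always, under `"drop"` —
#' the variant is dropped with a warning and `NULL` is returned.
#'
#' @param exposure,outcome Single-row canonical association records for the
#'   same variant (or a proxy-resolved pair).
#' @param palindrome_policy `"frequency"` (default) or `"drop"`.
#' @param freq_threshold Ambiguity band edge for the frequency policy
#'   (default 0.42: frequencies in \[0.42, 0.58\] are ambiguous).
#' @param proxy_of Original rsID when `outcome` is a proxy record.
#' @return One-row `data.frame` with `snp`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `flipped`, `proxy_of`; or `NULL` when the
#'   variant is dropped by the palindrome policy.
#' @examples
#' exp <- association_table("rs1", "A", "G", 0.2, 0.01, trait = "iron")
#' out <- association_table("rs1", "G", "A", 0.05, 0.02, trait = "stroke")
#' harmonize(exp, out)   # outcome beta becomes -0.05, flipped = TRUE
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("frequency", "drop"),
                      freq_threshold = 0.42, proxy_of = NA_character_) {
  palindrome_policy <- match.arg(palindrome_policy)
  ea <- exposure$effect_allele; oa <- exposure$other_allele
  pal_exp <- is_palindromic(ea, oa)
  pal_out <- is_palindromic(outcome$effect_allele, outcome$other_allele)

  result <- function(beta_out, se_out, flipped) {
    data.frame(snp = if (is.na(proxy_of)) exposure$snp else outcome$snp,
               beta_exposure = exposure$beta, se_exposure = exposure$se,
               beta_outcome = beta_out, se_outcome = se_out,
               flipped = flipped, proxy_of = proxy_of,
               stringsAsFactors = FALSE)
  }
  drop_with <- function(why) {
    warning(sprintf("variant %s dropped during harmonization: %s",
                    exposure$snp, why), call. = FALSE)
    NULL
  }

  if (pal_exp || pal_out) {
    if (!(pal_exp && pal_out)) {
      ironmr_error(sprintf(
        "incompatible allele sets for %s: %s/%s vs %s/%s", exposure$snp,
        ea, oa, outcome$effect_allele, outcome$other_allele),
        "harmonization_error")
    }
    if (palindrome_policy == "drop") return(drop_with("palindromic alleles"))
    f1 <- exposure$eaf; f2 <- outcome$eaf
    if (is.na(f1) || is.na(f2)) {
      return(drop_with("palindromic alleles with missing allele frequency"))
    }
    lo <- freq_threshold; hi <- 1 - freq_threshold
    if ((f1 < lo && f2 < lo) || (f1 > hi && f2 > hi)) {
      # same frequency side: the outcome effect allele is the same physical
      # allele as the exposure effect allele, whatever the strand labels say
      return(result(outcome$beta, outcome$se, FALSE))
    }
    return(drop_with(sprintf(
      "palindromic alleles with ambiguous frequencies (%.3f, %.3f)", f1, f2)))
  }

  aligned <- align_to_alleles(outcome, ea, oa)
  if (is.null(aligned)) {
    ironmr_error(sprintf(
      "incompatible allele sets for %s: %s/%s vs %s/%s", exposure$snp,
      ea, oa, outcome$effect_allele, outcome$other_allele),
      "harmonization_error")
  }
  # flipped records whether the outcome labels referred to the other allele
  flipped <- (outcome$effect_allele == oa && outcome$other_allele == ea) ||
    (allele_complement(outcome$effect_allele) == oa &&
       allele_complement(outcome$other_allele) == ea)
  result(aligned$beta, aligned$se, flipped)
}

#' Find a linkage-disequilibrium proxy for a missing variant
#'
#' When the target variant is absent from the outcome data, searches the
#' candidate records for the variant in highest LD with the target, subject
#' to `r2` strictly greater than `r2_min`. Ties in `r2` are broken by the
#' lexicographically smallest rsID so the result does not depend on input
#' order. The selection (or absence) is logged via `message()`.
#'
#' @param target rsID of the missing variant.
#' @param candidates Canonical association table of variants with outcome
#'   data available.
#' @param ld Data frame with columns `snp_a`, `snp_b`, `r2` (symmetric).
#' @param r2_min Strict lower bound on r2 (default 0.3).
#' @return The selected candidate record (one-row data.frame) or `NULL`.
#' @examples
#' ld <- data.frame(snp_a = "rs1800562", snp_b = "rs9999999", r2 = 0.9)
#' cand <- association_table("rs9999999", "A", "G", 0.1, 0.02,
#'                           trait = "stroke")
#' find_proxy("rs1800562", cand, ld)
#' @export
find_proxy <- function(target, candidates, ld, r2_min = 0.3) {
  if (is.null(ld) || nrow(ld) == 0 || is.null(candidates) ||
      nrow(candidates) == 0) {
    message(sprintf("no proxy available for %s", target))
    return(NULL)
  }
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld)))
  hits <- rbind(
    data.frame(snp = ld$snp_b[ld$snp_a == target],
               r2 = ld$r2[ld$snp_a == target], stringsAsFactors = FALSE),
    data.frame(snp = ld$snp_a[ld$snp_b == target],
               r2 = ld$r2[ld$snp_b == target], stringsAsFactors = FALSE)
  )
  hits <- hits[hits$snp %in% candidates$snp & hits$r2 > r2_min, , drop = FALSE]
  if (nrow(hits) == 0) {
    message(sprintf("no proxy available for %s (none with r2 > %g)",
                    target, r2_min))
    return(NULL)
  }
  hits <- hits[order(-hits$r2, hits$snp), , drop = FALSE]
  chosen <- hits$snp[1]
  message(sprintf("proxy for %s: %s (r2 = %g)", target, chosen, hits$r2[1]))
  candidates[candidates$snp == chosen, , drop = FALSE][1, ]
}

#' Paths to the bundled synthetic iron-biomarker GWAS fixture
#'
#' The package ships a small synthetic stand-in for the iron-biomarker
#' GWAS meta-analysis summary table: the eleven genome-wide significant
#' locus rsIDs with invented betas, standard errors and p-values whose
#' significance/direction pattern reproduces the published instrument
#' selection (three variants concordant and genome-wide significant in all
#' four biomarkers; three more genome-wide significant in at least one and
#' direction-concordant in the rest). The numbers are synthetic: they are
#' for exercising the selection and harmonization machinery, not for
#' inference about iron biology.
#'
#' @return Named character vector of file paths (`iron`, `ferritin`,
#'   `saturation`, `transferrin`).
#' @export
gis_synthetic_paths <- function() {
  bm <- c(iron = "gis_synthetic_serum_iron.tsv",
          ferritin = "gis_synthetic_log_ferritin.tsv",
          saturation = "gis_synthetic_transferrin_saturation.tsv",
          transferrin = "gis_synthetic_transferrin.tsv")
  vapply(bm, function(f) system.file("extdata", f, package = "ironmr"),
         character(1))
}
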