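# Study orchestration: four iron biomarkers x any number of stroke outcome
# tables x strict/relaxed instrument sets, all requested estimators, with
# per-variant (forest-plot) rows, proxy resolution, logging and a
# reproducible output bundle.

#' Build a study run configuration
#'
#' @param exposures Named list (`iron`, `ferritin`, `saturation`,
#'   `transferrin`) of canonical association tables, or of file paths read
#'   via [read_gwas_summary()].
#' @param outcomes Named list of outcome association tables or file paths;
#'   names are the outcome labels (e.g. `any_stroke`, `cardioembolic`).
#' @param mode Instrument selection: `"strict"`, `"relaxed"` or `"both"`.
#' @param methods Estimators to run: subset of `"ivw"`, `"egger"`,
#'   `"weighted_median"`. Default `NULL` runs IVW everywhere and adds the
#'   sensitivity estimators in relaxed mode, mirroring the study design.
#' @param delta_order Delta-method order for Wald-ratio SEs
#'   (`"second"`, default, or `"first"`).
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Integer seed; required when the weighted median is run.
#' @param ld Optional LD table (`snp_a`, `snp_b`, `r2`) or path, for proxy
#'   lookup of variants missing from an outcome table.
#' @param annotation Optional variant-phenotype annotation table
#'   (`snp`, `phenotype`, `pvalue`) or path, for the pleiotropy report.
#' @param gw_threshold Genome-wide significance threshold for selection.
#' @param proxy_r2 Strict lower bound on proxy LD r2 (default 0.3).
#' @param palindrome_policy Passed to [harmonize()].
#' @param column_maps Optional named list of column maps (per table name)
#'   used when `exposures`/`outcomes` are paths.
#' @param output_dir Optional directory for the output bundle (results TSV,
#'   per-variant TSV, JSON manifest, plain-text log).
#' @return An object of class `run_config`.
#' @export
run_config <- function(exposures, outcomes, mode = c("strict", "relaxed", "both"),
                       methods = NULL, delta_order = c("second", "first"),
                       n_boot = 10000, seed = NULL, ld = NULL,
                       annotation = NULL, gw_threshold = 5e-8,
                       proxy_r2 = 0.3,
                       palindrome_policy = c("frequency", "drop"),
                       column_maps = NULL, output_dir = NULL) {
  mode <- match.arg(mode)
  delta_order <- match.arg(delta_order)
  palindrome_policy <- match.arg(palindrome_policy)
  if (length(exposures) == 0 || length(outcomes) == 0 ||
      is.null(names(outcomes)) || any(names(outcomes) == "")) {
    ironmr_error("at least one named exposure and outcome table is required",
                 "configuration_error")
  }
  if (!is.null(methods)) {
    stopifnot(all(methods %in% c("ivw", "egger", "weighted_median")))
  }
  wm_requested <- is.null(methods) || "weighted_median" %in% methods
  if (wm_requested && mode %in% c("relaxed", "both") && is.null(seed)) {
    ironmr_error("a seed is required when the weighted median is to be run",
                 "configuration_error")
  }
  structure(list(
    exposures = exposures, outcomes = outcomes, mode = mode,
    methods = methods, delta_order = delta_order, n_boot = n_boot,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    ld = ld, annotation = annotation, gw_threshold = gw_threshold,
    proxy_r2 = proxy_r2, palindrome_policy = palindrome_policy,
    column_maps = column_maps, output_dir = output_dir
  ), class = "run_config")
}

resolve_table <- function(x, name, column_maps, trait) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_gwas_summary(x, trait = trait,
                             column_map = column_maps[[name]]))
  }
  ironmr_error(sprintf("table '%s' must be a data.frame or a file path", name),
               "configuration_error")
}

#' Run the full Mendelian randomization study
#'
#' For every exposure biomarker x outcome x instrument mode: selects
#' instruments from the four biomarker tables, resolves variants missing
#' from the outcome table through LD proxies (dropping them with a logged
#' warning when none qualifies), harmonizes alleles, and runs the requested
#' estimators. Emits a results table (one row per estimate, odds-ratio
#' scale included), a per-variant Wald-ratio table (forest-plot data), a
#' plain-text decision log, and — when an annotation table is configured —
#' a secondary-phenotype pleiotropy report. Cells with zero usable
#' instruments are recorded explicitly with `status = "no_instruments"`
#' rather than omitted.
#'
#' @param config A [run_config()].
#' @return An object of class `mr_study`: list with `results`, `per_snp`,
#'   `pleiotropy_report`, `log` (character vector) and `manifest`.
#' @examples
#' study <- simulate_study(simulation_config(theta = 0.1, seed = 11),
#'                         outcomes = "any_stroke")
#' cfg <- run_config(study$exposures, study$outcomes, mode = "strict")
#' res <- run_study(cfg)
#' subset(res$results, method == "ivw")
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  quiet <- function(expr) {
    # route estimator/harmonization messages and warnings into the run log
    withCallingHandlers(expr,
      warning = function(w) {
        note("warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        note("%s", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }

  exposure_tables <- lapply(names(config$exposures), function(nm)
    resolve_table(config$exposures[[nm]], nm, config$column_maps, nm))
  names(exposure_tables) <- names(config$exposures)
  outcome_tables <- lapply(names(config$outcomes), function(nm)
    resolve_table(config$outcomes[[nm]], nm, config$column_maps, nm))
  names(outcome_tables) <- names(config$outcomes)

  ld <- config$ld
  if (is.character(ld)) {
    ld <- utils::read.table(ld, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  }
  annotation <- config$annotation
  if (is.character(annotation)) {
    annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  }

  modes <- if (config$mode == "both") c("strict", "relaxed") else config$mode
  biomarkers <- names(IRON_BIOMARKERS)
  results <- list()
  per_snp <- list()

  for (mode in modes) {
    instruments <- select_instruments(exposure_tables, mode = mode,
                                      gw_threshold = config$gw_threshold)
    note("%s mode: %d instrument(s) selected: %s", mode, nrow(instruments),
         paste(instruments$snp, collapse = ", "))
    methods <- config$methods %||%
      if (mode == "relaxed") c("ivw", "egger", "weighted_median") else "ivw"

    for (oc in names(outcome_tables)) {
      out_tab <- outcome_tables[[oc]]
      for (bm in biomarkers) {
        harm <- list()
        for (i in seq_len(nrow(instruments))) {
          ins <- instruments[i, ]
          exp_rec <- data.frame(
            snp = ins$snp, effect_allele = ins$effect_allele,
            other_allele = ins$other_allele,
            beta = ins[[paste0("beta_", bm)]],
            se = ins[[paste0("se_", bm)]],
            eaf = ins[[paste0("eaf_", bm)]],
            stringsAsFactors = FALSE)
          out_rec <- out_tab[out_tab$snp == ins$snp, , drop = FALSE]
          proxy_of <- NA_character_
          if (nrow(out_rec) == 0) {
            note("%s absent from outcome '%s'; searching proxies", ins$snp, oc)
            out_rec <- quiet(find_proxy(ins$snp, out_tab, ld,
                                        r2_min = config$proxy_r2))
            if (is.null(out_rec)) {
              note("dropped %s for outcome '%s': no data and no proxy with r2 > %g",
                   ins$snp, oc, config$proxy_r2)
              next
            }
            proxy_of <- ins$snp
          }
          h <- tryCatch(
            quiet(harmonize(exp_rec, out_rec[1, ],
                            palindrome_policy = config$palindrome_policy,
                            proxy_of = proxy_of)),
            harmonization_error = function(e) {
              note("dropped %s for outcome '%s': %s", ins$snp, oc,
                   conditionMessage(e))
              NULL
            })
          if (is.null(h)) next
          harm[[length(harm) + 1]] <- h
        }

        cell <- sprintf("%s x %s [%s]", bm, oc, mode)
        if (length(harm) == 0) {
          note("cell %s failed: no usable instruments", cell)
          results[[length(results) + 1]] <- data.frame(
            exposure = bm, outcome = oc, mode = mode, method = "ivw",
            n_snps = 0L, beta = NA_real_, se = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, pvalue = NA_real_, odds_ratio = NA_real_,
            or_ci_low = NA_real_, or_ci_high = NA_real_,
            status = "no_instruments", stringsAsFactors = FALSE)
          next
        }
        harm_tab <- do.call(rbind, harm)
        note("cell %s: %d instrument(s) harmonized", cell, nrow(harm_tab))

        wald <- lapply(seq_len(nrow(harm_tab)), function(j)
          quiet(wald_ratio(harm_tab$beta_exposure[j], harm_tab$se_exposure[j],
                           harm_tab$beta_outcome[j], harm_tab$se_outcome[j],
                           order = config$delta_order)))
        for (j in seq_along(wald)) {
          wd <- as.data.frame(wald[[j]])
          per_snp[[length(per_snp) + 1]] <- cbind(
            data.frame(exposure = bm, outcome = oc, mode = mode,
                       snp = harm_tab$snp[j],
                       beta_exposure = harm_tab$beta_exposure[j],
                       se_exposure = harm_tab$se_exposure[j],
                       beta_outcome = harm_tab$beta_outcome[j],
                       se_outcome = harm_tab$se_outcome[j],
                       flipped = harm_tab$flipped[j],
                       proxy_of = harm_tab$proxy_of[j],
                       stringsAsFactors = FALSE),
            wd[, setdiff(names(wd), c("method", "n_snps"))])
        }

        add_result <- function(method, est_df) {
          results[[length(results) + 1]] <<- cbind(
            data.frame(exposure = bm, outcome = oc, mode = mode,
                       stringsAsFactors = FALSE),
            est_df, data.frame(status = "ok", stringsAsFactors = FALSE))
        }

        if ("ivw" %in% methods) {
          add_result("ivw", as.data.frame(ivw_fixed(wald)))
        }
        if ("egger" %in% methods) {
          if (nrow(harm_tab) >= 3) {
            eg <- egger_regression(harm_tab)
            add_result("egger_slope", data.frame(
              method = "egger_slope", n_snps = eg$n_snps, beta = eg$slope,
              se = eg$slope_se, ci_low = eg$slope_ci_low,
              ci_high = eg$slope_ci_high, pvalue = eg$slope_p,
              odds_ratio = exp(eg$slope), or_ci_low = exp(eg$slope_ci_low),
              or_ci_high = exp(eg$slope_ci_high), stringsAsFactors = FALSE))
            add_result("egger_intercept", data.frame(
              method = "egger_intercept", n_snps = eg$n_snps,
              beta = eg$intercept, se = eg$intercept_se,
              ci_low = eg$intercept_ci_low, ci_high = eg$intercept_ci_high,
              pvalue = eg$intercept_p, odds_ratio = NA_real_,
              or_ci_low = NA_real_, or_ci_high = NA_real_,
              stringsAsFactors = FALSE))
          } else {
            note("cell %s: MR-Egger skipped (%d < 3 instruments)", cell,
                 nrow(harm_tab))
          }
        }
        if ("weighted_median" %in% methods) {
          wm <- quiet(weighted_median(harm_tab, n_boot = config$n_boot,
                                      seed = config$seed,
                                      order = config$delta_order))
          add_result("weighted_median", data.frame(
            method = "weighted_median", n_snps = wm$n_snps, beta = wm$beta,
            se = wm$se, ci_low = wm$ci_low, ci_high = wm$ci_high,
            pvalue = wm$pvalue, odds_ratio = wm$odds_ratio,
            or_ci_low = wm$or_ci_low, or_ci_high = wm$or_ci_high,
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  results_tab <- do.call(rbind, results)
  rownames(results_tab) <- NULL
  per_snp_tab <- if (length(per_snp) > 0) do.call(rbind, per_snp) else
    data.frame()
  rownames(per_snp_tab) <- NULL

  pleio_report <- NULL
  if (!is.null(annotation)) {
    all_snps <- unique(unlist(lapply(modes, function(m)
      select_instruments(exposure_tables, mode = m,
                         gw_threshold = config$gw_threshold)$snp)))
    pleio_report <- quiet(annotate_pleiotropy(all_snps, annotation))
    note("pleiotropy report: %d secondary association(s) flagged",
         if (is.null(pleio_report)) 0L else nrow(pleio_report))
  }

  manifest <- list(
    package = "ironmr",
    version = as.character(utils::packageVersion("ironmr")),
    seed = config$seed,
    mode = config$mode,
    delta_order = config$delta_order,
    n_boot = config$n_boot,
    gw_threshold = config$gw_threshold,
    proxy_r2 = config$proxy_r2,
    palindrome_policy = config$palindrome_policy,
    exposures = names(config$exposures),
    outcomes = names(config$outcomes),
    config_hash = config_hash(config),
    n_results = nrow(results_tab)
  )

  study <- structure(list(results = results_tab, per_snp = per_snp_tab,
                          pleiotropy_report = pleio_report,
                          log = log_lines, manifest = manifest),
                     class = "mr_study")
  if (!is.null(config$output_dir)) write_study_outputs(study, config$output_dir)
  study
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("MR study: %d estimate(s) across %d cell(s); %d per-SNP row(s)\n",
              nrow(x$results),
              nrow(unique(x$results[c("exposure", "outcome", "mode")])),
              nrow(x$per_snp)))
  failed <- x$results$status != "ok"
  if (any(failed)) {
    cat(sprintf("  %d failed cell(s) with no usable instruments\n",
                sum(failed)))
  }
  invisible(x)
}

#' Deterministic fingerprint of a run configuration
#' @noRd
config_hash <- function(config) {
  key <- config[setdiff(names(config), c("output_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(key, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write the study output bundle
#'
#' Emits `results.tsv`, `per_snp.tsv`, `manifest.json` and `run.log` (and
#' `pleiotropy_report.tsv` when present) into `dir`. Runs with identical
#' configuration and seed produce byte-identical tables.
#'
#' @param study An `mr_study`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_study_outputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(dir, "results.tsv"),
             per_snp = file.path(dir, "per_snp.tsv"),
             manifest = file.path(dir, "manifest.json"),
             log = file.path(dir, "run.log"))
  utils::write.table(study$results, paths[["results"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$per_snp, paths[["per_snp"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(study$log, paths[["log"]])
  if (!is.null(study$pleiotropy_report)) {
    paths[["pleiotropy"]] <- file.path(dir, "pleiotropy_report.tsv")
    utils::write.table(study$pleiotropy_report, paths[["pleiotropy"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Report secondary phenotypes of instrument variants
#'
#' Scans a static variant-phenotype annotation table (a local stand-in for
#' an online phenome-wide lookup) and lists, per instrument, the secondary
#' phenotype associations reaching genome-wide significance. Purely a
#' report: estimates are never altered.
#'
#' @param snps Character vector of instrument rsIDs.
#' @param annotation_table Data frame with columns `snp`, `phenotype`,
#'   `pvalue`; `NULL` skips the report with a warning.
#' @param p_threshold Flagging threshold (default 5e-8).
#' @return Data frame of flagged associations (possibly zero rows), or
#'   `NULL` when no table is available.
#' @examples
#' ann <- data.frame(snp = "rs1799945",
#'                   phenotype = "systolic blood pressure", pvalue = 1e-10)
#' annotate_pleiotropy("rs1799945", ann)
#' @export
annotate_pleiotropy <- function(snps, annotation_table, p_threshold = 5e-8) {
  if (is.null(annotation_table)) {
    warning("no annotation table available; pleiotropy report skipped",
            call. = FALSE)
    return(NULL)
  }
  stopifnot(all(c("snp", "phenotype", "pvalue") %in% names(annotation_table)))
  hit <- annotation_table$snp %in% snps &
    annotation_table$pvalue < p_threshold
  out <- annotation_table[hit, c("snp", "phenotype", "pvalue"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a run configuration from a YAML file
#'
#' Reads a nested key-value config: `exposures:` and `outcomes:` map table
#' names to file paths; remaining keys are passed to [run_config()]
#' (`mode`, `methods`, `delta_order`, `n_boot`, `seed`, `ld`, `annotation`,
#' `gw_threshold`, `proxy_r2`, `palindrome_policy`, `column_maps`,
#' `output_dir`). Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path Path to the YAML configuration.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.character(p) && length(p) == 1 && !file.exists(p) &&
        file.exists(file.path(base, p))) file.path(base, p) else p
  }
  raw$exposures <- lapply(raw$exposures, fix_path)
  raw$outcomes <- lapply(raw$outcomes, fix_path)
  if (!is.null(raw$ld)) raw$ld <- fix_path(raw$ld)
  if (!is.null(raw$annotation)) raw$annotation <- fix_path(raw$annotation)
  allowed <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), allowed)])
}
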