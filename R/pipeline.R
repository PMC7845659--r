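#' Pipeline configuration
#'
#' Assembles the full-run configuration: generator settings, phenotype
#' families, QC thresholds, gene regions, permutation and imputation
#' counts, combination shape and the threshold scheme. Can be loaded from
#' a YAML file with [read_pipeline_config()].
#'
#' @param simulate A [sim_config()].
#' @param phenotypes Named character vector mapping outcome column to
#'   model family.
#' @param qc List of marker/sample QC thresholds.
#' @param regions Gene region tibble (gene_id, chrom, start, end).
#' @param K Gene-test permutations.
#' @param m Imputations.
#' @param alpha Inverse-gamma combination shape (1 = Fisher).
#' @param scheme A [threshold_scheme()].
#' @param seed Master seed (mandatory).
#' @param out_dir Optional output directory for TSV/PNG artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            phenotypes = c(remitted_code = "logistic",
                                           response_code = "logistic",
                                           pct_change = "linear",
                                           stem_code = "logistic"),
                            qc = list(hwe_p_min = 1e-4, max_missing = 0.05,
                                      min_maf = 0.05, min_call_rate = 0.97),
                            regions = NULL,
                            K = 999, m = 5, alpha = 1,
                            scheme = threshold_scheme(),
                            seed = 1L, out_dir = NULL) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  structure(list(simulate = simulate, phenotypes = phenotypes, qc = qc,
                 regions = regions, K = K, m = m, alpha = alpha,
                 scheme = scheme, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the `pipeline_config()`
#'   arguments (`simulate` as a nested map, `regions` as a TSV path).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- lapply(raw$simulate %||% list(), function(x) {
    if (is.list(x) && !is.data.frame(x)) unlist(x) else x
  })
  if (!is.null(sim_args$causal)) sim_args$causal <- tibble::as_tibble(raw$simulate$causal)
  sim <- do.call(sim_config, sim_args)
  regions <- if (!is.null(raw$regions)) read_regions(raw$regions)
  pipeline_config(simulate = sim,
                  phenotypes = unlist(raw$phenotypes %||%
                                        list(remitted_code = "logistic",
                                             response_code = "logistic",
                                             pct_change = "linear",
                                             stem_code = "logistic")),
                  qc = utils::modifyList(list(hwe_p_min = 1e-4, max_missing = 0.05,
                                              min_maf = 0.05, min_call_rate = 0.97),
                                         raw$qc %||% list()),
                  regions = regions, K = raw$K %||% 999, m = raw$m %||% 5,
                  alpha = raw$alpha %||% 1,
                  seed = raw$seed %||% stop("config must set a seed"),
                  out_dir = raw$out_dir)
}

#' Run the full pharmacogenetic pipeline on synthetic data
#'
#' Simulation, missingness injection, phenotype derivation, multiple
#' imputation, marker QC, per-cohort association scans (MI-pooled marker
#' estimates), gene-level permutation tests, Fisher meta-analysis and
#' pooled mega-analysis, tier classification, and report tables. Fully
#' deterministic given the config seed. When `out_dir` is set, every
#' result table is written as TSV stamped with the config hash and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `subjects`, `phenotypes` (observed, with
#'   missing visits), `stacks` (per-cohort `imputed_stack`), `qc`,
#'   `markers` (per-phenotype combined tibble with per-cohort, mega and
#'   meta columns plus tiers), `genes` (per-phenotype gene-test tibble, if
#'   regions configured), `tables` (report tables), `hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$simulate
  geno <- simulate_genotypes(sim)
  trial <- simulate_trial(geno, sim)
  panel <- inject_missingness(trial$panel, sim)
  pheno <- build_phenotypes(panel, trial$subjects)

  cohorts <- unique(trial$subjects$cohort)
  if (length(cohorts) != 2) stop("pipeline expects exactly two cohorts", call. = FALSE)
  split_ids <- split(trial$subjects$subject_id, trial$subjects$cohort)
  genos <- lapply(split_ids, function(ids) geno_subset(geno, subjects = ids))
  phenos <- lapply(split_ids, function(ids) dplyr::filter(pheno, .data$subject_id %in% ids))

  stacks <- lapply(cohorts, function(cc) {
    impute_stack(phenos[[cc]], m = config$m,
                 seed = derive_seed(config$seed, paste0("mi_", cc)))
  })
  names(stacks) <- cohorts

  qc_res <- lapply(cohorts, function(cc) {
    rep <- variant_stats(genos[[cc]])
    flt <- filter_variants(rep, hwe_p_min = config$qc$hwe_p_min,
                           max_missing = config$qc$max_missing,
                           min_maf = config$qc$min_maf)
    cr <- sample_call_rate(genos[[cc]])
    smp <- filter_samples(cr, min_rate = config$qc$min_call_rate)
    list(variants = rep, variant_filter = flt, call_rates = cr, sample_filter = smp)
  })
  names(qc_res) <- cohorts
  keep_ids <- Reduce(intersect, lapply(qc_res, function(q) q$variant_filter$retained))
  genos_qc <- lapply(cohorts, function(cc) {
    geno_subset(genos[[cc]],
                subjects = intersect(subject_ids(genos[[cc]]),
                                     qc_res[[cc]]$sample_filter$retained),
                variants = keep_ids)
  })
  names(genos_qc) <- cohorts

  merged <- merge_cohorts(genos_qc[[1]], genos_qc[[2]])
  pheno_mega <- dplyr::bind_rows(lapply(stacks, function(s) s$tables[[1]]))

  markers <- lapply(names(config$phenotypes), function(outc) {
    fam <- config$phenotypes[[outc]]
    per_cohort <- lapply(cohorts, function(cc) {
      mi_pooled_scan(genos_qc[[cc]], stacks[[cc]], outc, family = fam)
    })
    names(per_cohort) <- cohorts
    mega <- mega_scan(merged, pheno_mega, outc, family = fam)
    combined <- per_cohort[[1]] %>%
      dplyr::select("id", "chrom", "pos", "maf",
                    beta_a = "beta", p_a = "p_value") %>%
      dplyr::inner_join(per_cohort[[2]] %>%
                          dplyr::select("id", beta_b = "beta", p_b = "p_value"),
                        by = "id") %>%
      dplyr::inner_join(mega %>%
                          dplyr::select("id", mega_beta = "beta", mega_p = "p_value"),
                        by = "id") %>%
      dplyr::mutate(meta_p = purrr::map2_dbl(.data$p_a, .data$p_b, function(pa, pb) {
        if (is.na(pa) || is.na(pb)) NA_real_
        else inverse_gamma_combine(c(pa, pb), alpha = config$alpha)
      }))
    classify_hits(combined, config$scheme, unit = "snp")
  })
  names(markers) <- names(config$phenotypes)

  genes <- NULL
  if (!is.null(config$regions) && nrow(config$regions)) {
    genes <- lapply(names(config$phenotypes), function(outc) {
      fam <- config$phenotypes[[outc]]
      per_cohort <- lapply(cohorts, function(cc) {
        gene_scan(genos_qc[[cc]], stacks[[cc]]$tables[[1]], outc, config$regions,
                  family = fam, K = config$K,
                  seed = derive_seed(config$seed, paste0("gene_", cc, "_", outc)))
      })
      names(per_cohort) <- cohorts
      mega_g <- gene_scan(merged$genotypes, pheno_mega, outc, config$regions,
                          family = fam, K = config$K,
                          seed = derive_seed(config$seed, paste0("gene_mega_", outc)))
      out <- per_cohort[[1]] %>%
        dplyr::select("gene_id", "n_mapped", "n_retained",
                      prop_a = "prop_sig", p_a = "empirical_p") %>%
        dplyr::inner_join(per_cohort[[2]] %>%
                            dplyr::select("gene_id", prop_b = "prop_sig",
                                          p_b = "empirical_p"),
                          by = "gene_id") %>%
        dplyr::inner_join(mega_g %>%
                            dplyr::select("gene_id", mega_prop = "prop_sig",
                                          mega_p = "empirical_p"),
                          by = "gene_id") %>%
        dplyr::mutate(meta_p = purrr::map2_dbl(.data$p_a, .data$p_b, function(pa, pb) {
          if (is.na(pa) || is.na(pb)) NA_real_
          else inverse_gamma_combine(c(pa, pb), alpha = config$alpha)
        }))
      classify_hits(out, config$scheme, unit = "gene")
    })
    names(genes) <- names(config$phenotypes)
  }

  tables <- list(demography = report_demography(pheno),
                 response = report_response(pheno))
  hash <- rlang::hash(unclass(config))
  result <- list(subjects = trial$subjects, phenotypes = pheno, stacks = stacks,
                 qc = qc_res, merged_log = merged$log, markers = markers,
                 genes = genes, tables = tables, hash = hash, seed = config$seed)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  invisible(result)
}

# MI-aware marker scan: run the scan on each completed dataset and pool
# beta/se per variant by Rubin's rules; p from the pooled t.
mi_pooled_scan <- function(genotypes, stack, outcome, family) {
  scans <- lapply(stack$tables, function(tab) {
    scan_markers(genotypes, tab, outcome, family = family)
  })
  base <- scans[[1]]
  for (i in seq_len(nrow(base))) {
    est <- vapply(scans, function(s) s$beta[i], numeric(1))
    va <- vapply(scans, function(s) s$se[i]^2, numeric(1))
    if (anyNA(est) || anyNA(va)) next
    pl <- pool_rubin(est, va)
    base$beta[i] <- pl$estimate
    base$se[i] <- sqrt(pl$total)
    base$statistic[i] <- pl$statistic
    base$p_value[i] <- pl$p_value
    if (family == "logistic") base$or[i] <- exp(pl$estimate)
  }
  base
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = config$seed, config_hash = result$hash)
  p <- function(...) file.path(config$out_dir, paste0(...))
  readr::write_tsv(result$phenotypes, p("phenotypes.tsv"), na = "NA")
  readr::write_tsv(result$tables$demography, p("table_demography.tsv"))
  readr::write_tsv(result$tables$response, p("table_response.tsv"))
  for (outc in names(result$markers)) {
    readr::write_tsv(result$markers[[outc]], p("markers_", outc, ".tsv"), na = "NA")
  }
  if (!is.null(result$genes)) {
    for (outc in names(result$genes)) {
      readr::write_tsv(result$genes[[outc]], p("genes_", outc, ".tsv"), na = "NA")
    }
  }
  jsonlite::write_json(stamp, p("run.json"), auto_unbox = TRUE)
  invisible(NULL)
}

#' Demography report table
#'
#' Cohort-by-cohort summary in `N (%)` / `mean (s.d.)` cell format with a
#' between-cohort difference test per row (t for continuous, chi-square
#' for categorical).
#'
#' @param pheno Phenotype tibble (with cohort, sex, age).
#' @return Tibble: measure, one column per cohort, combined, p_value.
#' @export
report_demography <- function(pheno) {
  if (!nrow(pheno)) return(tibble::tibble(measure = character()))
  cohorts <- sort(unique(pheno$cohort))
  cell_n <- function(d, cond) fmt_n_pct(sum(cond(d), na.rm = TRUE), nrow(d))
  row_for <- function(measure, cell_fun, test_var, categorical) {
    cells <- c(list(combined = cell_fun(pheno)),
               stats::setNames(lapply(cohorts, function(cc) {
                 cell_fun(dplyr::filter(pheno, .data$cohort == cc))
               }), cohorts))
    pv <- tryCatch(difference_test(pheno, test_var, "cohort")$p_value,
                   error = function(e) NA_real_)
    tibble::as_tibble(c(list(measure = measure), cells, list(p_value = pv)))
  }
  dplyr::bind_rows(
    row_for("n", function(d) as.character(nrow(d)), "sex", TRUE) %>%
      dplyr::mutate(p_value = NA_real_),
    row_for("male", function(d) cell_n(d, function(x) x$sex == "male"), "sex", TRUE),
    row_for("age_years", function(d) fmt_mean_sd(d$age), "age", FALSE)
  )
}

#' Treatment-response summary table
#'
#' Remission by week, week-4 response and stem-depressed rates in
#' `N (%)` format, plus mean (s.d.) of the continuous percent change by
#' responder status.
#'
#' @param pheno Phenotype tibble.
#' @return Tibble: measure, cell, numerator, denominator, percent.
#' @export
report_response <- function(pheno) {
  if (!nrow(pheno)) return(tibble::tibble(measure = character()))
  rates <- summarize_rates(pheno)$rates
  rates %>%
    dplyr::mutate(cell = purrr::map2_chr(.data$numerator, .data$denominator, fmt_n_pct),
                  .after = "measure")
}

#' Gene plot of marker association signal
#'
#' `-log10(p)` against position for every marker in the flanked region,
#' one panel per analysis column, with the gene body and flank boundaries
#' drawn.
#'
#' @param markers Tibble with `pos` and one or more p-value columns.
#' @param region One-row gene region tibble.
#' @param p_cols P-value columns to plot (default all ending in `_p` or
#'   named `p_value`).
#' @param flank Flank in bp.
#' @return A ggplot object; the plotted data is in `$data`.
#' @export
plot_gene_region <- function(markers, region, p_cols = NULL, flank = 50000) {
  if (!nrow(markers)) stop("no markers in region", call. = FALSE)
  if (is.null(p_cols)) {
    p_cols <- grep("(_p$|^p_value$|^meta_p$|^mega_p$)", names(markers), value = TRUE)
  }
  long <- markers %>%
    dplyr::select("pos", dplyr::all_of(p_cols)) %>%
    tidyr::pivot_longer(-"pos", names_to = "analysis", values_to = "p") %>%
    dplyr::filter(!is.na(.data$p)) %>%
    dplyr::mutate(neglog10p = -log10(.data$p))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$neglog10p)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = c(region$start, region$end), linetype = "solid",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(region$start - flank, region$end + flank),
                        linetype = "dashed", colour = "grey70") +
    ggplot2::facet_wrap(~analysis) +
    ggplot2::labs(x = sprintf("chr%s position (bp)", region$chrom),
                  y = expression(-log[10](italic(p))),
                  title = region$gene_id) +
    ggplot2::theme_bw()
}

#' Save a gene plot with its underlying data
#'
#' Writes the image and a TSV of the plotted points alongside it, so
#' downstream checks can read numbers instead of parsing pixels.
#'
#' @param plot A ggplot from [plot_gene_region()].
#' @param path Image path (e.g. `.png`); the data TSV gets the same stem.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
save_gene_plot <- function(plot, path, width = 7, height = 5, dpi = 150) {
  suppressMessages(ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi))
  readr::write_tsv(plot$data, paste0(tools::file_path_sans_ext(path), "_data.tsv"))
  invisible(path)
}

#' Published HTR2A antidepressant-response marker summary
#'
#' Published per-cohort, mega- and meta-analysis summary statistics for
#' the HTR2A region markers reported for the remitted and response
#' phenotypes (two SSRI-treated MDD cohorts). Used to check the
#' combination and classification machinery against printed values.
#'
#' @return Tibble: snp, section, position, maf_a, or_a, p_a, maf_b, or_b,
#'   p_b, mega_maf, mega_or, mega_p, meta_p.
#' @export
published_htr2a_snps <- function() {
  path <- system.file("extdata", "htr2a_published_snps.tsv", package = "adpgx")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(snp = "c", section = "c", .default = "d"))
}
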