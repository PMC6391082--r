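#' Run pipeline stages end-to-end on synthetic data
#'
#' Umbrella driver: generates the synthetic inputs for each requested
#' stage (seeded from the config), executes the stage, writes its
#' tables under `out_dir`, and returns a machine-readable run report.
#' Stages: `enhancers` (stitch/score/rank/associate), `screen`
#' (three-criteria target screen), `dilution` (suppression curve),
#' `reporter` (normalized reporter values).
#'
#' @param config A `tregmir_config` from [default_config()].
#' @param stages Character vector of stage names, run in the order
#'   above regardless of input order.
#' @param out_dir Output directory (created if needed).
#' @return Run report (list): `config`, `config_hash`, `r_version`,
#'   `package_version`, `n_warnings`, `stages` (per-stage summary and
#'   output paths). Also written as `run_report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("enhancers", "screen", "dilution", "reporter"),
                         out_dir = tempfile("tregmir_run_")) {
  validate_config(config)
  known <- c("enhancers", "screen", "dilution", "reporter")
  if (length(stages) == 0L) stop("Empty stage list (usage error)")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L)
    stop("Unknown stage name(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  n_warn <- 0L
  report_stages <- list()
  run_stage <- function(name, fn) {
    res <- withCallingHandlers(fn(), warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
    log_msg(name, "done")
    res
  }

  if ("enhancers" %in% stages) {
    report_stages$enhancers <- run_stage("enhancers", function() {
      land <- gen_enhancer_landscape(seed, stitch_distance = config$stitch_distance)
      res <- call_super_enhancers(land$peaks, land$treatment, land$control,
                                  loci = land$loci,
                                  stitch_distance = config$stitch_distance)
      write_tsv(res$ranking, file.path(out_dir, "ranked_enhancers.tsv"))
      write_tsv(res$associations, file.path(out_dir, "locus_associations.tsv"))
      list(n_regions = nrow(res$ranking),
           n_super = sum(res$ranking$is_super),
           locus_rank = res$associations$rank[1L],
           locus_distance_bp = res$associations$distance_bp[1L],
           outputs = c("ranked_enhancers.tsv", "locus_associations.tsv"))
    })
  }
  if ("screen" %in% stages) {
    report_stages$screen <- run_stage("screen", function() {
      cohort <- gen_screen_cohort(seed, mirna = config$mirna_sequence %|na|%
                                    NULL)
      stats <- cohort_de_stats(cohort)
      cand <- run_screen(cohort$utrs, cohort$mirna, cohort$ago, stats,
                         fold_threshold = config$fold_threshold,
                         alpha = config$alpha)
      write_tsv(data.frame(gene = cand$genes), file.path(out_dir, "candidates.tsv"))
      jsonlite::write_json(
        lapply(cand$evidence, function(e) lapply(e, function(d)
          as.list(d[1L, , drop = FALSE]))),
        file.path(out_dir, "candidate_evidence.json"),
        auto_unbox = TRUE, digits = NA)
      list(n_candidates = length(cand$genes), candidates = cand$genes,
           outputs = c("candidates.tsv", "candidate_evidence.json"))
    })
  }
  if ("dilution" %in% stages) {
    report_stages$dilution <- run_stage("dilution", function() {
      wells <- gen_dilution_wells(seed, max_generations = config$max_generations)
      curve <- suppression_curve(wells$events, wells$wells,
                                 max_generations = config$max_generations)
      write_tsv(curve, file.path(out_dir, "suppression_curve.tsv"))
      list(ratios = curve$ratio, S = curve$S,
           outputs = "suppression_curve.tsv")
    })
  }
  if ("reporter" %in% stages) {
    report_stages$reporter <- run_stage("reporter", function() {
      rep_wells <- gen_reporter_wells(seed)
      norm <- normalize_reporter(rep_wells$wells)
      write_tsv(norm, file.path(out_dir, "reporter_normalized.tsv"))
      list(normalized = stats::setNames(
             norm$normalized_value[norm$vector == "mir_expressing"],
             norm$construct[norm$vector == "mir_expressing"]),
           outputs = "reporter_normalized.tsv")
    })
  }

  report <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("tregmir")),
    n_warnings = n_warn,
    stages = report_stages
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# NA-coalescing helper for optional config slots.
`%|na|%` <- function(x, y) if (length(x) == 1L && is.na(x)) y else x

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
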